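# Gene-expression layer: RPKM normalization, AR activity score, Spearman
# correlation.

#' The seven androgen-receptor-regulated genes of the AR activity score
#' @export
AR_TARGET_GENES <- c("TMPRSS2", "KLK2", "KLK3", "SLC45A3", "FKBP5",
                     "NKX3-1", "ACSL3")

#' Reads-per-kilobase-per-million (RPKM) normalization
#'
#' `rpkm = counts * 1e9 / (transcript_length_bp * library_size)`; linear
#' in counts, inversely proportional to library size.
#'
#' @param counts genes x samples matrix (or vector) of read counts.
#' @param transcript_length_bp per-gene transcript lengths (recycled down
#'   rows).
#' @param library_size per-sample library sizes (default: column sums of
#'   `counts`).
#' @return Matrix (or vector) of RPKM values.
#' @export
rpkm <- function(counts, transcript_length_bp, library_size = NULL) {
  stopifnot(all(counts >= 0), all(transcript_length_bp > 0))
  if (is.matrix(counts)) {
    library_size <- library_size %||% colSums(counts)
    stopifnot(all(library_size > 0),
              length(transcript_length_bp) %in% c(1, nrow(counts)))
    sweep(counts / transcript_length_bp, 2, library_size, "/") * 1e9
  } else {
    stopifnot(!is.null(library_size), all(library_size > 0))
    counts * 1e9 / (transcript_length_bp * library_size)
  }
}

#' Androgen-receptor activity score
#'
#' The per-sample median RPKM of the seven AR-regulated genes (TMPRSS2,
#' KLK2, KLK3, SLC45A3, FKBP5, NKX3-1, ACSL3). All seven genes must be
#' present; a score from fewer genes would be silently biased, so missing
#' genes are an error.
#'
#' @param expr genes x samples RPKM matrix with gene rownames.
#' @param genes the AR-regulated gene set (default [AR_TARGET_GENES]).
#' @return Named numeric vector of per-sample scores.
#' @export
ar_activity <- function(expr, genes = AR_TARGET_GENES) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  missing <- setdiff(genes, rownames(expr))
  if (length(missing) > 0) {
    stop("AR activity score requires all ", length(genes),
         " AR-regulated genes; missing: ", paste(missing, collapse = ", "))
  }
  apply(expr[genes, , drop = FALSE], 2, median)
}

#' Spearman rank correlation
#'
#' Pearson correlation of midrank-transformed values (ties share their
#' average rank).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return Correlation in \[-1, 1\].
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  cor(x, y, method = "spearman")
}
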