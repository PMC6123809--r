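# Gene-model handling, UTR derivation, region classification, minimal
# coding-consequence annotation, and the coverage-normalized mutation-rate
# statistic.
#
# All intervals are 0-based half-open two-column matrices (start, end),
# sorted and non-overlapping within a transcript.

#' Construct a gene model
#'
#' @param gene gene name.
#' @param chrom contig name.
#' @param strand `"+"` or `"-"`.
#' @param transcripts list of transcripts, each a list with `exons` (2-col
#'   matrix of 0-based half-open intervals) and `cds` (same shape, or NULL
#'   for non-coding transcripts). CDS must lie within the exons.
#' @param predominant index of the predominantly expressed transcript
#'   (default 1); can be overridden from expression data in
#'   [derive_utrs()].
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene, chrom, strand, transcripts, predominant = 1L) {
  stopifnot(strand %in% c("+", "-"), length(transcripts) >= 1)
  for (tx in transcripts) {
    ex <- tx$exons
    stopifnot(is.matrix(ex), ncol(ex) == 2, all(ex[, 2] > ex[, 1]))
    if (nrow(ex) > 1) {
      stopifnot(all(diff(ex[, 1]) > 0), all(ex[-nrow(ex), 2] <= ex[-1, 1]))
    }
    if (!is.null(tx$cds)) {
      stopifnot(all(apply(tx$cds, 1, function(iv)
        any(iv[1] >= ex[, 1] & iv[2] <= ex[, 2]))))
    }
  }
  structure(list(gene = gene, chrom = chrom, strand = strand,
                 transcripts = transcripts,
                 predominant = as.integer(predominant)),
            class = "gene_model")
}

# Gene span: leftmost exon start to rightmost exon end over all transcripts.
gene_span <- function(model) {
  exons <- do.call(rbind, lapply(model$transcripts, `[[`, "exons"))
  c(min(exons[, 1]), max(exons[, 2]))
}

# All CDS intervals over all transcripts (possibly overlapping).
all_cds <- function(model) {
  cds <- lapply(model$transcripts, `[[`, "cds")
  cds <- cds[!vapply(cds, is.null, logical(1))]
  if (length(cds) == 0) return(matrix(numeric(0), ncol = 2))
  do.call(rbind, cds)
}

# TRUE if [start, end) overlaps any interval row of mat.
overlaps_any <- function(start, end, mat) {
  if (nrow(mat) == 0) return(FALSE)
  any(start < mat[, 2] & end > mat[, 1])
}

#' Read gene models from a feature table
#'
#' Reads the transcript-feature TSV emitted by [write_cohort()] (columns
#' `gene`, `chrom`, `strand`, `transcript`, `feature` in `exon`/`CDS`,
#' `start`, `end`, `predominant`; 0-based half-open coordinates) into a
#' list of [gene_model()] objects.
#'
#' @param path TSV file path.
#' @return Named list of `gene_model` objects.
#' @export
read_gene_models <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  out <- list()
  for (g in unique(tab$gene)) {
    gt <- tab[tab$gene == g, , drop = FALSE]
    tx_ids <- unique(gt$transcript)
    txs <- lapply(tx_ids, function(id) {
      tt <- gt[gt$transcript == id, , drop = FALSE]
      ex <- tt[tt$feature == "exon", , drop = FALSE]
      cd <- tt[tt$feature == "CDS", , drop = FALSE]
      list(id = id,
           exons = matrix(c(ex$start, ex$end), ncol = 2),
           cds = if (nrow(cd)) matrix(c(cd$start, cd$end), ncol = 2)
                 else NULL)
    })
    pred <- match(TRUE, vapply(tx_ids, function(id)
      any(gt$predominant[gt$transcript == id]), logical(1)))
    out[[g]] <- gene_model(g, gt$chrom[1], gt$strand[1], txs,
                           predominant = if (is.na(pred)) 1L else pred)
  }
  out
}

#' Derive UTR intervals from a gene model
#'
#' UTRs are the exonic sequence of the predominantly expressed transcript
#' that lies outside its CDS; the 5' vs 3' assignment follows the strand.
#' When per-transcript expression values are supplied the transcript with
#' the highest expression is taken as predominant; otherwise the model's
#' `predominant` index is used, falling back to the transcript with the
#' longest CDS.
#'
#' @param model a [gene_model()].
#' @param expression optional numeric vector of per-transcript expression
#'   (same order/length as `model$transcripts`).
#' @return list with `utr5` and `utr3` interval matrices, the chosen
#'   `transcript` index, and `coding` (FALSE for a non-coding predominant
#'   transcript, in which case no UTRs are returned).
#' @export
derive_utrs <- function(model, expression = NULL) {
  stopifnot(inherits(model, "gene_model"))
  idx <- if (!is.null(expression)) {
    stopifnot(length(expression) == length(model$transcripts))
    which.max(expression)
  } else if (!is.null(model$predominant)) {
    model$predominant
  } else {
    cds_len <- vapply(model$transcripts, function(tx)
      if (is.null(tx$cds)) 0 else sum(tx$cds[, 2] - tx$cds[, 1]), numeric(1))
    which.max(cds_len)
  }
  tx <- model$transcripts[[idx]]
  if (is.null(tx$cds) || nrow(tx$cds) == 0) {
    return(list(utr5 = matrix(numeric(0), ncol = 2),
                utr3 = matrix(numeric(0), ncol = 2),
                transcript = idx, coding = FALSE))
  }
  cds_lo <- min(tx$cds[, 1])
  cds_hi <- max(tx$cds[, 2])
  left <- interval_intersect(tx$exons, 0, cds_lo)
  right <- interval_intersect(tx$exons, cds_hi, Inf)
  if (model$strand == "+") {
    list(utr5 = left, utr3 = right, transcript = idx, coding = TRUE)
  } else {
    list(utr5 = right, utr3 = left, transcript = idx, coding = TRUE)
  }
}

# Intersect interval rows of mat with the window [lo, hi).
interval_intersect <- function(mat, lo, hi) {
  s <- pmax(mat[, 1], lo)
  e <- pmin(mat[, 2], hi)
  keep <- e > s
  matrix(c(s[keep], e[keep]), ncol = 2)
}

#' Classify a variant position or interval by genomic region
#'
#' Priority order CDS > UTR > intron > intergenic. A variant is CDS if it
#' overlaps *any* annotated CDS of *any* transcript of the gene (UTR calls
#' are never allowed to overlap an annotated CDS); UTR5/UTR3 intervals come
#' from the predominant transcript; anything else inside the gene span is
#' intronic. Variants overlapping several genes yield one row per gene.
#'
#' @param chrom contig of the variant.
#' @param start,end 0-based half-open span of the affected reference bases
#'   (for an SNV, `end = start + 1`; for a pure insertion, `end = start`
#'   is widened to a 1 bp probe at the anchor base).
#' @param models list of [gene_model()] objects.
#' @return data.frame with columns `gene` and `region`
#'   (`CDS`/`UTR5`/`UTR3`/`intron`/`intergenic`); a single `intergenic` row
#'   with `gene = NA` if no gene overlaps.
#' @export
classify_variant <- function(chrom, start, end, models) {
  if (end <= start) end <- start + 1  # insertion anchor probe
  rows <- list()
  for (model in models) {
    if (model$chrom != chrom) next
    span <- gene_span(model)
    if (!(start < span[2] && end > span[1])) next
    region <- if (overlaps_any(start, end, all_cds(model))) {
      "CDS"
    } else {
      utrs <- derive_utrs(model)
      if (overlaps_any(start, end, utrs$utr5)) "UTR5"
      else if (overlaps_any(start, end, utrs$utr3)) "UTR3"
      else "intron"
    }
    rows[[length(rows) + 1L]] <- data.frame(
      gene = model$gene, region = region, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    return(data.frame(gene = NA_character_, region = "intergenic",
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Predict the coding consequence of a normalized variant
#'
#' A minimal consequence classifier on the predominant transcript: CDS SNVs
#' are translated through the standard genetic code (synonymous / missense /
#' stopgain); CDS indels are frameshift iff their length is not a multiple
#' of 3; UTR variants are `utr` (an indel in a UTR can never be a
#' frameshift); variants straddling an exon/intron boundary are
#' `splice_region` with no codon call.
#'
#' @param chrom,pos,ref,alt normalized variant (0-based `pos`).
#' @param model the [gene_model()] for the gene being annotated.
#' @param reference named character vector of contig sequences.
#' @return One of `synonymous`, `missense`, `stopgain`, `frameshift_indel`,
#'   `inframe_indel`, `utr`, `intronic`, `intergenic`, `splice_region`.
#' @export
consequence <- function(chrom, pos, ref, alt, model, reference) {
  stopifnot(inherits(model, "gene_model"))
  span_start <- pos
  span_end <- max(pos + nchar(ref), pos + 1)
  cls <- classify_variant(chrom, span_start, span_end, list(model))
  cls <- cls$region[match(model$gene, cls$gene)]
  if (is.na(cls) || cls == "intergenic") return("intergenic")
  if (cls %in% c("UTR5", "UTR3")) return("utr")
  if (cls == "intron") return("intronic")
  tx <- model$transcripts[[model$predominant]]
  # splice check: affected span crosses an internal exon edge of the
  # predominant transcript (an edge with adjacent intron)
  ex <- tx$exons
  if (nrow(ex) > 1) {
    internal_edges <- c(ex[-nrow(ex), 2], ex[-1, 1])
    if (any(internal_edges > span_start & internal_edges < span_end)) {
      return("splice_region")
    }
  }
  if (nchar(ref) != nchar(alt)) {
    len <- allele_length(ref, alt)
    return(if (len %% 3 == 0) "inframe_indel" else "frameshift_indel")
  }
  # CDS SNV: translate the affected codon
  cds <- tx$cds
  ord <- order(cds[, 1])
  cds <- cds[ord, , drop = FALSE]
  cds_pos_fwd <- unlist(apply(cds, 1, function(iv) seq(iv[1], iv[2] - 1)))
  i <- match(pos, cds_pos_fwd)
  if (is.na(i)) return("splice_region")  # overlaps CDS but base not in predominant CDS
  seq_ <- reference[[chrom]]
  cds_seq <- paste(substring(seq_, cds_pos_fwd + 1, cds_pos_fwd + 1),
                   collapse = "")
  if (model$strand == "-") {
    cds_seq <- revcomp(cds_seq)
    i <- nchar(cds_seq) - i + 1L
    ref <- revcomp(ref)
    alt <- revcomp(alt)
  }
  codon_i <- (i - 1) %/% 3
  frame <- (i - 1) %% 3
  codon <- substr(cds_seq, codon_i * 3 + 1, codon_i * 3 + 3)
  if (nchar(codon) < 3) return("splice_region")  # truncated terminal codon
  new_codon <- codon
  substr(new_codon, frame + 1, frame + 1) <- alt
  code <- Biostrings::GENETIC_CODE
  aa_old <- code[[codon]]
  aa_new <- code[[new_codon]]
  if (aa_new == aa_old) "synonymous"
  else if (aa_new == "*") "stopgain"
  else "missense"
}

#' Coverage-normalized somatic mutation rate
#'
#' The regional mutation rate is defined as the total number of somatic
#' mutations in the region, divided by the number of genomic positions
#' exceeding the coverage floor (in megabases), divided by the number of
#' ctDNA-positive cfDNA samples. The coverage floor is strict
#' (`depth > depth_floor`) and the ctDNA gate is strict
#' (`ctdna_fraction > ctdna_floor`).
#'
#' @param mutations data.frame of mutations with columns `chrom`, `pos`
#'   (0-based); only rows falling inside `region` are counted.
#' @param depth data.frame depth track with columns `chrom`, `pos`
#'   (0-based), `depth` (the pooled per-position track; positions absent
#'   from the track count as uncovered).
#' @param region data.frame of intervals with columns `chrom`, `start`,
#'   `end` (0-based half-open).
#' @param samples data.frame of cfDNA sample metadata with a
#'   `ctdna_fraction` column.
#' @param depth_floor coverage floor (default 200).
#' @param ctdna_floor ctDNA-positivity gate (default 0.02).
#' @return list with `mutation_count`, `covered_mb`, `n_samples`, and
#'   `rate` (mutations per Mb per sample; `NA` with `defined = FALSE` when
#'   no position passes the coverage floor or no sample is eligible).
#' @export
mutation_rate <- function(mutations, depth, region, samples,
                          depth_floor = 200, ctdna_floor = 0.02) {
  in_region <- function(chrom, pos) {
    hit <- rep(FALSE, length(pos))
    for (i in seq_len(nrow(region))) {
      hit <- hit | (chrom == region$chrom[i] &
                    pos >= region$start[i] & pos < region$end[i])
    }
    hit
  }
  count <- if (nrow(mutations) == 0) 0L else
    sum(in_region(mutations$chrom, mutations$pos))
  covered <- if (nrow(depth) == 0) 0L else
    sum(in_region(depth$chrom, depth$pos) & depth$depth > depth_floor)
  covered_mb <- covered / 1e6
  n_samples <- sum(samples$ctdna_fraction > ctdna_floor)
  if (covered == 0L || n_samples == 0L) {
    return(list(mutation_count = count, covered_mb = covered_mb,
                n_samples = n_samples, rate = NA_real_, defined = FALSE))
  }
  list(mutation_count = count, covered_mb = covered_mb,
       n_samples = n_samples, rate = count / covered_mb / n_samples,
       defined = TRUE)
}
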