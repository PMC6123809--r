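# Internal helpers shared across modules.

BASES <- c("A", "C", "G", "T")

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Generate a random DNA sequence
#' @param n sequence length in bp.
#' @return A character scalar over the alphabet ACGT.
#' @keywords internal
random_dna <- function(n) {
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

#' Reverse complement of a DNA string
#' @param x character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

# Centered moving average with shrinking windows at the edges: value i is the
# mean of x over [i - h, i + h] intersected with [1, n], h = (window - 1) / 2.
smoothed_mean <- function(x, window) {
  stopifnot(window >= 1, window %% 2 == 1)
  n <- length(x)
  if (n == 0L) return(numeric(0))
  h <- (window - 1L) / 2L
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Deterministic sub-seed derivation: a seeded run draws one 31-bit seed per
# stream so samples can be re-materialized independently and identically.
derive_seeds <- function(master_seed, n) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(master_seed)
  sample.int(.Machine$integer.max - 1L, n)
}

# Left-align and make parsimonious a variant allele against a reference
# sequence (single contig, 0-based pos). SNVs pass through; indels are
# shifted left through repeat context and reduced to the VCF-style minimal
# representation in which ref and alt share their first base.
#
# seq: reference contig as a character scalar; pos: 0-based position of the
# first base of `ref` on the contig.
normalize_allele <- function(seq, pos, ref, alt) {
  stopifnot(nchar(ref) >= 1, nchar(alt) >= 1)
  if (nchar(ref) == 1 && nchar(alt) == 1) {
    return(list(pos = pos, ref = ref, alt = alt))
  }
  r <- strsplit(ref, "")[[1]]
  a <- strsplit(alt, "")[[1]]
  repeat {
    # trim shared trailing base; if one allele would empty, extend left
    if (length(r) > 0 && length(a) > 0 && r[length(r)] == a[length(a)]) {
      if (length(r) == 1L || length(a) == 1L) {
        if (pos == 0L) break  # cannot extend past contig start
        pos <- pos - 1L
        b <- substr(seq, pos + 1L, pos + 1L)
        r <- c(b, r[-length(r)])
        a <- c(b, a[-length(a)])
      } else {
        r <- r[-length(r)]
        a <- a[-length(a)]
      }
    } else break
  }
  # trim shared leading bases, keep at least one in each allele
  while (length(r) > 1L && length(a) > 1L && r[1] == a[1]) {
    r <- r[-1]
    a <- a[-1]
    pos <- pos + 1L
  }
  list(pos = pos, ref = paste(r, collapse = ""), alt = paste(a, collapse = ""))
}

# Variant type from a normalized ref/alt pair.
allele_type <- function(ref, alt) {
  ifelse(nchar(ref) == 1 & nchar(alt) == 1, "SNV",
    ifelse(nchar(ref) > nchar(alt), "del", "ins"))
}

# Signed length of a normalized indel (0 for SNVs).
allele_length <- function(ref, alt) {
  abs(nchar(alt) - nchar(ref))
}

# "chrom:pos:ref>alt" identity key used for cross-sample mutation matching.
allele_key <- function(chrom, pos, ref, alt) {
  paste0(chrom, ":", pos, ":", ref, ">", alt)
}
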