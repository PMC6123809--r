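# In-house read preprocessing: smoothed base-quality tail trimming and
# SNP-genotype verification of cfDNA/WBC sample pairings.

#' Trim a low-quality 3' read tail using smoothed base qualities
#'
#' Base qualities are smoothed with a centered moving average (window
#' shrinking at the read edges). The maximal contiguous 3'-terminal run of
#' positions whose smoothed quality falls below `threshold` is removed;
#' interior quality dips are left untouched (only tails are trimmed, and
#' the 5' end is never touched). Trimming is applied iteratively until a
#' fixed point, so the operation is idempotent even though edge-shrinking
#' changes smoothed values near a new 3' end.
#'
#' @param read a list with elements `seq` (character scalar), `baseq`
#'   (integer vector of Phred scores, one per base), and optionally `cigar`
#'   (character scalar), which is truncated consistently.
#' @param window odd smoothing window width in bases (default 11).
#' @param threshold Phred threshold; smoothed quality below this is trimmed
#'   (default 30).
#' @return The read with `seq`/`baseq` (and `cigar` if present) truncated;
#'   a logical element `fully_trimmed` is set when nothing survives (the
#'   read is emitted with zero length, not dropped).
#' @export
trim_low_quality_tail <- function(read, window = 11, threshold = 30) {
  stopifnot(window >= 1, window %% 2 == 1)
  stopifnot(nchar(read$seq) == length(read$baseq))
  n <- length(read$baseq)
  repeat {
    if (n == 0L) break
    sm <- smoothed_mean(read$baseq[seq_len(n)], window)
    # length of the contiguous low-quality suffix
    low <- sm < threshold
    k <- 0L
    while (k < n && low[n - k]) k <- k + 1L
    if (k == 0L) break
    n <- n - k
  }
  trimmed <- length(read$baseq) - n
  read$seq <- substr(read$seq, 1L, n)
  read$baseq <- read$baseq[seq_len(n)]
  if (!is.null(read$cigar) && trimmed > 0L) {
    read$cigar <- truncate_cigar(read$cigar, n)
  }
  read$fully_trimmed <- n == 0L
  read
}

# Truncate a CIGAR string so it consumes exactly new_qlen query bases.
# Trailing deletions left dangling after truncation are dropped.
truncate_cigar <- function(cigar, new_qlen) {
  if (new_qlen == 0L) return("*")
  ops <- cigar_ops(cigar)
  consumes_q <- ops$op %in% c("M", "I", "S", "=", "X")
  out_op <- character(0)
  out_len <- integer(0)
  left <- new_qlen
  for (i in seq_along(ops$op)) {
    if (left == 0L) break
    take <- if (consumes_q[i]) min(ops$len[i], left) else ops$len[i]
    out_op <- c(out_op, ops$op[i])
    out_len <- c(out_len, take)
    if (consumes_q[i]) left <- left - take
  }
  # drop trailing non-query ops (e.g. a deletion at the cut point)
  while (length(out_op) > 0 && out_op[length(out_op)] %in% c("D", "N")) {
    out_op <- out_op[-length(out_op)]
    out_len <- out_len[-length(out_len)]
  }
  paste0(out_len, out_op, collapse = "")
}

# Parse a CIGAR string into op/len vectors.
cigar_ops <- function(cigar) {
  if (cigar == "*") return(list(op = character(0), len = integer(0)))
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
  stopifnot(length(lens) == length(ops))
  list(op = ops, len = lens)
}

#' Verify a cfDNA/WBC sample pairing from SNP genotypes
#'
#' Discretizes per-SNP allele fractions into genotypes (hom-ref below 0.15,
#' het between 0.15 and 0.85 inclusive, hom-alt above 0.85) and reports the
#' fraction of concordant genotype calls across usable SNP sites. A pairing
#' passes at concordance >= `min_concordance`; with fewer than `min_snps`
#' usable sites the verdict is `"indeterminate"`, never `"fail"`.
#'
#' @param cfdna_af,wbc_af numeric vectors of per-SNP allele fractions for
#'   the same SNP sites in the two samples.
#' @param cfdna_depth,wbc_depth optional per-site depths; sites with depth
#'   below `min_depth` in either sample are excluded.
#' @param min_snps minimum usable SNP count (default 20).
#' @param min_depth per-site depth requirement (default 20).
#' @param min_concordance pass threshold (default 0.90).
#' @return list with `concordance`, `n_snps` (usable sites) and `verdict`
#'   in `"pass"`, `"fail"`, `"indeterminate"`.
#' @export
verify_pairing <- function(cfdna_af, wbc_af,
                           cfdna_depth = NULL, wbc_depth = NULL,
                           min_snps = 20, min_depth = 20,
                           min_concordance = 0.90) {
  stopifnot(length(cfdna_af) == length(wbc_af))
  usable <- !is.na(cfdna_af) & !is.na(wbc_af)
  if (!is.null(cfdna_depth)) usable <- usable & cfdna_depth >= min_depth
  if (!is.null(wbc_depth)) usable <- usable & wbc_depth >= min_depth
  gt <- function(af) findInterval(af, c(0.15, 0.85 + 1e-12))  # 0/1/2
  cf <- gt(cfdna_af[usable])
  wb <- gt(wbc_af[usable])
  n <- length(cf)
  if (n < min_snps) {
    return(list(concordance = NA_real_, n_snps = n,
                verdict = "indeterminate"))
  }
  conc <- mean(cf == wb)
  list(concordance = conc, n_snps = n,
       verdict = if (conc >= min_concordance) "pass" else "fail")
}
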