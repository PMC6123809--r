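# Statistical layer: exact tests, ctDNA-corrected allele fractions and
# longitudinal clone tracking.

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric enumeration, computed in log space for stability.
#' Two conventions for the two-sided p-value are provided, because exact
#' 2x2 tests admit more than one standard definition and published values
#' may follow either:
#'
#' * `"minlike"` (default): the sum of probabilities of all tables with the
#'   observed margins whose hypergeometric probability does not exceed that
#'   of the observed table (probability-mass ordering; the definition used
#'   by [stats::fisher.test()]).
#' * `"central"`: twice the smaller one-sided tail, capped at 1.
#'
#' @param table 2x2 matrix of non-negative counts (rows = groups,
#'   columns = outcome / non-outcome), or a length-4 vector `c(a, b, c, d)`
#'   filled by row.
#' @param method two-sided convention, `"minlike"` or `"central"`.
#' @return Two-sided p-value (numeric scalar).
#' @examples
#' fisher_exact(matrix(c(30, 7, 19, 122), 2, byrow = TRUE))
#' @export
fisher_exact <- function(table, method = c("minlike", "central")) {
  method <- match.arg(method)
  if (!is.matrix(table)) table <- matrix(as.numeric(table), 2, 2, byrow = TRUE)
  stopifnot(all(dim(table) == 2), all(table >= 0), all(table == round(table)))
  a <- table[1, 1]; b <- table[1, 2]; c_ <- table[2, 1]; d <- table[2, 2]
  m <- a + b          # row 1 margin (draws)
  k <- a + c_         # column 1 margin (white balls)
  n <- a + b + c_ + d
  if (m == 0 || k == 0 || m == n || k == n) {
    stop("fisher_exact: a table margin is empty; the test is undefined")
  }
  support <- max(0, m + k - n):min(m, k)
  logp <- dhyper(support, k, n - k, m, log = TRUE)
  obs <- logp[match(a, support)]
  if (method == "minlike") {
    # relative tolerance guards against ties broken by floating-point noise
    sum(exp(logp[logp <= obs + 1e-7]))
  } else {
    lower <- sum(exp(logp[support <= a]))
    upper <- sum(exp(logp[support >= a]))
    min(1, 2 * min(lower, upper))
  }
}

#' Exact two-sided binomial comparison of two mutation rates
#'
#' Conditional on the total count `n = count1 + count2`, `count1` is
#' Binomial(n, e1 / (e1 + e2)) under the null hypothesis of equal rates,
#' where `e1`, `e2` are the exposures (e.g. megabase-samples of covered
#' territory). The two-sided p-value sums all outcome probabilities not
#' exceeding that of the observed count (the definition used by
#' [stats::binom.test()]).
#'
#' @param count1,count2 observed mutation counts in the two regions.
#' @param exposure1,exposure2 positive exposures for the two regions.
#' @return Two-sided p-value. If both counts are zero, returns 1 (with a
#'   `"note"` attribute).
#' @export
binomial_rate_test <- function(count1, exposure1, count2, exposure2) {
  stopifnot(exposure1 > 0, exposure2 > 0, count1 >= 0, count2 >= 0)
  n <- count1 + count2
  if (n == 0) {
    return(structure(1, note = "no events observed; test uninformative"))
  }
  p0 <- exposure1 / (exposure1 + exposure2)
  logp <- dbinom(0:n, n, p0, log = TRUE)
  obs <- logp[count1 + 1L]
  sum(exp(logp[logp <= obs + 1e-7]))
}

#' Wilcoxon rank-sum test (two-sided)
#'
#' Mid-rank tie handling. For small samples (both sizes <= 20, no ties) the
#' exact null distribution is enumerated; otherwise the normal approximation
#' with continuity correction is used. Delegates to [stats::wilcox.test()],
#' which implements both regimes.
#'
#' @param x,y non-empty numeric vectors.
#' @return Two-sided p-value.
#' @export
ranksum_test <- function(x, y) {
  stopifnot(length(x) > 0, length(y) > 0)
  if (length(unique(c(x, y))) == 1L) return(1)  # degenerate: all identical
  exact <- max(length(x), length(y)) <= 20 && !any(duplicated(c(x, y)))
  suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided",
                exact = exact, correct = TRUE)$p.value
  )
}

#' ctDNA-fraction-corrected allele fraction
#'
#' Rescales a raw somatic allele fraction by the sample's ctDNA fraction so
#' that a clonal heterozygous mutation maps to ~0.5 regardless of tumor
#' content; values above 0.5 indicate loss of heterozygosity or
#' amplification of the mutant allele. With `convention = "diploid"` the
#' fraction is instead divided by ctdna/2, mapping a clonal heterozygous
#' mutation to ~1.
#'
#' Samples at or below the ctDNA floor are suppressed (`NA`), mirroring the
#' ctDNA-positivity gate applied throughout the cohort statistics.
#'
#' @param raw_af raw allele fraction(s) in \[0, 1\].
#' @param ctdna_fraction ctDNA fraction(s) in \[0, 1\], recycled.
#' @param floor minimum ctDNA fraction for a usable estimate (default 0.02).
#' @param convention `"half"` (default, clonal het -> 0.5) or `"diploid"`
#'   (clonal het -> 1).
#' @return Numeric vector of corrected allele fractions (NA where
#'   suppressed).
#' @export
corrected_af <- function(raw_af, ctdna_fraction, floor = 0.02,
                         convention = c("half", "diploid")) {
  convention <- match.arg(convention)
  stopifnot(all(raw_af >= 0 & raw_af <= 1, na.rm = TRUE))
  denom <- if (convention == "half") ctdna_fraction else ctdna_fraction / 2
  out <- raw_af / denom
  out[ctdna_fraction <= floor] <- NA_real_
  out
}

#' Track mutation clones across longitudinal cfDNA timepoints
#'
#' Classifies each (patient, mutation) pair over its ctDNA-positive
#' timepoints. A mutation is *detected* at a timepoint if it was called
#' there; *absent* if zero supporting reads were observed with depth >= 200
#' (so low coverage is never miscalled as clone loss); and *indeterminate*
#' otherwise (1-9 supporting reads, or insufficient depth).
#'
#' Classification per trajectory: `persistent` (detected at every eligible
#' timepoint), `late_rising` (absent early, detected later), `lost`
#' (detected, then absent later), `indeterminate` otherwise. Patients with
#' fewer than two eligible timepoints are excluded.
#'
#' @param calls data.frame with columns `patient`, `timepoint` (orderable),
#'   `key` (mutation identity), `detected` (logical), `supporting_reads`,
#'   `depth`, `ctdna_fraction`, and optionally `corrected_af`.
#' @param min_ctdna minimum ctDNA fraction for an eligible timepoint
#'   (default 0.05).
#' @param min_absent_depth depth required to score an absence (default 200).
#' @return data.frame with one row per (patient, mutation):
#'   `patient`, `key`, `n_timepoints`, `n_detected`, `classification`.
#' @export
track_clones <- function(calls, min_ctdna = 0.05, min_absent_depth = 200) {
  need <- c("patient", "timepoint", "key", "detected", "supporting_reads",
            "depth", "ctdna_fraction")
  stopifnot(all(need %in% names(calls)))
  eligible <- calls[calls$ctdna_fraction > min_ctdna, , drop = FALSE]
  out <- list()
  for (pat in unique(eligible$patient)) {
    pc <- eligible[eligible$patient == pat, , drop = FALSE]
    tps <- sort(unique(pc$timepoint))
    if (length(tps) < 2L) next
    for (k in unique(pc$key)) {
      kc <- pc[pc$key == k, , drop = FALSE]
      status <- vapply(tps, function(tp) {
        row <- kc[kc$timepoint == tp, , drop = FALSE]
        if (nrow(row) == 0L) return("indeterminate")  # no observation record
        if (any(row$detected)) return("detected")
        if (max(row$supporting_reads) == 0 && max(row$depth) >= min_absent_depth)
          return("absent")
        "indeterminate"
      }, character(1))
      det <- which(status == "detected")
      abs_ <- which(status == "absent")
      cls <- if (length(det) == length(tps)) {
        "persistent"
      } else if (length(det) > 0 && length(abs_) > 0 &&
                 min(abs_) < min(det) && max(det) > max(abs_)) {
        "late_rising"
      } else if (length(det) > 0 && length(abs_) > 0 &&
                 max(abs_) > max(det)) {
        "lost"
      } else {
        "indeterminate"
      }
      out[[length(out) + 1L]] <- data.frame(
        patient = pat, key = k, n_timepoints = length(tps),
        n_detected = length(det), classification = cls,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(patient = character(0), key = character(0),
                      n_timepoints = integer(0), n_detected = integer(0),
                      classification = character(0)))
  }
  do.call(rbind, out)
}
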