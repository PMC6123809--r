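# Independent oracles and small fixture builders shared across tests.

# Two-sided Fisher p by central doubling, computed independently of the
# package via cumulative hypergeometric tails.
central_fisher_oracle <- function(a, b, c_, d) {
  m <- a + b; k <- a + c_; n <- a + b + c_ + d
  lower <- phyper(a, k, n - k, m)
  upper <- phyper(a - 1, k, n - k, m, lower.tail = FALSE)
  min(1, 2 * min(lower, upper))
}

# Brute-force two-sided binomial p by direct summation.
binom_two_sided_oracle <- function(x, n, p) {
  probs <- dbinom(0:n, n, p)
  sum(probs[probs <= probs[x + 1] * (1 + 1e-7)])
}

# Brute-force application of the five caller inequalities to one
# candidate.
five_filter_oracle <- function(af, alt_reads, bg_af, wbc_af, wbc_depth,
                               min_af = 0.01, min_reads = 10,
                               bg_ratio = 25, wbc_ratio = 3,
                               min_wbc_depth = 20) {
  af >= min_af && alt_reads >= min_reads && af >= bg_ratio * bg_af &&
    af >= wbc_ratio * wbc_af && wbc_depth >= min_wbc_depth
}

random_dna_test <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Minimal pileup constructor for hand-built columns on a single contig.
mk_pileup <- function(ref_seq, depth, alleles = NULL,
                      chrom = "ctg", sample_id = "S") {
  n <- nchar(ref_seq)
  stopifnot(length(depth) == n)
  sites <- data.frame(chrom = chrom, pos = seq_len(n) - 1L,
                      ref = strsplit(ref_seq, "")[[1]], depth = depth,
                      stringsAsFactors = FALSE)
  if (is.null(alleles)) {
    alleles <- data.frame(chrom = character(0), pos = integer(0),
                          ref = character(0), alt = character(0),
                          count = integer(0))
  }
  structure(list(sample_id = sample_id, sites = sites, alleles = alleles),
            class = "pileup")
}

# A small standard cohort used by several integration tests.
small_cohort <- function(seed = 11, n_patients = 12, ...) {
  simulate_cohort(sim_config(
    seed = seed, n_genes = 5, n_patients = n_patients,
    ctdna_fractions = rep(0.35, n_patients),
    somatic_spec = standard_somatic_spec(), ...))
}
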