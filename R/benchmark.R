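# Sensitivity benchmark for the five-condition caller under the emulated
# study conditions.

#' Benchmark caller sensitivity on planted clonal variants
#'
#' Simulates `n_sites` independent panel positions each carrying one
#' planted somatic substitution at an allele fraction drawn uniformly from
#' `af_range`, with per-position depth Poisson(`depth_mean`) and i.i.d.
#' per-base substitution error in both channels; the paired WBC sample and
#' a WBC background cohort of `n_background` samples carry error only.
#' Runs [build_background()] and [call_somatic()] at the standard
#' thresholds and reports the fraction of planted variants called.
#'
#' @param n_sites number of planted sites (default 500).
#' @param depth_mean mean depth (default 751).
#' @param af_range allele-fraction range of the planted variants (default
#'   0.035-0.05).
#' @param per_base_error substitution error rate (default 0.001).
#' @param n_background WBC background cohort size (default 20).
#' @param seed RNG seed.
#' @param ... thresholds passed to [call_somatic()].
#' @return list with `sensitivity` (fraction), `n_sites`, `n_called`, and
#'   the per-site `detail` data.frame.
#' @export
simulate_caller_benchmark <- function(n_sites = 500, depth_mean = 751,
                                      af_range = c(0.035, 0.05),
                                      per_base_error = 0.001,
                                      n_background = 20, seed = 1, ...) {
  set.seed(seed)
  ref <- random_dna(n_sites)
  ref_b <- strsplit(ref, "")[[1]]
  alt_b <- vapply(ref_b, function(b) sample(setdiff(BASES, b), 1),
                  character(1), USE.NAMES = FALSE)
  af <- runif(n_sites, af_range[1], af_range[2])
  reference <- c(sites = ref)

  error_pileup <- function(id) {
    depth <- rpois(n_sites, depth_mean)
    e <- rbinom(n_sites, depth, per_base_error)
    idx <- which(e > 0)
    alleles <- if (length(idx)) {
      do.call(rbind, lapply(idx, function(i) {
        picks <- table(sample(setdiff(BASES, ref_b[i]), e[i],
                              replace = TRUE))
        data.frame(chrom = "sites", pos = i - 1L, ref = ref_b[i],
                   alt = names(picks), count = as.integer(picks),
                   stringsAsFactors = FALSE)
      }))
    } else {
      data.frame(chrom = character(0), pos = integer(0),
                 ref = character(0), alt = character(0),
                 count = integer(0))
    }
    structure(list(sample_id = id,
                   sites = data.frame(chrom = "sites",
                                      pos = seq_len(n_sites) - 1L,
                                      ref = ref_b, depth = depth,
                                      stringsAsFactors = FALSE),
                   alleles = alleles), class = "pileup")
  }

  wbc_cohort <- lapply(seq_len(n_background), function(i)
    error_pileup(paste0("BG", i)))
  bg <- build_background(wbc_cohort)
  wbc <- error_pileup("WBC")

  cf <- error_pileup("CF")
  somatic <- rbinom(n_sites, cf$sites$depth, af)
  planted <- data.frame(chrom = "sites", pos = seq_len(n_sites) - 1L,
                        ref = ref_b, alt = alt_b, count = somatic,
                        stringsAsFactors = FALSE)
  al <- rbind(cf$alleles, planted[planted$count > 0, ])
  k <- allele_key(al$chrom, al$pos, al$ref, al$alt)
  first <- !duplicated(k)
  agg <- rowsum(al$count, k)
  al <- al[first, , drop = FALSE]
  al$count <- as.integer(agg[match(k[first], rownames(agg)), 1])
  cf$alleles <- al

  calls <- call_somatic(cf, wbc, bg, ...)
  called_key <- allele_key(calls$chrom, calls$pos, calls$ref, calls$alt)
  truth_key <- allele_key(planted$chrom, planted$pos, planted$ref,
                          planted$alt)
  hit <- truth_key %in% called_key
  list(sensitivity = mean(hit), n_sites = n_sites, n_called = sum(hit),
       detail = data.frame(pos = planted$pos, af = af,
                           alt_reads = planted$count, called = hit))
}
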