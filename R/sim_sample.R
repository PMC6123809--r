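# Deterministic per-sample materialization of the simulated cohort.
# Every sample has its own RNG seed drawn once at cohort construction, so
# any sample can be regenerated independently and identically (and the
# same WBC sample is bit-identical whether visited during background
# estimation or paired calling).

contig_offsets <- function(reference) {
  lens <- nchar(reference)
  setNames(c(0, cumsum(lens))[seq_along(lens)], names(reference))
}

# Events carried by a sample's pileup (SNVs and indels below the
# large-indel routing threshold present at this timepoint).
sample_pileup_events <- function(sim, info) {
  ev <- sim$events
  if (nrow(ev) == 0 || info$type != "cfDNA") return(ev[0, ])
  keep <- ev$patient == info$patient & ev$timepoint_from <= info$timepoint &
    (ev$type == "SNV" | ev$length < sim$config$large_indel_min)
  ev[keep, , drop = FALSE]
}

# Events routed to the split-read caller for this sample.
sample_large_events <- function(sim, info) {
  ev <- sim$events
  if (nrow(ev) == 0 || info$type != "cfDNA") return(ev[0, ])
  keep <- ev$patient == info$patient & ev$timepoint_from <= info$timepoint &
    ev$type != "SNV" & ev$length >= sim$config$large_indel_min
  ev[keep, , drop = FALSE]
}

#' Materialize the pileup of one simulated sample
#'
#' Per-position depth is Poisson around the panel mean; substitution errors
#' are i.i.d. per read base and uniformly assigned to the three non-reference
#' bases; germline heterozygous SNPs are sampled at allele fraction 0.5 in
#' both the cfDNA and WBC channels; planted somatic events (below the
#' large-indel routing threshold) are sampled at allele fraction
#' `ctdna_fraction * clonality / 2` in the cfDNA channel only; the WBC
#' channel additionally carries spurious 1 bp indels at the configured
#' noise rate.
#'
#' @param sim a `cfdna_cohort` from [simulate_cohort()].
#' @param sample_id sample identifier from `sim$samples`.
#' @return A `pileup` object: list with `sample_id`, `sites` (data.frame
#'   `chrom`, `pos`, `ref`, `depth` covering every panel position) and
#'   `alleles` (data.frame `chrom`, `pos`, `ref`, `alt`, `count` of
#'   non-reference observations, normalized representation).
#' @export
sim_pileup <- function(sim, sample_id) {
  stopifnot(inherits(sim, "cfdna_cohort"))
  info <- sim$samples[match(sample_id, sim$samples$sample_id), ]
  if (is.na(info$seed)) stop("unknown sample_id: ", sample_id)
  cfg <- sim$config
  set.seed(info$seed)

  chroms <- names(sim$reference)
  lens <- nchar(sim$reference)
  n <- sum(lens)
  chrom_col <- rep(chroms, lens)
  pos_col <- unlist(lapply(lens, function(L) seq_len(L) - 1L),
                    use.names = FALSE)
  ref_col <- unlist(strsplit(paste(sim$reference, collapse = ""), ""),
                    use.names = FALSE)
  offs <- contig_offsets(sim$reference)

  depth <- rpois(n, cfg$panel_depth_mean)

  # substitution errors, uniformly over the three non-reference bases
  e <- rbinom(n, depth, cfg$per_base_error)
  gi <- rep(which(e > 0L), e[e > 0L])
  alt_slot <- sample.int(3L, length(gi), replace = TRUE)
  nonref <- rbind(c("C", "G", "T"), c("A", "G", "T"),
                  c("A", "C", "T"), c("A", "C", "G"))  # rows follow BASES
  key <- gi * 4 + alt_slot
  uk <- sort(unique(key))
  cnt <- tabulate(match(key, uk))
  gi_u <- uk %/% 4
  slot_u <- uk %% 4
  alleles <- data.frame(
    chrom = chrom_col[gi_u], pos = pos_col[gi_u], ref = ref_col[gi_u],
    alt = nonref[cbind(match(ref_col[gi_u], BASES), slot_u)], count = cnt,
    stringsAsFactors = FALSE)

  # germline heterozygous SNPs (both channels)
  germ <- sim$germline[sim$germline$patient == info$patient, , drop = FALSE]
  if (nrow(germ) > 0) {
    g_gi <- offs[germ$chrom] + germ$pos + 1L
    gc <- rbinom(nrow(germ), depth[g_gi], 0.5)
    alleles <- rbind(alleles, data.frame(
      chrom = germ$chrom, pos = germ$pos, ref = germ$ref, alt = germ$alt,
      count = gc, stringsAsFactors = FALSE))
  }

  # planted somatic events (cfDNA only)
  ev <- sample_pileup_events(sim, info)
  if (nrow(ev) > 0) {
    s_gi <- offs[ev$chrom] + ev$pos + 1L
    af <- info$ctdna_fraction * ev$clonality / 2
    sc <- rbinom(nrow(ev), depth[s_gi], af)
    alleles <- rbind(alleles, data.frame(
      chrom = ev$chrom, pos = ev$pos, ref = ev$ref, alt = ev$alt,
      count = sc, stringsAsFactors = FALSE))
  }

  # WBC channel: spurious short indels at the configured noise rate
  if (info$type == "WBC" && cfg$wbc_indel_noise > 0) {
    ne <- rbinom(n, depth, cfg$wbc_indel_noise)
    idx <- which(ne > 0L & pos_col < rep(lens, lens) - 1L)
    if (length(idx) > 0) {
      alleles <- rbind(alleles, data.frame(
        chrom = chrom_col[idx], pos = pos_col[idx],
        ref = paste0(ref_col[idx], ref_col[idx + 1L]), alt = ref_col[idx],
        count = ne[idx], stringsAsFactors = FALSE))
    }
  }

  alleles <- alleles[alleles$count > 0L, , drop = FALSE]
  if (nrow(alleles) > 0) {
    # aggregate identical alleles and enforce count sums <= depth
    k <- allele_key(alleles$chrom, alleles$pos, alleles$ref, alleles$alt)
    agg <- rowsum(alleles$count, k)
    first <- !duplicated(k)
    alleles <- alleles[first, , drop = FALSE]
    alleles$count <- as.integer(agg[match(k[first], rownames(agg)), 1])
    a_gi <- offs[alleles$chrom] + alleles$pos + 1L
    tot <- rowsum(alleles$count, a_gi)
    over <- as.integer(tot[match(a_gi, rownames(tot)), 1]) - depth[a_gi]
    excess <- pmax(over, 0L)
    alleles$count <- pmax(alleles$count - excess, 0L)
    alleles <- alleles[alleles$count > 0L, , drop = FALSE]
    alleles <- alleles[order(match(alleles$chrom, chroms), alleles$pos,
                             alleles$alt), , drop = FALSE]
    rownames(alleles) <- NULL
  }

  structure(list(sample_id = sample_id,
                 sites = data.frame(chrom = chrom_col, pos = pos_col,
                                    ref = ref_col, depth = depth,
                                    stringsAsFactors = FALSE),
                 alleles = alleles),
            class = "pileup")
}

#' Materialize unaligned junction reads for a sample's large indels
#'
#' Reads whose alignment would cross a planted large-indel junction are the
#' entry point of the split-read caller. For every planted event of length
#' at or above the routing threshold, junction-spanning reads are drawn
#' from the donor haplotype at the event's expected allele fraction, with
#' distinct start positions (deduplicated fragments).
#'
#' @param sim a `cfdna_cohort`.
#' @param sample_id cfDNA sample identifier.
#' @return data.frame of unaligned reads: `read_id`, `seq`, `qual`, plus
#'   `truth_event` linking back to the planted event.
#' @export
sim_unaligned_reads <- function(sim, sample_id) {
  stopifnot(inherits(sim, "cfdna_cohort"))
  info <- sim$samples[match(sample_id, sim$samples$sample_id), ]
  if (is.na(info$seed)) stop("unknown sample_id: ", sample_id)
  cfg <- sim$config
  set.seed(info$seed + 1L)
  ev <- sample_large_events(sim, info)
  out <- list()
  rl <- cfg$read_len
  al <- cfg$anchor_len
  for (i in seq_len(nrow(ev))) {
    e <- ev[i, ]
    ref_seq <- sim$reference[[e$chrom]]
    jd <- e$pos + 1L  # junction: first base after the shared anchor
    if (e$type == "del") {
      hap <- paste0(substr(ref_seq, 1, jd),
                    substr(ref_seq, jd + e$length + 1L, nchar(ref_seq)))
    } else {
      ins <- substr(e$alt, 2L, nchar(e$alt))
      hap <- paste0(substr(ref_seq, 1, jd), ins,
                    substr(ref_seq, jd + 1L, nchar(ref_seq)))
    }
    af <- info$ctdna_fraction * e$clonality / 2
    # the discordant junction is where donor and reference diverge; for a
    # left-aligned tandem duplication the inserted copy matches the
    # reference in place, pushing the junction to the end of the copy
    m <- 0L
    max_scan <- min(nchar(hap) - jd, e$length + 2L * al)
    while (m < max_scan &&
           substr(hap, jd + m + 1L, jd + m + 1L) ==
           substr(ref_seq, jd + m + 1L, jd + m + 1L)) {
      m <- m + 1L
    }
    jd <- jd + m
    window <- (jd - (rl - al)):(jd - al)  # donor starts spanning junction
    window <- window[window >= 0 & window + rl <= nchar(hap)]
    n_slots <- max(1L, round(length(window) * cfg$panel_depth_mean / rl))
    n_reads <- rbinom(1, n_slots, af)
    n_reads <- min(n_reads, length(window))
    if (n_reads == 0) next
    starts <- sort(sample(window, n_reads))
    seqs <- substring(hap, starts + 1L, starts + rl)
    # per-base substitution errors
    seqs <- vapply(seqs, function(s) {
      hit <- which(runif(rl) < cfg$per_base_error)
      for (h in hit) {
        substr(s, h, h) <- sample(setdiff(BASES, substr(s, h, h)), 1)
      }
      s
    }, character(1), USE.NAMES = FALSE)
    out[[length(out) + 1L]] <- data.frame(
      read_id = sprintf("%s_%s_j%03d", sample_id, e$event_id,
                        seq_len(n_reads)),
      seq = seqs, qual = strrep(rawToChar(as.raw(37 + 33)), rl),
      truth_event = e$event_id, stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(read_id = character(0), seq = character(0),
                      qual = character(0), truth_event = character(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
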