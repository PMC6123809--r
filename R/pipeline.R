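# End-to-end orchestration: cohort simulation or input, background model,
# per-patient somatic calling (pileup channel + split-read channel),
# region annotation, and cohort-level summary tables.

#' Run the full analysis pipeline on a simulated cohort
#'
#' Streams the cohort patient by patient: builds the WBC-cohort background
#' model, calls somatic mutations in every cfDNA sample against its paired
#' WBC sample (five-condition caller on the pileup channel; split-read
#' caller on unaligned junction reads for large indels), annotates calls
#' with gene, region class and coding consequence, computes
#' ctDNA-corrected allele fractions, and assembles the cohort table plus
#' summary reports. A patient without a WBC sample is skipped with an
#' explicit log entry; the run continues. Deterministic given the
#' configuration.
#'
#' @param config a [sim_config()] (or an already-built `cfdna_cohort`).
#' @param min_af,min_reads,bg_ratio,wbc_ratio,min_wbc_depth caller
#'   thresholds, see [call_somatic()].
#' @param depth_floor coverage floor for rate denominators (default 200).
#' @param ctdna_floor ctDNA-positivity gate (default 0.02).
#' @return An object of class `utrscan_report`: list with `table` (the
#'   cohort table: one row per variant x sample), `summary` (per
#'   gene x region counts, rates, patient percentages), `indel_fraction`
#'   (per gene x region indel fractions and the hypermutated-gene contrast
#'   with its Fisher p), `trajectories` (clone tracking), `samples`,
#'   `truth` (planted truth set) and `logs` (filter decision counters).
#' @export
run_pipeline <- function(config, min_af = 0.01, min_reads = 10,
                         bg_ratio = 25, wbc_ratio = 3, min_wbc_depth = 20,
                         depth_floor = 200, ctdna_floor = 0.02) {
  sim <- if (inherits(config, "cfdna_cohort")) config else
    simulate_cohort(config)
  cfg <- sim$config
  samples <- sim$samples
  logs <- list(skipped_patients = character(0),
               candidates = 0L,
               fail_af = 0L, fail_support = 0L, fail_background = 0L,
               fail_wbc_ratio = 0L, fail_wbc_depth = 0L, pass = 0L)

  bg <- build_background(sim)

  cf_samples <- samples[samples$type == "cfDNA", , drop = FALSE]
  eligible <- cf_samples$ctdna_fraction > ctdna_floor
  depth_sum <- numeric(bg$n_positions)
  n_depth_samples <- 0L

  rows <- list()
  traj_rows <- list()
  for (pat in unique(cf_samples$patient)) {
    wbc_id <- samples$sample_id[samples$patient == pat &
                                samples$type == "WBC"]
    if (length(wbc_id) == 0) {
      logs$skipped_patients <- c(logs$skipped_patients, pat)
      next
    }
    wbc <- sim_pileup(sim, wbc_id[1])
    pat_cf <- cf_samples[cf_samples$patient == pat, , drop = FALSE]
    pat_pileups <- list()
    pat_calls <- list()
    for (si in seq_len(nrow(pat_cf))) {
      s <- pat_cf[si, ]
      cf <- sim_pileup(sim, s$sample_id)
      pat_pileups[[s$sample_id]] <- cf
      if (s$ctdna_fraction > ctdna_floor) {
        depth_sum <- depth_sum + cf$sites$depth
        n_depth_samples <- n_depth_samples + 1L
      }
      audit <- call_somatic(cf, wbc, bg, min_af = min_af,
                            min_reads = min_reads, bg_ratio = bg_ratio,
                            wbc_ratio = wbc_ratio,
                            min_wbc_depth = min_wbc_depth,
                            keep_filtered = TRUE)
      logs$candidates <- logs$candidates + nrow(audit)
      logs$fail_af <- logs$fail_af + sum(!audit$flag_af)
      logs$fail_support <- logs$fail_support + sum(!audit$flag_support)
      logs$fail_background <- logs$fail_background +
        sum(!audit$flag_background)
      logs$fail_wbc_ratio <- logs$fail_wbc_ratio +
        sum(!audit$flag_wbc_ratio)
      logs$fail_wbc_depth <- logs$fail_wbc_depth +
        sum(!audit$flag_wbc_depth)
      calls <- audit[audit$pass, , drop = FALSE]
      logs$pass <- logs$pass + nrow(calls)
      calls$source <- rep("pileup", nrow(calls))
      # split-read channel for large indels
      ur <- sim_unaligned_reads(sim, s$sample_id)
      if (nrow(ur) > 0) {
        evs <- detect_large_indels(ur, sim$reference,
                                   anchor_len = cfg$anchor_len)
        for (ei in seq_len(nrow(evs))) {
          e <- evs[ei, ]
          chrom_seq <- sim$reference[[e$chrom]]
          anchor <- substr(chrom_seq, e$left_bp, e$left_bp)
          if (e$type == "deletion") {
            ref <- paste0(anchor, e$seq); alt <- anchor
          } else {
            ref <- anchor; alt <- paste0(anchor, e$seq)
          }
          nrm <- normalize_allele(chrom_seq, e$left_bp - 1L, ref, alt)
          dp <- cf$sites$depth[cf$sites$chrom == e$chrom &
                               cf$sites$pos == nrm$pos]
          dp <- if (length(dp)) dp[1] else NA_integer_
          # AF from junction evidence: unique fragments over the expected
          # number of junction-spanning read slots at this depth
          slots <- max(1, round((cfg$read_len - 2 * cfg$anchor_len + 1) *
                                dp / cfg$read_len))
          calls <- rbind(calls, data.frame(
            chrom = e$chrom, pos = nrm$pos, ref = nrm$ref, alt = nrm$alt,
            alt_reads = e$unique_fragments, depth = dp,
            af = min(1, e$unique_fragments / slots),
            background_af = NA_real_,
            wbc_af = NA_real_, wbc_depth = NA_integer_,
            flag_af = NA, flag_support = NA, flag_background = NA,
            flag_wbc_ratio = NA, flag_wbc_depth = NA, pass = TRUE,
            source = "split_read", stringsAsFactors = FALSE))
        }
      }
      if (nrow(calls) == 0) next
      ann <- annotate_calls(calls, sim)
      ann$sample_id <- s$sample_id
      ann$patient <- pat
      ann$timepoint <- s$timepoint
      ann$ctdna_fraction <- s$ctdna_fraction
      ann$corrected_af <- corrected_af(pmin(ann$af, 1), s$ctdna_fraction,
                                       floor = ctdna_floor)
      pat_calls[[s$sample_id]] <- ann
      rows[[length(rows) + 1L]] <- ann
    }
    # longitudinal clone records: every key called in >= 1 timepoint,
    # observed (or scored absent) at every timepoint of the patient
    if (nrow(pat_cf) >= 2 && length(pat_calls) > 0) {
      all_calls <- do.call(rbind, pat_calls)
      for (k in unique(all_calls$key)) {
        k1 <- all_calls[all_calls$key == k, ][1, ]
        for (si in seq_len(nrow(pat_cf))) {
          s <- pat_cf[si, ]
          called <- k %in% (pat_calls[[s$sample_id]]$key %||% character(0))
          p <- pat_pileups[[s$sample_id]]
          dp <- p$sites$depth[p$sites$chrom == k1$chrom &
                              p$sites$pos == k1$pos]
          cnt <- p$alleles$count[p$alleles$chrom == k1$chrom &
                                 p$alleles$pos == k1$pos &
                                 p$alleles$ref == k1$ref &
                                 p$alleles$alt == k1$alt]
          cnt <- if (length(cnt)) cnt[1] else
            if (k1$source == "split_read" && called) k1$alt_reads else 0L
          traj_rows[[length(traj_rows) + 1L]] <- data.frame(
            patient = pat, timepoint = s$timepoint, key = k,
            detected = called, supporting_reads = cnt,
            depth = if (length(dp)) dp[1] else 0L,
            ctdna_fraction = s$ctdna_fraction, stringsAsFactors = FALSE)
        }
      }
    }
  }

  table <- if (length(rows)) do.call(rbind, rows) else empty_cohort_table()
  rownames(table) <- NULL
  depth_track <- data.frame(
    chrom = bg_sites_chrom(sim), pos = bg_sites_pos(sim),
    depth = if (n_depth_samples > 0) depth_sum / n_depth_samples else 0)
  summary <- summarize_by_gene_region(table, samples,
                                      region_table(sim), depth_track,
                                      depth_floor = depth_floor,
                                      ctdna_floor = ctdna_floor)
  indel_fraction <- indel_fraction_tables(table, samples, cfg,
                                          ctdna_floor)
  trajectories <- if (length(traj_rows)) {
    track_clones(do.call(rbind, traj_rows))
  } else {
    track_clones(data.frame(patient = character(0),
                            timepoint = integer(0), key = character(0),
                            detected = logical(0),
                            supporting_reads = integer(0),
                            depth = integer(0),
                            ctdna_fraction = numeric(0)))
  }
  structure(list(table = table, summary = summary,
                 indel_fraction = indel_fraction,
                 trajectories = trajectories, samples = samples,
                 truth = truth_set(sim), depth_track = depth_track,
                 logs = logs),
            class = "utrscan_report")
}

empty_cohort_table <- function() {
  data.frame(chrom = character(0), pos = integer(0), ref = character(0),
             alt = character(0), alt_reads = integer(0),
             depth = integer(0), af = numeric(0),
             background_af = numeric(0), wbc_af = numeric(0),
             wbc_depth = integer(0), flag_af = logical(0),
             flag_support = logical(0), flag_background = logical(0),
             flag_wbc_ratio = logical(0), flag_wbc_depth = logical(0),
             pass = logical(0), source = character(0),
             gene = character(0), region = character(0),
             consequence = character(0), type = character(0),
             length = integer(0), key = character(0),
             sample_id = character(0), patient = character(0),
             timepoint = integer(0), ctdna_fraction = numeric(0),
             corrected_af = numeric(0))
}

bg_sites_chrom <- function(sim) {
  rep(names(sim$reference), nchar(sim$reference))
}
bg_sites_pos <- function(sim) {
  unlist(lapply(nchar(sim$reference), function(L) seq_len(L) - 1L),
         use.names = FALSE)
}

# Gene x region interval table for summaries.
region_table <- function(sim) {
  do.call(rbind, lapply(names(sim$regions), function(g) {
    r <- sim$regions[[g]]
    data.frame(gene = g, chrom = g,
               region = c("UTR5", "CDS", "UTR3"),
               start = c(r$UTR5[1], r$CDS[1], r$UTR3[1]),
               end = c(r$UTR5[2], r$CDS[2], r$UTR3[2]),
               stringsAsFactors = FALSE)
  }))
}

# Annotate calls with gene, region class, consequence, type, length, key.
annotate_calls <- function(calls, sim) {
  out <- list()
  for (i in seq_len(nrow(calls))) {
    cl <- calls[i, , drop = FALSE]
    span_end <- cl$pos + max(nchar(cl$ref), 1L)
    hits <- classify_variant(cl$chrom, cl$pos, span_end, sim$models)
    for (hi in seq_len(nrow(hits))) {
      row <- cl
      row$gene <- hits$gene[hi]
      row$region <- hits$region[hi]
      row$consequence <- if (is.na(hits$gene[hi])) "intergenic" else {
        model <- sim$models[[match(hits$gene[hi],
                                   vapply(sim$models, `[[`, character(1),
                                          "gene"))]]
        consequence(cl$chrom, cl$pos, cl$ref, cl$alt, model,
                    sim$reference)
      }
      row$type <- allele_type(cl$ref, cl$alt)
      row$length <- allele_length(cl$ref, cl$alt)
      row$key <- allele_key(cl$chrom, cl$pos, cl$ref, cl$alt)
      out[[length(out) + 1L]] <- row
    }
  }
  do.call(rbind, out)
}

#' Summarize a cohort table by gene and region
#'
#' Counts (by gene, region and mutation type), coverage-normalized
#' mutation rates (via [mutation_rate()], pooled mean-depth track), and
#' patient-level prevalence: the fraction of eligible (ctDNA-positive)
#' patients carrying at least one qualifying mutation per gene x region. A
#' mutation observed at multiple timepoints of one patient counts once
#' (identity = chrom:pos:ref>alt after normalization).
#'
#' @param table cohort table from [run_pipeline()].
#' @param samples sample metadata data.frame.
#' @param regions gene x region interval table (`gene`, `chrom`,
#'   `region`, `start`, `end`).
#' @param depth_track pooled per-position depth data.frame (`chrom`,
#'   `pos`, `depth`).
#' @param depth_floor,ctdna_floor see [mutation_rate()].
#' @return data.frame with one row per gene x region: `n_mutations`
#'   (unique patient-mutations), `n_indels`, `n_substitutions`,
#'   `covered_mb`, `rate` (mutations/Mb/sample), `n_patients`,
#'   `patient_pct`.
#' @export
summarize_by_gene_region <- function(table, samples, regions, depth_track,
                                     depth_floor = 200,
                                     ctdna_floor = 0.02) {
  cf <- samples[samples$type == "cfDNA", , drop = FALSE]
  elig_samples <- cf[cf$ctdna_fraction > ctdna_floor, , drop = FALSE]
  elig_patients <- unique(elig_samples$patient)
  # qualifying mutations: called in an eligible sample; dedup per patient
  tab <- table[table$sample_id %in% elig_samples$sample_id, , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(regions))) {
    rg <- regions[i, ]
    sub <- tab[!is.na(tab$gene) & tab$gene == rg$gene &
               tab$region == rg$region, , drop = FALSE]
    uniq <- sub[!duplicated(paste(sub$patient, sub$key)), , drop = FALSE]
    mr <- mutation_rate(
      data.frame(chrom = uniq$chrom, pos = uniq$pos),
      depth_track, data.frame(chrom = rg$chrom, start = rg$start,
                              end = rg$end),
      elig_samples, depth_floor = depth_floor, ctdna_floor = ctdna_floor)
    n_pat <- length(unique(uniq$patient))
    out[[length(out) + 1L]] <- data.frame(
      gene = rg$gene, region = rg$region,
      n_mutations = mr$mutation_count,
      n_indels = sum(uniq$type != "SNV"),
      n_substitutions = sum(uniq$type == "SNV"),
      covered_mb = mr$covered_mb, n_samples = mr$n_samples,
      rate = mr$rate, n_patients = n_pat,
      patient_pct = if (length(elig_patients) > 0)
        100 * n_pat / length(elig_patients) else NA_real_,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Indel-fraction tables: per gene x region, plus the hypermutated-gene
# 3'-UTR vs all-other-genes 3'-UTR contingency contrast.
indel_fraction_tables <- function(table, samples, cfg, ctdna_floor) {
  cf <- samples[samples$type == "cfDNA" &
                samples$ctdna_fraction > ctdna_floor, , drop = FALSE]
  tab <- table[table$sample_id %in% cf$sample_id, , drop = FALSE]
  tab <- tab[!duplicated(paste(tab$patient, tab$key, tab$gene)), ,
             drop = FALSE]
  utr3 <- tab[!is.na(tab$gene) & tab$region == "UTR3", , drop = FALSE]
  hyper_gene <- sprintf("GENE%02d", cfg$hypermut_gene)
  a <- sum(utr3$gene == hyper_gene & utr3$type != "SNV")
  b <- sum(utr3$gene == hyper_gene & utr3$type == "SNV")
  c_ <- sum(utr3$gene != hyper_gene & utr3$type != "SNV")
  d <- sum(utr3$gene != hyper_gene & utr3$type == "SNV")
  p <- if ((a + b) > 0 && (c_ + d) > 0 && (a + c_) > 0 && (b + d) > 0) {
    fisher_exact(matrix(c(a, b, c_, d), 2, byrow = TRUE))
  } else NA_real_
  by_gr <- if (nrow(tab) == 0 || all(is.na(tab$gene))) {
    data.frame(gene = character(0), region = character(0),
               indel = integer(0), substitution = integer(0))
  } else {
    aggregate(cbind(indel = type != "SNV", substitution = type == "SNV") ~
                gene + region, data = tab, FUN = sum)
  }
  list(
    by_gene_region = by_gr,
    hypermut_contrast = list(gene = hyper_gene, table = matrix(
      c(a, b, c_, d), 2, byrow = TRUE,
      dimnames = list(c(hyper_gene, "other"),
                      c("indel", "substitution"))),
      indel_fraction_hyper = if (a + b > 0) a / (a + b) else NA_real_,
      indel_fraction_other = if (c_ + d > 0) c_ / (c_ + d) else NA_real_,
      p = p))
}
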