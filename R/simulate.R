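# Synthetic targeted-panel cfDNA cohort generator.
#
# The generator emulates the statistical structure of a targeted liquid
# biopsy panel applied to a metastatic prostate cancer cohort: a multi-gene
# panel with annotated UTR/CDS structure, paired cfDNA/WBC samples per
# patient (optionally longitudinal), germline heterozygous SNPs at allele
# fraction ~0.5 in both channels, i.i.d. per-base substitution sequencing
# error in both channels, and planted somatic substitutions and indels
# (1-500 bp) whose expected cfDNA allele fraction follows the heterozygous
# model ctdna_fraction * clonality / 2. One designated gene carries an
# indel-dominant 3'-UTR hypermutation process.

#' Build a simulation configuration
#'
#' All downstream outputs are fully determined by `seed`. Defaults encode
#' the emulated study conditions: mean targeted depth 751x, per-base
#' substitution error 1e-3, a ~12% patient prevalence of indel-dominant
#' (81% indels) 3'-UTR hypermutation in one gene, deletions of 1-89 bp
#' (median ~8) and insertions of 1-99 bp (median ~18) dominated by
#' short-tandem duplications.
#'
#' @param seed integer master seed.
#' @param n_genes number of panel genes.
#' @param gene_structure optional data.frame with columns `gene`, `strand`,
#'   `utr5`, `cds`, `utr3` (lengths in bp; `cds` a multiple of 3). When
#'   NULL a deterministic default layout is generated from the seed.
#' @param panel_depth_mean mean sequencing depth inside targeted regions
#'   (default 751).
#' @param per_base_error i.i.d. per-base substitution error probability in
#'   both channels (default 0.001; a conventional short-read value).
#' @param n_patients number of patients.
#' @param timepoints_per_patient cfDNA timepoints per patient (default 1).
#' @param ctdna_fractions optional numeric vector in \[0,1\] recycled over
#'   cfDNA samples; when NULL, fractions are drawn from the default mix
#'   (~30% ctDNA-negative below 2%, the rest uniform on \[0.1, 0.6\]).
#' @param germline_snp_rate per-bp probability of a heterozygous germline
#'   SNP per patient (default 1e-3).
#' @param somatic_spec optional data.frame of explicitly planted events
#'   with columns `gene` (index), `region` (`CDS`/`UTR5`/`UTR3`), `type`
#'   (`SNV`/`del`/`ins`), `length`, `clonality`, and optionally `patient`
#'   (index; NA = random eligible), `pos` (0-based; NA = random),
#'   `sequence_rule` (`tandem`/`repeat_unit`/`random`; NA = type default),
#'   `timepoint_from` (first timepoint carrying the event; default 1).
#' @param hypermut_gene index of the gene receiving the hypermutation
#'   process (default 1; 0 disables it).
#' @param hypermut_prevalence fraction of eligible patients receiving a
#'   hypermutation event (default 0.12; planted as a deterministic rounded
#'   count).
#' @param hypermut_indel_fraction fraction of hypermutation events that are
#'   indels (default 0.81, exact by rounding).
#' @param hypermut_del_fraction fraction of those indels that are deletions
#'   (default 0.77).
#' @param wbc_indel_noise per-bp, per-read probability of a spurious 1 bp
#'   indel in the WBC channel (default 2e-4), the background-noise knob for
#'   the caller's indel channel.
#' @param flank intergenic flank length around each gene contig (default
#'   300 bp).
#' @param read_len simulated read length (default 150).
#' @param anchor_len split-read anchor length (default 30); somatic events
#'   of length >= `large_indel_min` are carried by junction reads rather
#'   than pileup alleles.
#' @param large_indel_min minimum length routed to the split-read caller
#'   (default 30).
#' @param unaligned_fraction fraction of junction-crossing reads emitted as
#'   unaligned rather than soft-clipped (default 1).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_genes = 10,
                       gene_structure = NULL,
                       panel_depth_mean = 751,
                       per_base_error = 0.001,
                       n_patients = 20,
                       timepoints_per_patient = 1,
                       ctdna_fractions = NULL,
                       germline_snp_rate = 0.001,
                       somatic_spec = NULL,
                       hypermut_gene = 1L,
                       hypermut_prevalence = 0.12,
                       hypermut_indel_fraction = 0.81,
                       hypermut_del_fraction = 0.77,
                       wbc_indel_noise = 2e-4,
                       flank = 300,
                       read_len = 150,
                       anchor_len = 30,
                       large_indel_min = 30,
                       unaligned_fraction = 1) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  stopifnot(n_genes >= 1, n_patients >= 1, timepoints_per_patient >= 1)
  stopifnot(panel_depth_mean > 0, per_base_error >= 0, per_base_error < 1)
  if (!is.null(ctdna_fractions)) {
    stopifnot(all(ctdna_fractions >= 0 & ctdna_fractions <= 1))
  }
  stopifnot(hypermut_prevalence >= 0, hypermut_prevalence <= 1,
            hypermut_indel_fraction >= 0, hypermut_indel_fraction <= 1)
  structure(list(
    seed = as.integer(seed), n_genes = as.integer(n_genes),
    gene_structure = gene_structure,
    panel_depth_mean = panel_depth_mean, per_base_error = per_base_error,
    n_patients = as.integer(n_patients),
    timepoints_per_patient = as.integer(timepoints_per_patient),
    ctdna_fractions = ctdna_fractions,
    germline_snp_rate = germline_snp_rate,
    somatic_spec = somatic_spec,
    hypermut_gene = as.integer(hypermut_gene),
    hypermut_prevalence = hypermut_prevalence,
    hypermut_indel_fraction = hypermut_indel_fraction,
    hypermut_del_fraction = hypermut_del_fraction,
    wbc_indel_noise = wbc_indel_noise,
    flank = as.integer(flank), read_len = as.integer(read_len),
    anchor_len = as.integer(anchor_len),
    large_indel_min = as.integer(large_indel_min),
    unaligned_fraction = unaligned_fraction
  ), class = "sim_config")
}

#' Standard planted-event mix for the emulated study conditions
#'
#' Fixed boundary events guaranteeing that the planted indel spectrum
#' spans the emulated size ranges: 3'-UTR deletions of 1, 8 (the median)
#' and 89 bp (the maximum) and tandem-duplication insertions of 1, 18
#' (the median) and 99 bp (the maximum) in the hypermutated gene, plus
#' coding substitutions and a 3 bp in-frame deletion in other genes.
#'
#' @param hypermut_gene gene index carrying the UTR3 events (default 1).
#' @param clonality clonality of every event (default 1).
#' @return data.frame suitable for `sim_config(somatic_spec = ...)`.
#' @export
standard_somatic_spec <- function(hypermut_gene = 1L, clonality = 1) {
  rbind(
    data.frame(gene = hypermut_gene, region = "UTR3",
               type = c("del", "del", "del", "ins", "ins", "ins"),
               length = c(1L, 8L, 89L, 1L, 18L, 99L),
               clonality = clonality, stringsAsFactors = FALSE),
    data.frame(gene = c(2L, 2L, 4L), region = "CDS",
               type = c("SNV", "SNV", "del"), length = c(0L, 0L, 3L),
               clonality = clonality, stringsAsFactors = FALSE))
}

# Default panel layout: gene 1 is the hypermutation target with a long
# (1814 bp) 3'-UTR; one gene is on the minus strand and one carries an
# alternative transcript whose CDS extends into the predominant 3'-UTR
# (exercising the CDS-override rule for UTR classification).
default_gene_structure <- function(n_genes) {
  utr5 <- 150 + 30 * ((seq_len(n_genes) * 7) %% 6)
  cds <- 900 + 3 * 40 * ((seq_len(n_genes) * 5) %% 5)
  utr3 <- 800 + 120 * ((seq_len(n_genes) * 3) %% 9)
  utr3[1] <- 1814
  strand <- rep("+", n_genes)
  if (n_genes >= 2) strand[2] <- "-"
  data.frame(gene = sprintf("GENE%02d", seq_len(n_genes)),
             strand = strand, utr5 = utr5, cds = cds, utr3 = utr3,
             stringsAsFactors = FALSE)
}

#' Simulate a synthetic targeted-panel cfDNA cohort
#'
#' Builds the reference panel, gene models, sample sheet, germline SNPs and
#' planted somatic truth set. Per-sample data (pileups, reads) are
#' materialized lazily and deterministically from per-sample seeds with
#' [sim_pileup()], [sim_reads()] and [sim_unaligned_reads()], so large
#' cohorts can be streamed. Regenerating with the same configuration is
#' byte-identical.
#'
#' @param config a [sim_config()].
#' @return An object of class `cfdna_cohort`: list with `config`,
#'   `reference` (named character vector of contigs), `models` (list of
#'   [gene_model()]), `regions` (per-gene interval sets), `samples`
#'   (metadata data.frame: `sample_id`, `patient`, `timepoint`, `type`,
#'   `ctdna_fraction`), `germline` (SNP data.frame), `events` (planted
#'   somatic events, one row per patient-level event) and `repeats`
#'   (embedded microsatellite/tandem-repeat loci).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  gs <- config$gene_structure %||% default_gene_structure(config$n_genes)
  stopifnot(nrow(gs) == config$n_genes, all(gs$cds %% 3 == 0))

  # --- reference and gene models (one contig per gene locus) -------------
  reference <- character(0)
  models <- list()
  regions <- list()
  repeats <- list()
  for (g in seq_len(config$n_genes)) {
    L <- config$flank * 2L + gs$utr5[g] + gs$cds[g] + gs$utr3[g]
    seq_ <- random_dna(L)
    fl <- config$flank
    if (gs$strand[g] == "+") {
      u5 <- c(fl, fl + gs$utr5[g])
      cd <- c(u5[2], u5[2] + gs$cds[g])
      u3 <- c(cd[2], cd[2] + gs$utr3[g])
    } else {
      u3 <- c(fl, fl + gs$utr3[g])
      cd <- c(u3[2], u3[2] + gs$cds[g])
      u5 <- c(cd[2], cd[2] + gs$utr5[g])
    }
    exon <- matrix(c(fl, L - fl), ncol = 2)
    txs <- list(list(id = paste0(gs$gene[g], ".1"), exons = exon,
                     cds = matrix(cd, ncol = 2)))
    # one non-hypermut gene gets an alternative transcript whose CDS
    # extends 150 bp into the predominant transcript's 3'-UTR
    if (config$n_genes >= 3 && g == 3 && g != config$hypermut_gene) {
      ext <- if (gs$strand[g] == "+") c(cd[1], cd[2] + 150)
             else c(cd[1] - 150, cd[2])
      txs[[2]] <- list(id = paste0(gs$gene[g], ".2"), exons = exon,
                       cds = matrix(ext, ncol = 2))
    }
    # embed tandem-repeat motifs in the hypermutated 3'-UTR so that
    # repeat-unit deletions have real repeat context (incl. an AACAAC-type
    # microsatellite and an AAT x3 run)
    if (g == config$hypermut_gene) {
      motifs <- list(c("AAC", 4L), c("AAT", 3L), c("TG", 6L))
      at <- u3[1] + floor((u3[2] - u3[1]) * c(0.25, 0.5, 0.75))
      for (i in seq_along(motifs)) {
        run <- strrep(motifs[[i]][1], as.integer(motifs[[i]][2]))
        substr(seq_, at[i] + 1L, at[i] + nchar(run)) <- run
        repeats[[length(repeats) + 1L]] <- data.frame(
          chrom = gs$gene[g], pos = at[i], unit = motifs[[i]][1],
          n_units = as.integer(motifs[[i]][2]), stringsAsFactors = FALSE)
      }
    }
    reference[[gs$gene[g]]] <- seq_
    models[[g]] <- gene_model(gs$gene[g], gs$gene[g], gs$strand[g], txs)
    regions[[gs$gene[g]]] <- list(UTR5 = u5, CDS = cd, UTR3 = u3,
                                  span = c(fl, L - fl))
  }
  repeats <- if (length(repeats)) do.call(rbind, repeats) else
    data.frame(chrom = character(0), pos = integer(0),
               unit = character(0), n_units = integer(0))

  # --- sample sheet ------------------------------------------------------
  patients <- sprintf("P%03d", seq_len(config$n_patients))
  cf <- expand.grid(timepoint = seq_len(config$timepoints_per_patient),
                    patient = patients, stringsAsFactors = FALSE)
  cf <- cf[order(cf$patient, cf$timepoint), ]
  n_cf <- nrow(cf)
  ctdna <- if (!is.null(config$ctdna_fractions)) {
    rep_len(config$ctdna_fractions, n_cf)
  } else {
    neg <- runif(n_cf) < 0.3
    ifelse(neg, runif(n_cf, 0, 0.02), runif(n_cf, 0.1, 0.6))
  }
  samples <- rbind(
    data.frame(sample_id = sprintf("%s_T%d", cf$patient, cf$timepoint),
               patient = cf$patient, timepoint = cf$timepoint,
               type = "cfDNA", ctdna_fraction = ctdna,
               stringsAsFactors = FALSE),
    data.frame(sample_id = paste0(patients, "_WBC"), patient = patients,
               timepoint = 0L, type = "WBC", ctdna_fraction = 0,
               stringsAsFactors = FALSE))
  rownames(samples) <- NULL

  # --- germline heterozygous SNPs per patient ----------------------------
  germ <- list()
  for (p in patients) {
    for (chrom in names(reference)) {
      L <- nchar(reference[[chrom]])
      n_snp <- rbinom(1, L, config$germline_snp_rate)
      if (n_snp == 0) next
      pos <- sort(sample.int(L, n_snp) - 1L)
      ref <- substring(reference[[chrom]], pos + 1, pos + 1)
      alt <- vapply(ref, function(b) sample(setdiff(BASES, b), 1),
                    character(1), USE.NAMES = FALSE)
      germ[[length(germ) + 1L]] <- data.frame(
        patient = p, chrom = chrom, pos = pos, ref = ref, alt = alt,
        stringsAsFactors = FALSE)
    }
  }
  germline <- if (length(germ)) do.call(rbind, germ) else
    data.frame(patient = character(0), chrom = character(0),
               pos = integer(0), ref = character(0), alt = character(0))
  rownames(germline) <- NULL

  sim <- structure(list(config = config, reference = reference,
                        models = models, regions = regions,
                        samples = samples, germline = germline,
                        repeats = repeats), class = "cfdna_cohort")

  # --- planted somatic events -------------------------------------------
  sim$events <- plant_events(sim)

  # per-sample RNG seeds, fixed after all cohort-level draws
  sim$samples$seed <- derive_seeds(config$seed + 1L, nrow(sim$samples))
  sim
}

# Plant the hypermutation process and any explicit somatic_spec events.
# Called inside simulate_cohort's seeded stream.
plant_events <- function(sim) {
  cfg <- sim$config
  gs_names <- names(sim$reference)
  events <- list()
  occupied <- list()  # per patient: data.frame(chrom, start, end)

  eligible <- unique(sim$samples$patient[
    sim$samples$type == "cfDNA" & sim$samples$ctdna_fraction > 0.02])

  add_event <- function(patient, gene_i, region, type, len, clonality,
                        sequence_rule, pos = NA, timepoint_from = 1L,
                        explicit = FALSE) {
    chrom <- gs_names[gene_i]
    reg <- sim$regions[[chrom]][[region]]
    seq_ <- sim$reference[[chrom]]
    for (attempt in seq_len(80)) {
      p <- if (!is.na(pos)) pos else {
        lo <- reg[1] + cfg$anchor_len + 1L
        hi <- reg[2] - len - cfg$anchor_len - 1L
        if (hi <= lo) stop("region too small for planted event of length ",
                           len, " in ", chrom, " ", region)
        sample(lo:hi, 1)
      }
      if (type == "SNV") {
        ref <- substr(seq_, p + 1, p + 1)
        alt <- sample(setdiff(BASES, ref), 1)
        span <- c(p, p + 1)
      } else if (type == "del") {
        rule <- if (is.na(sequence_rule)) "random" else sequence_rule
        if (rule == "repeat_unit") {
          # target an embedded repeat on this contig
          reps <- sim$repeats[sim$repeats$chrom == chrom &
                              nchar(sim$repeats$unit) == len, , drop = FALSE]
          if (nrow(reps) == 0) stop("no embedded repeat of unit length ",
                                    len, " on ", chrom)
          p <- reps$pos[1]
        }
        pl <- plant_large_indel(seq_, p, "del", len, sequence_rule = rule)
        ref <- pl$ref; alt <- pl$alt; p <- pl$pos
        span <- c(p, p + nchar(ref))
      } else {
        rule <- if (is.na(sequence_rule)) "tandem" else sequence_rule
        pl <- plant_large_indel(seq_, p, "ins", len, sequence_rule = rule)
        ref <- pl$ref; alt <- pl$alt; p <- pl$pos
        span <- c(p, p + max(nchar(ref), 1))
      }
      occ <- occupied[[patient]]
      clash <- !is.null(occ) && any(occ$chrom == chrom &
                                    span[1] < occ$end & span[2] > occ$start)
      if (clash && explicit) {
        stop("overlapping planted events at ", chrom, ":", span[1],
             " in patient ", patient)
      }
      if (!clash) {
        occupied[[patient]] <<- rbind(
          occ, data.frame(chrom = chrom, start = span[1], end = span[2]))
        nrm <- normalize_allele(seq_, p, ref, alt)
        events[[length(events) + 1L]] <<- data.frame(
          patient = patient, gene = chrom, chrom = chrom, pos = nrm$pos,
          ref = nrm$ref, alt = nrm$alt, type = type,
          length = if (type == "SNV") 0L else len, region = region,
          clonality = clonality, timepoint_from = timepoint_from,
          stringsAsFactors = FALSE)
        return(invisible(TRUE))
      }
      pos <- NA  # resample on clash for auto-planted events
    }
    stop("could not place planted event after 80 attempts")
  }

  # hypermutation process: deterministic rounded counts so the planted
  # prevalence and indel fraction are exact
  if (cfg$hypermut_gene >= 1 && length(eligible) > 0) {
    n_hyper <- round(cfg$hypermut_prevalence * length(eligible))
    hyper_pat <- sample(eligible, n_hyper)
    n_indel <- round(cfg$hypermut_indel_fraction * n_hyper)
    n_del <- round(cfg$hypermut_del_fraction * n_indel)
    kinds <- c(rep("del", n_del), rep("ins", n_indel - n_del),
               rep("SNV", n_hyper - n_indel))
    for (i in seq_len(n_hyper)) {
      len <- switch(kinds[i],
        del = min(89L, max(1L, round(rlnorm(1, log(8), 1.1)))),
        ins = min(99L, max(1L, round(rlnorm(1, log(18), 0.9)))),
        SNV = 0L)
      add_event(hyper_pat[i], cfg$hypermut_gene, "UTR3", kinds[i], len,
                clonality = 1, sequence_rule = NA)
    }
  }

  # explicit spec rows
  spec <- cfg$somatic_spec
  if (!is.null(spec)) {
    for (i in seq_len(nrow(spec))) {
      pat <- if (!is.null(spec$patient) && !is.na(spec$patient[i])) {
        sprintf("P%03d", spec$patient[i])
      } else if (length(eligible)) sample(eligible, 1) else
        sample(unique(sim$samples$patient), 1)
      add_event(pat, spec$gene[i], spec$region[i], spec$type[i],
                spec$length[i], spec$clonality[i],
                sequence_rule = if (is.null(spec$sequence_rule)) NA else
                  spec$sequence_rule[i],
                pos = if (is.null(spec$pos)) NA else spec$pos[i],
                timepoint_from = if (is.null(spec$timepoint_from)) 1L else
                  spec$timepoint_from[i],
                explicit = !is.null(spec$pos) && !is.na(spec$pos[i]))
    }
  }

  if (length(events) == 0L) {
    return(data.frame(patient = character(0), gene = character(0),
                      chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      type = character(0), length = integer(0),
                      region = character(0), clonality = numeric(0),
                      timepoint_from = integer(0)))
  }
  ev <- do.call(rbind, events)
  ev$event_id <- sprintf("E%04d", seq_len(nrow(ev)))
  rownames(ev) <- NULL
  ev
}

#' Expand the planted truth set to per-sample expected events
#'
#' One row per (event, cfDNA sample) in which the event is present
#' (timepoint >= the event's `timepoint_from`), with the expected allele
#' fraction `ctdna_fraction * clonality / 2` under the heterozygous model.
#'
#' @param sim a `cfdna_cohort`.
#' @return data.frame truth set.
#' @export
truth_set <- function(sim) {
  stopifnot(inherits(sim, "cfdna_cohort"))
  cf <- sim$samples[sim$samples$type == "cfDNA", ]
  out <- list()
  for (i in seq_len(nrow(sim$events))) {
    ev <- sim$events[i, ]
    sm <- cf[cf$patient == ev$patient & cf$timepoint >= ev$timepoint_from, ]
    if (nrow(sm) == 0) next
    out[[length(out) + 1L]] <- data.frame(
      event_id = ev$event_id, patient = ev$patient,
      sample_id = sm$sample_id, chrom = ev$chrom, pos = ev$pos,
      ref = ev$ref, alt = ev$alt, type = ev$type, length = ev$length,
      region = ev$region, clonality = ev$clonality,
      ctdna_fraction = sm$ctdna_fraction,
      expected_af = sm$ctdna_fraction * ev$clonality / 2,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(event_id = character(0), patient = character(0),
                      sample_id = character(0), chrom = character(0),
                      pos = integer(0), ref = character(0),
                      alt = character(0), type = character(0),
                      length = integer(0), region = character(0),
                      clonality = numeric(0), ctdna_fraction = numeric(0),
                      expected_af = numeric(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Plant a large indel into a reference haplotype
#'
#' Produces the modified (donor) haplotype plus the normalized VCF-style
#' allele. Sequence rules: `"tandem"` insertions duplicate the reference
#' segment immediately preceding the insertion point; `"repeat_unit"`
#' deletions remove one unit of an existing tandem repeat (an error if the
#' deleted segment does not equal the adjacent same-length segment on
#' either side); `"random"` inserts random bases or deletes an arbitrary
#' segment.
#'
#' @param reference reference contig sequence (character scalar).
#' @param position 0-based position: insertion point (inserted bases go
#'   before `reference[position]`) or first deleted base.
#' @param type `"ins"` or `"del"`.
#' @param length event length in bp, 1 to 500 (longer events are rejected:
#'   the downstream caller excludes them by design).
#' @param sequence_rule `"random"`, `"tandem"` (insertions) or
#'   `"repeat_unit"` (deletions).
#' @return list with `haplotype` (modified sequence), `junction` (0-based
#'   donor junction position), normalized `pos`/`ref`/`alt`, and `seq`
#'   (the inserted or deleted bases).
#' @export
plant_large_indel <- function(reference, position, type = c("ins", "del"),
                              length,
                              sequence_rule = c("random", "tandem",
                                                "repeat_unit")) {
  type <- match.arg(type)
  sequence_rule <- match.arg(sequence_rule)
  L <- nchar(reference)
  if (length < 1) stop("indel length must be at least 1 (empty event)")
  if (length > 500) stop("indels longer than 500 bp are excluded by design")
  stopifnot(position >= 1, position < L)
  if (type == "ins") {
    ins <- if (sequence_rule == "tandem") {
      if (position < length) stop("tandem duplication needs ", length,
                                  " bp of preceding reference")
      substr(reference, position - length + 1L, position)
    } else if (sequence_rule == "repeat_unit") {
      stop("sequence_rule 'repeat_unit' applies to deletions")
    } else {
      random_dna(length)
    }
    hap <- paste0(substr(reference, 1, position), ins,
                  substr(reference, position + 1L, L))
    anchor <- substr(reference, position, position)
    list(haplotype = hap, junction = position,
         pos = position - 1L, ref = anchor, alt = paste0(anchor, ins),
         seq = ins)
  } else {
    if (position + length > L) stop("deletion extends past contig end")
    del <- substr(reference, position + 1L, position + length)
    if (sequence_rule == "tandem") {
      stop("sequence_rule 'tandem' applies to insertions")
    }
    if (sequence_rule == "repeat_unit") {
      left <- if (position >= length)
        substr(reference, position - length + 1L, position) else ""
      right <- substr(reference, position + length + 1L,
                      position + 2L * length)
      if (!identical(del, left) && !identical(del, right)) {
        stop("no tandem repeat unit of length ", length, " at position ",
             position)
      }
    }
    hap <- paste0(substr(reference, 1, position),
                  substr(reference, position + length + 1L, L))
    anchor <- substr(reference, position, position)
    list(haplotype = hap, junction = position,
         pos = position - 1L, ref = paste0(anchor, del), alt = anchor,
         seq = del)
  }
}
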