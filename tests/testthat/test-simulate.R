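test_that("the same seed regenerates an identical cohort and byte-identical files", {
  cfg <- sim_config(seed = 303, n_genes = 3, n_patients = 3,
                    ctdna_fractions = c(0.3, 0.2, 0.4))
  sim1 <- simulate_cohort(cfg)
  sim2 <- simulate_cohort(cfg)
  expect_identical(sim1$reference, sim2$reference)
  expect_identical(sim1$events, sim2$events)
  expect_identical(sim_pileup(sim1, "P001_T1"),
                   sim_pileup(sim2, "P001_T1"))
  d1 <- file.path(tempdir(), "cohortA")
  d2 <- file.path(tempdir(), "cohortB")
  write_cohort(sim1, d1, sample_ids = c("P001_T1", "P001_WBC"))
  write_cohort(sim2, d2, sample_ids = c("P001_T1", "P001_WBC"))
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("mean panel depth tracks the configured depth", {
  sim <- simulate_cohort(sim_config(seed = 304, n_genes = 2,
                                    n_patients = 1,
                                    ctdna_fractions = 0.3,
                                    hypermut_gene = 0L))
  p <- sim_pileup(sim, "P001_T1")
  expect_lt(abs(mean(p$sites$depth) - 751) / 751, 0.05)
})

test_that("a ctDNA-negative sample carries germline but no somatic support", {
  cfg <- sim_config(seed = 305, n_genes = 2, n_patients = 1,
                    ctdna_fractions = 0,
                    somatic_spec = data.frame(
                      gene = 1, region = "UTR3", type = "SNV",
                      length = 0, clonality = 1, patient = 1),
                    hypermut_gene = 0L)
  sim <- simulate_cohort(cfg)
  tr <- truth_set(sim)
  expect_equal(tr$expected_af, 0)
  p <- sim_pileup(sim, "P001_T1")
  hit <- p$alleles[p$alleles$pos == tr$pos & p$alleles$alt == tr$alt &
                   p$alleles$chrom == tr$chrom, ]
  expect_true(nrow(hit) == 0 || all(hit$count <= 3))  # error reads only
  germ <- sim$germline[sim$germline$patient == "P001", ]
  gk <- paste(germ$chrom, germ$pos, germ$alt)
  pk <- paste(p$alleles$chrom, p$alleles$pos, p$alleles$alt)
  gaf <- p$alleles$count[match(gk, pk)] /
    p$sites$depth[match(paste(germ$chrom, germ$pos),
                        paste(p$sites$chrom, p$sites$pos))]
  expect_gt(mean(gaf, na.rm = TRUE), 0.45)
  expect_lt(mean(gaf, na.rm = TRUE), 0.55)
})

test_that("planted allele fractions follow the heterozygous binomial model", {
  # clonality 1 at ctDNA 30%: observed AF ~ Binomial(depth, 0.15);
  # ~200 replicate sites pooled across genes
  spec <- do.call(rbind, lapply(1:5, function(g)
    data.frame(gene = g, region = rep(c("CDS", "UTR3", "UTR5"),
                                      length.out = 40),
               type = "SNV", length = 0, clonality = 1, patient = 1)))
  cfg <- sim_config(seed = 306, n_genes = 5, n_patients = 1,
                    ctdna_fractions = 0.30, somatic_spec = spec,
                    hypermut_gene = 0L, germline_snp_rate = 0)
  sim <- simulate_cohort(cfg)
  tr <- truth_set(sim)
  expect_equal(nrow(tr), 200)
  p <- sim_pileup(sim, "P001_T1")
  pk <- allele_key(p$alleles$chrom, p$alleles$pos, p$alleles$ref,
                   p$alleles$alt)
  tk <- allele_key(tr$chrom, tr$pos, tr$ref, tr$alt)
  counts <- p$alleles$count[match(tk, pk)]
  counts[is.na(counts)] <- 0
  depths <- p$sites$depth[match(paste(tr$chrom, tr$pos),
                                paste(p$sites$chrom, p$sites$pos))]
  af_hat <- counts / depths
  # each site within a generous binomial band, pooled mean within 3 SE
  p0 <- 0.15
  se_pool <- sqrt(p0 * (1 - p0) / sum(depths))
  expect_lt(abs(sum(counts) / sum(depths) - p0), 3 * se_pool)
  per_site_ok <- abs(af_hat - p0) <= 5 * sqrt(p0 * (1 - p0) / depths)
  expect_gt(mean(per_site_ok), 0.98)
})

test_that("pooled support converges to the expected AF at high depth", {
  cfg <- sim_config(seed = 307, n_genes = 2, n_patients = 1,
                    panel_depth_mean = 5000, ctdna_fractions = 0.4,
                    somatic_spec = data.frame(
                      gene = 1:2, region = "UTR3", type = c("del", "ins"),
                      length = c(8, 18), clonality = c(1, 0.5),
                      patient = 1),
                    hypermut_gene = 0L, germline_snp_rate = 0)
  sim <- simulate_cohort(cfg)
  tr <- truth_set(sim)
  p <- sim_pileup(sim, "P001_T1")
  pk <- allele_key(p$alleles$chrom, p$alleles$pos, p$alleles$ref,
                   p$alleles$alt)
  for (i in seq_len(nrow(tr))) {
    cnt <- p$alleles$count[match(allele_key(tr$chrom[i], tr$pos[i],
                                            tr$ref[i], tr$alt[i]), pk)]
    dp <- p$sites$depth[p$sites$chrom == tr$chrom[i] &
                        p$sites$pos == tr$pos[i]]
    sd3 <- 3 * sqrt(tr$expected_af[i] * (1 - tr$expected_af[i]) / dp)
    expect_lt(abs(cnt / dp - tr$expected_af[i]), sd3)
  }
})

test_that("hypermutation planting hits the configured prevalence and indel fraction exactly", {
  cfg <- sim_config(seed = 308, n_genes = 3, n_patients = 10,
                    ctdna_fractions = rep(0.3, 10),
                    hypermut_prevalence = 1.0,
                    hypermut_indel_fraction = 0.8)
  sim <- simulate_cohort(cfg)
  ev <- sim$events[sim$events$region == "UTR3" &
                   sim$events$gene == "GENE01", ]
  expect_equal(length(unique(ev$patient)), 10)
  expect_equal(mean(ev$type != "SNV"), 0.8)
  expect_true(all(ev$length[ev$type == "del"] <= 89))
  expect_true(all(ev$length[ev$type == "ins"] <= 99))
})

test_that("the standard event mix spans the emulated indel size range", {
  sim <- small_cohort(seed = 309)
  lens <- sim$events$length[sim$events$type != "SNV"]
  expect_equal(min(lens), 1)
  expect_gte(max(lens), 99)
  # germline SNPs are present in both channels of a patient
  pat <- sim$samples$patient[1]
  cf <- sim_pileup(sim, paste0(pat, "_T1"))
  wb <- sim_pileup(sim, paste0(pat, "_WBC"))
  germ <- sim$germline[sim$germline$patient == pat, ][1:5, ]
  for (i in 1:5) {
    for (p in list(cf, wb)) {
      cnt <- p$alleles$count[p$alleles$chrom == germ$chrom[i] &
                             p$alleles$pos == germ$pos[i] &
                             p$alleles$alt == germ$alt[i]]
      expect_gt(sum(cnt), 0)
    }
  }
  # somatic events are absent from the WBC channel
  ev <- sim$events[sim$events$patient == pat, ]
  if (nrow(ev) > 0) {
    wk <- allele_key(wb$alleles$chrom, wb$alleles$pos, wb$alleles$ref,
                     wb$alleles$alt)
    expect_false(any(allele_key(ev$chrom, ev$pos, ev$ref, ev$alt) %in% wk))
  }
})

test_that("gene models round-trip through the on-disk feature table", {
  sim <- small_cohort(seed = 312, n_patients = 2)
  d <- file.path(tempdir(), "cohort_models")
  write_cohort(sim, d, sample_ids = character(0))
  models <- read_gene_models(file.path(d, "genes.tsv"))
  expect_equal(length(models), length(sim$models))
  for (m in sim$models) {
    rt <- models[[m$gene]]
    expect_equal(rt$strand, m$strand)
    expect_equal(length(rt$transcripts), length(m$transcripts))
    u1 <- derive_utrs(m); u2 <- derive_utrs(rt)
    expect_equal(u1$utr3, u2$utr3)
    expect_equal(u1$utr5, u2$utr5)
  }
  unlink(d, recursive = TRUE)
})

test_that("plant_large_indel implements the sequence rules and bounds", {
  ref <- paste0(strrep("G", 40), "AATAATAAT", strrep("C", 40))
  # removing one AAT unit of the embedded repeat: AATAATAAT -> AATAAT
  pl <- plant_large_indel(ref, 40, "del", 3, sequence_rule = "repeat_unit")
  expect_equal(substr(pl$haplotype, 39, 48), "GGAATAATCC")
  expect_equal(nchar(pl$haplotype), nchar(ref) - 3)
  # no repeat context: repeat_unit is rejected
  ref_norep <- paste0(strrep("A", 10), "CGT", strrep("T", 10))
  expect_error(plant_large_indel(ref_norep, 10, "del", 3,
                                 sequence_rule = "repeat_unit"),
               "repeat")
  # tandem insertion duplicates the preceding reference segment
  set.seed(310)
  ref2 <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
                collapse = "")
  pl <- plant_large_indel(ref2, 100, "ins", 18, sequence_rule = "tandem")
  expect_equal(pl$seq, substr(ref2, 83, 100))  # reference[p-18, p)
  expect_equal(substr(pl$haplotype, 101, 118), pl$seq)
  # empty and oversized events are rejected
  expect_error(plant_large_indel(ref2, 100, "ins", 0), "at least 1")
  expect_error(plant_large_indel(ref2, 100, "del", 501), "500")
})

test_that("overlapping explicitly placed events are rejected with a diagnostic", {
  spec <- data.frame(gene = c(1, 1), region = "UTR3", type = "del",
                     length = 10, clonality = 1, patient = c(1, 1),
                     pos = c(2500, 2505))
  expect_error(
    simulate_cohort(sim_config(seed = 311, n_genes = 2, n_patients = 1,
                               ctdna_fractions = 0.3,
                               somatic_spec = spec, hypermut_gene = 0L)),
    "overlapping")
})
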