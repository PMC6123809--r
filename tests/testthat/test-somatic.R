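test_that("build_pileup counts matches, mismatches and depth from CIGARs", {
  ref <- c(ctg = strrep("ACGT", 50))
  # 100 reads matching the reference: no alleles, depth 100
  reads <- data.frame(read_id = sprintf("r%03d", 1:100),
                      chrom = "ctg", pos = 0L, cigar = "40M",
                      seq = substr(ref[["ctg"]], 1, 40),
                      stringsAsFactors = FALSE)
  p <- build_pileup(reads, ref)
  expect_equal(nrow(p$alleles), 0)
  expect_equal(p$sites$depth[1:40], rep(100, 40))
  expect_equal(p$sites$depth[41], 0)
  # 95 ref + 5 alt reads at one position
  alt_seq <- reads$seq[1]
  substr(alt_seq, 10, 10) <- "T"  # position 9 (0-based) is C in ACGT...
  reads$seq[1:5] <- alt_seq
  p <- build_pileup(reads, ref)
  expect_equal(nrow(p$alleles), 1)
  expect_equal(p$alleles$pos, 9)
  expect_equal(p$alleles$ref, "C")
  expect_equal(p$alleles$alt, "T")
  expect_equal(p$alleles$count, 5)
  expect_equal(p$alleles$count / p$sites$depth[10], 0.05)
})

test_that("build_pileup normalizes equivalent indel representations in repeat context", {
  # an AACAAC microsatellite: a 3 bp deletion has several CIGAR-level
  # placements that must collapse to one left-aligned allele
  left <- strrep("G", 30)
  right <- strrep("T", 30)
  ref <- c(ctg = paste0(left, "AACAACAAC", right))
  mk_del_read <- function(id, del_at) {
    # read covering [20, 60) with a 3 bp deletion starting at del_at
    seq_ <- paste0(substr(ref[["ctg"]], 21, del_at),
                   substr(ref[["ctg"]], del_at + 4, 63))
    data.frame(read_id = id, chrom = "ctg", pos = 20L,
               cigar = paste0(del_at - 20, "M3D", 63 - del_at - 3, "M"),
               seq = seq_, stringsAsFactors = FALSE)
  }
  # deletions of the first, second and third AAC unit (1-based starts
  # 31, 34, 37) are the same haplotype
  reads <- rbind(mk_del_read("a", 30), mk_del_read("b", 33),
                 mk_del_read("c", 36))
  p <- build_pileup(reads, ref)
  expect_equal(nrow(p$alleles), 1)
  expect_equal(p$alleles$count, 3)
  # brute-force check: left-aligned anchor just before the repeat run
  nrm <- utrscan:::normalize_allele(ref[["ctg"]], 30, "AACA", "A")
  expect_equal(p$alleles$pos, nrm$pos)
  expect_equal(p$alleles$ref, nrm$ref)
  expect_equal(p$alleles$alt, nrm$alt)
})

test_that("build_pileup records insertions, skips soft-clips, errors on unknown contigs", {
  ref <- c(ctg = strrep("ACGT", 25))
  rd <- data.frame(read_id = "i1", chrom = "ctg", pos = 10L,
                   cigar = "10M2I8M", seq = NA, stringsAsFactors = FALSE)
  rd$seq <- paste0(substr(ref[["ctg"]], 11, 20), "TT",
                   substr(ref[["ctg"]], 21, 28))
  p <- build_pileup(rd, ref)
  expect_equal(nrow(p$alleles), 1)
  expect_equal(nchar(p$alleles$alt) - nchar(p$alleles$ref), 2)
  # soft-clipped tail contributes no alleles or depth
  rd2 <- data.frame(read_id = "s1", chrom = "ctg", pos = 0L,
                    cigar = "10M10S",
                    seq = paste0(substr(ref[["ctg"]], 1, 10),
                                 strrep("G", 10)),
                    stringsAsFactors = FALSE)
  p2 <- build_pileup(rd2, ref)
  expect_equal(nrow(p2$alleles), 0)
  expect_equal(p2$sites$depth[11], 0)
  expect_error(build_pileup(data.frame(read_id = "x", chrom = "nope",
                                       pos = 0L, cigar = "5M",
                                       seq = "ACGTA"), ref), "nope")
})

test_that("the five-condition caller equals the brute-force inequality filter", {
  # randomized battery of pileup columns with adversarial boundary values
  set.seed(501)
  n <- 4000
  ref <- random_dna_test(n)
  refb <- strsplit(ref, "")[[1]]
  depth <- sample(c(0:5, 15:30, 700:800), n, replace = TRUE)
  altn <- vapply(refb, function(b) sample(setdiff(c("A", "C", "G", "T"),
                                                  b), 1), character(1),
                 USE.NAMES = FALSE)
  count <- pmin(depth, sample(c(0:12, 20, 50), n, replace = TRUE))
  cf <- mk_pileup(ref, depth,
                  data.frame(chrom = "ctg", pos = which(count > 0) - 1L,
                             ref = refb[count > 0], alt = altn[count > 0],
                             count = count[count > 0],
                             stringsAsFactors = FALSE))
  wbc_depth <- sample(c(0:25, 700:800), n, replace = TRUE)
  wbc_count <- pmin(wbc_depth, sample(0:3, n, replace = TRUE))
  wbc <- mk_pileup(ref, wbc_depth,
                   data.frame(chrom = "ctg",
                              pos = which(wbc_count > 0) - 1L,
                              ref = refb[wbc_count > 0],
                              alt = altn[wbc_count > 0],
                              count = wbc_count[wbc_count > 0],
                              stringsAsFactors = FALSE))
  bgs <- lapply(1:3, function(i) {
    d <- sample(600:900, n, replace = TRUE)
    cnt <- rbinom(n, d, 0.0005)
    mk_pileup(ref, d, data.frame(chrom = "ctg",
                                 pos = which(cnt > 0) - 1L,
                                 ref = refb[cnt > 0],
                                 alt = altn[cnt > 0],
                                 count = cnt[cnt > 0],
                                 stringsAsFactors = FALSE))
  })
  bg <- build_background(bgs)
  audit <- call_somatic(cf, wbc, bg, keep_filtered = TRUE)
  # brute force, candidate by candidate
  bg_alt <- integer(n); bg_dp <- numeric(n)
  for (b in bgs) {
    bg_dp <- bg_dp + b$sites$depth
    ak <- b$alleles$pos + 1L
    bg_alt[ak] <- bg_alt[ak] + b$alleles$count
  }
  for (i in seq_len(nrow(audit))) {
    pos1 <- audit$pos[i] + 1L
    expect_equal(audit$pass[i], five_filter_oracle(
      af = count[pos1] / depth[pos1], alt_reads = count[pos1],
      bg_af = (bg_alt[pos1] + 1) / (bg_dp[pos1] + 1),
      wbc_af = if (wbc_depth[pos1] > 0)
        wbc_count[pos1] / wbc_depth[pos1] else 0,
      wbc_depth = wbc_depth[pos1]))
  }
  # every candidate is audited
  expect_equal(nrow(audit), sum(count > 0))
})

test_that("raising any caller threshold never adds a call", {
  sim <- small_cohort(seed = 502, n_patients = 6)
  bg <- build_background(sim)
  cf <- sim_pileup(sim, "P001_T1")
  wbc <- sim_pileup(sim, "P001_WBC")
  base <- call_somatic(cf, wbc, bg)
  base_keys <- allele_key(base$chrom, base$pos, base$ref, base$alt)
  tighter <- list(list(min_af = 0.05), list(min_reads = 30),
                  list(bg_ratio = 100), list(wbc_ratio = 10),
                  list(min_wbc_depth = 600))
  for (tw in tighter) {
    args <- c(list(cfdna = cf, wbc = wbc, background = bg), tw)
    calls <- do.call(call_somatic, args)
    keys <- allele_key(calls$chrom, calls$pos, calls$ref, calls$alt)
    expect_true(all(keys %in% base_keys))
  }
})

test_that("germline heterozygous SNPs are never called somatic", {
  sim <- small_cohort(seed = 503, n_patients = 8)
  bg <- build_background(sim)
  for (pat in unique(sim$samples$patient)[1:4]) {
    cf <- sim_pileup(sim, paste0(pat, "_T1"))
    wbc <- sim_pileup(sim, paste0(pat, "_WBC"))
    calls <- call_somatic(cf, wbc, bg)
    germ <- sim$germline[sim$germline$patient == pat, ]
    gk <- allele_key(germ$chrom, germ$pos, germ$ref, germ$alt)
    ck <- allele_key(calls$chrom, calls$pos, calls$ref, calls$alt)
    expect_false(any(gk %in% ck))
  }
})

test_that("the background pseudocount keeps unseen alleles from passing on ratio alone", {
  ref <- "AAAA"
  cf <- mk_pileup(ref, rep(1000, 4),
                  data.frame(chrom = "ctg", pos = 1L, ref = "A",
                             alt = "G", count = 3L))
  wbc <- mk_pileup(ref, rep(1000, 4))
  bgp <- mk_pileup(ref, rep(1000, 4))
  bg <- build_background(list(bgp))
  expect_equal(as.numeric(background_af(bg, "ctg", 1L, "A", "G")),
               1 / 1001)
  audit <- call_somatic(cf, wbc, bg, keep_filtered = TRUE)
  # AF 0.003: fails the AF and support conditions but also the 25x
  # background rule (25/1001 > 0.003), by the pseudocount design
  expect_false(audit$flag_background)
})

test_that("VCF round-trip preserves coordinates and filter quantities bit-exactly", {
  sim <- small_cohort(seed = 504, n_patients = 6)
  bg <- build_background(sim)
  cf <- sim_pileup(sim, "P002_T1")
  wbc <- sim_pileup(sim, "P002_WBC")
  calls <- call_somatic(cf, wbc, bg)
  path <- tempfile(fileext = ".vcf")
  write_vcf(calls, path, sample_id = "P002_T1",
            reference = sim$reference)
  back <- read_vcf_calls(path)
  expect_equal(nrow(back), nrow(calls))
  expect_identical(back$pos, calls$pos)          # 0-based restored
  expect_identical(back$ref, calls$ref)
  expect_identical(back$af, calls$af)            # bit-exact floats
  expect_identical(back$background_af, calls$background_af)
  expect_identical(back$wbc_af, calls$wbc_af)
  # the 1-based convention on disk
  raw <- readLines(path)
  body <- raw[!startsWith(raw, "#")]
  expect_equal(as.integer(vapply(strsplit(body, "\t"), `[[`,
                                 character(1), 2)),
               calls$pos + 1L)
  # empty call set still yields a valid header-only VCF
  p0 <- tempfile(fileext = ".vcf")
  write_vcf(calls[0, ], p0)
  expect_true(any(startsWith(readLines(p0), "##fileformat=VCFv4.2")))
  expect_equal(nrow(read_vcf_calls(p0)), 0)
  # unsorted input is an error, not a silent reorder
  if (nrow(calls) >= 2) {
    expect_error(write_vcf(calls[rev(seq_len(nrow(calls))), ],
                           tempfile()), "sorted")
  }
  # independent parser agreement
  if (requireNamespace("vcfR", quietly = TRUE)) {
    v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
    expect_equal(as.integer(vcfR::getPOS(v)), calls$pos + 1L)
    expect_equal(vcfR::getALT(v), calls$alt)
  }
  unlink(c(path, p0))
})

test_that("background model TSV serialization reports pooled counts", {
  sim <- small_cohort(seed = 505, n_patients = 4)
  bg <- build_background(sim)
  p <- sim_pileup(sim, "P001_WBC")
  path <- tempfile(fileext = ".tsv")
  write_background(bg, path, p$sites)
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  expect_true(all(c("chrom", "pos", "alt", "cohort_alt",
                    "cohort_depth") %in% names(tab)))
  depth_rows <- tab[tab$alt == ".", ]
  expect_equal(nrow(depth_rows), bg$n_positions)
  expect_equal(sum(depth_rows$cohort_depth), sum(bg$depth_total))
  unlink(path)
})
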