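# A small hand-built locus: contig of 1200 bp, single-exon gene with
# exon [100, 1100), CDS [200, 900).
mk_locus <- function(strand = "+", alt_cds = NULL) {
  set.seed(99)
  ref <- paste(sample(c("A", "C", "G", "T"), 1200, replace = TRUE),
               collapse = "")
  txs <- list(list(id = "T1", exons = matrix(c(100, 1100), ncol = 2),
                   cds = matrix(c(200, 900), ncol = 2)))
  if (!is.null(alt_cds)) {
    txs[[2]] <- list(id = "T2", exons = matrix(c(100, 1100), ncol = 2),
                     cds = matrix(alt_cds, ncol = 2))
  }
  list(ref = c(ctg = ref),
       model = gene_model("G1", "ctg", strand, txs))
}

test_that("derive_utrs splits exonic sequence around the CDS by strand", {
  m <- gene_model("G", "c", "+", list(list(
    exons = matrix(c(0, 1000), ncol = 2),
    cds = matrix(c(100, 900), ncol = 2))))
  u <- derive_utrs(m)
  expect_equal(u$utr5, matrix(c(0, 100), ncol = 2))
  expect_equal(u$utr3, matrix(c(900, 1000), ncol = 2))
  m$strand <- "-"
  u <- derive_utrs(m)
  expect_equal(u$utr5, matrix(c(900, 1000), ncol = 2))
  expect_equal(u$utr3, matrix(c(0, 100), ncol = 2))
})

test_that("derive_utrs picks the predominant transcript from expression and flags non-coding genes", {
  m <- gene_model("G", "c", "+", list(
    list(exons = matrix(c(0, 1000), ncol = 2),
         cds = matrix(c(100, 900), ncol = 2)),
    list(exons = matrix(c(0, 1000), ncol = 2),
         cds = matrix(c(300, 600), ncol = 2))))
  u <- derive_utrs(m, expression = c(5, 50))
  expect_equal(u$transcript, 2L)
  expect_equal(u$utr5, matrix(c(0, 300), ncol = 2))
  nc <- gene_model("G", "c", "+", list(list(
    exons = matrix(c(0, 1000), ncol = 2), cds = NULL)))
  u <- derive_utrs(nc)
  expect_false(u$coding)
  expect_equal(nrow(u$utr3), 0)
})

test_that("UTR intervals never intersect any CDS interval of the gene", {
  loc <- mk_locus(alt_cds = c(850, 1000))
  u <- derive_utrs(loc$model)
  cds <- utrscan:::all_cds(loc$model)
  for (iv in list(u$utr5, u$utr3)) {
    for (i in seq_len(nrow(iv))) {
      # the predominant transcript's own CDS never overlaps its UTRs
      expect_false(utrscan:::overlaps_any(iv[i, 1], iv[i, 2],
                                          loc$model$transcripts[[1]]$cds))
    }
  }
  # and classification enforces the any-transcript CDS override
  cls <- classify_variant("ctg", 950, 951, list(loc$model))
  expect_equal(cls$region, "CDS")  # inside T1's UTR3 but T2's CDS
})

test_that("classify_variant applies CDS > UTR > intron > intergenic priority", {
  loc <- mk_locus()
  models <- list(loc$model)
  expect_equal(classify_variant("ctg", 150, 151, models)$region, "UTR5")
  expect_equal(classify_variant("ctg", 950, 951, models)$region, "UTR3")
  expect_equal(classify_variant("ctg", 500, 501, models)$region, "CDS")
  expect_equal(classify_variant("ctg", 50, 51, models)$region,
               "intergenic")
  # deletion spanning the CDS/UTR3 boundary takes CDS priority
  expect_equal(classify_variant("ctg", 895, 910, models)$region, "CDS")
  # positions not matching any contig are intergenic with gene NA
  cls <- classify_variant("other", 10, 11, models)
  expect_true(is.na(cls$gene))
  expect_equal(cls$region, "intergenic")
})

test_that("region classes partition every position deterministically", {
  loc <- mk_locus(alt_cds = c(850, 1000))
  models <- list(loc$model)
  set.seed(17)
  for (pos in sample(0:1199, 80)) {
    cls <- classify_variant("ctg", pos, pos + 1, models)
    expect_equal(nrow(cls), 1)
    expect_true(cls$region %in% c("CDS", "UTR5", "UTR3", "intron",
                                  "intergenic"))
    cls2 <- classify_variant("ctg", pos, pos + 1, models)
    expect_identical(cls, cls2)
  }
})

test_that("consequence translates CDS SNVs and routes indels by frame and region", {
  loc <- mk_locus()
  ref <- loc$ref
  # engineer a codon: CDS starts at 200, first codon = positions 200-202
  seq_ <- ref[["ctg"]]
  substr(seq_, 201, 203) <- "TCA"  # Ser
  ref[["ctg"]] <- seq_
  # TCA -> TAA is a stop gain at codon position 2
  expect_equal(consequence("ctg", 201, "C", "A", loc$model, ref),
               "stopgain")
  # TCA -> TCG is synonymous (Ser)
  expect_equal(consequence("ctg", 202, "A", "G", loc$model, ref),
               "synonymous")
  # TCA -> GCA is missense (Ser -> Ala)
  expect_equal(consequence("ctg", 200, "T", "G", loc$model, ref),
               "missense")
  # 3 bp CDS deletion is in-frame; 4 bp is a frameshift
  anchor <- substr(seq_, 300, 300)
  del3 <- substr(seq_, 300, 303)
  expect_equal(consequence("ctg", 299, del3, anchor, loc$model, ref),
               "inframe_indel")
  del4 <- substr(seq_, 300, 304)
  expect_equal(consequence("ctg", 299, del4, anchor, loc$model, ref),
               "frameshift_indel")
  # an 8 bp UTR3 deletion is utr, never a frameshift
  anchor <- substr(seq_, 950, 950)
  del8 <- substr(seq_, 950, 958)
  expect_equal(consequence("ctg", 949, del8, anchor, loc$model, ref),
               "utr")
})

test_that("consequence respects strand on a minus-strand gene", {
  loc <- mk_locus(strand = "-")
  ref <- loc$ref
  seq_ <- ref[["ctg"]]
  # minus-strand first codon is revcomp of positions 898-900 (1-based);
  # plant TGA on the genome = TCA on the transcript
  substr(seq_, 898, 900) <- "TGA"
  ref[["ctg"]] <- seq_
  # genome G->T at 0-based 898 makes transcript TCA->TAA: stopgain
  expect_equal(consequence("ctg", 898, "G", "T", loc$model, ref),
               "stopgain")
})

test_that("mutation_rate implements the coverage- and sample-normalized formula", {
  region <- data.frame(chrom = "ctg", start = 0, end = 500000)
  depth <- data.frame(chrom = "ctg", pos = 0:499999,
                      depth = rep(1000, 500000))
  samples <- data.frame(ctdna_fraction = c(0.3, 0.2, 0.1, 0.05, 0.01))
  muts <- data.frame(chrom = "ctg", pos = c(10, 20, 30, 40, 50, 60))
  r <- mutation_rate(muts, depth, region, samples)
  expect_equal(r$covered_mb, 0.5)
  expect_equal(r$n_samples, 4)  # strict > 2% gate
  expect_equal(r$rate, 6 / 0.5 / 4)
  # zero mutations: rate 0
  r0 <- mutation_rate(muts[0, ], depth, region, samples)
  expect_equal(r0$rate, 0)
  # halving covered territory doubles the rate
  depth2 <- depth
  depth2$depth[1:250000] <- 100  # below the strict 200 floor
  r2 <- mutation_rate(muts, depth2, region, samples)
  expect_equal(r2$rate, 2 * r$rate)
  # depth exactly at the floor does not count (strict inequality)
  depth3 <- depth
  depth3$depth[] <- 200
  r3 <- mutation_rate(muts, depth3, region, samples)
  expect_false(r3$defined)
  expect_true(is.na(r3$rate))
})
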