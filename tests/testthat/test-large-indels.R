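set.seed(601)
REF_SEQ <- random_dna_test(6000)
REF <- c(panel = REF_SEQ)

test_that("split_reads partitions reads into terminal anchors", {
  reads <- data.frame(read_id = c("a", "b"),
                      seq = c(substr(REF_SEQ, 1, 150),
                              substr(REF_SEQ, 200, 258)),
                      stringsAsFactors = FALSE)
  anchors <- split_reads(reads)
  # the 59 bp read is skipped with a counter
  expect_equal(attr(anchors, "skipped"), 1)
  a <- anchors[anchors$read_id == "a", ]
  expect_equal(a$seq[a$side == "five_prime"], substr(REF_SEQ, 1, 30))
  expect_equal(a$seq[a$side == "three_prime"], substr(REF_SEQ, 121, 150))
  # anchors plus the middle segment reproduce the read
  mid <- substr(reads$seq[1], 31, 120)
  expect_equal(paste0(a$seq[a$side == "five_prime"], mid,
                      a$seq[a$side == "three_prime"]), reads$seq[1])
})

test_that("anchor placement requires a unique exact match", {
  anchors <- data.frame(read_id = "r", side = "five_prime",
                        seq = substr(REF_SEQ, 1001, 1030),
                        read_len = 150, stringsAsFactors = FALSE)
  placed <- align_anchors(anchors, REF)
  expect_equal(placed$pos, 1000)
  expect_equal(placed$strand, "+")
  # a 1-mismatch anchor finds nothing under exact-match placement
  mm <- anchors
  b <- substr(mm$seq, 15, 15)
  substr(mm$seq, 15, 15) <- setdiff(c("A", "C", "G", "T"), b)[1]
  placed <- align_anchors(mm, REF)
  expect_equal(nrow(placed), 0)
  expect_equal(attr(placed, "unmatched"), 1)
  # an anchor present at two loci is dropped as ambiguous
  dup_ref <- c(panel = paste0(REF_SEQ, substr(REF_SEQ, 1001, 1030)))
  placed <- align_anchors(anchors, dup_ref)
  expect_equal(nrow(placed), 0)
  expect_equal(attr(placed, "ambiguous"), 1)
  # reverse-complement anchors place on the minus strand
  rc <- data.frame(read_id = "r2", side = "five_prime",
                   seq = revcomp(substr(REF_SEQ, 1001, 1030)),
                   read_len = 150, stringsAsFactors = FALSE)
  placed <- align_anchors(rc, REF)
  expect_equal(placed$pos, 1000)
  expect_equal(placed$strand, "-")
})

test_that("concordant pairs produce no cluster; spanning reads recover a planted deletion", {
  # concordant read straight off the reference
  reads <- data.frame(read_id = "c", seq = substr(REF_SEQ, 501, 650),
                      stringsAsFactors = FALSE)
  clusters <- cluster_discordant(align_anchors(split_reads(reads), REF),
                                 reads, REF)
  expect_equal(length(clusters), 0)
  # 5 reads spanning the same 89 bp deletion cluster together
  set.seed(602)
  jr <- make_junction_reads(REF_SEQ, "panel", 3000, "del", 89, n = 5)
  clusters <- cluster_discordant(
    align_anchors(split_reads(jr$reads), REF), jr$reads, REF)
  expect_equal(length(clusters), 1)
  expect_equal(clusters[[1]]$event, "deletion")
  expect_equal(clusters[[1]]$length, 89)
  expect_equal(clusters[[1]]$left_bp, 3000, tolerance = 5)
})

test_that("clustering tolerance separates or merges nearby breakpoints", {
  set.seed(603)
  jr1 <- make_junction_reads(REF_SEQ, "panel", 2000, "del", 40, n = 1)
  jr2 <- make_junction_reads(REF_SEQ, "panel", 2003, "del", 40, n = 1)
  reads <- rbind(jr1$reads, jr2$reads)
  reads$read_id <- c("p1", "p2")
  placed <- align_anchors(split_reads(reads), REF)
  with_tol <- cluster_discordant(placed, reads, REF, pos_tolerance = 5)
  expect_equal(length(with_tol), 1)
  no_tol <- cluster_discordant(placed, reads, REF, pos_tolerance = 0)
  expect_equal(length(no_tol), 2)
})

test_that("fragment deduplication collapses identical start positions", {
  members <- data.frame(read_id = sprintf("r%d", 1:6),
                        chrom = "panel",
                        start = c(100, 100, 200, 300, 300, 300),
                        left_bp = 400, delta = 50)
  cl <- structure(list(chrom = "panel", left_bp = 400, right_bp = 450,
                       event = "deletion", length = 50,
                       members = members,
                       unique_fragments = NA_integer_),
                  class = "breakpoint_cluster")
  expect_equal(dedupe_fragments(cl)$unique_fragments, 3)
  cl$members$start <- rep(7, 6)
  expect_equal(dedupe_fragments(cl)$unique_fragments, 1)
  # random duplication pattern equals the brute-force distinct count
  set.seed(604)
  for (i in 1:20) {
    cl$members <- members[sample(6, sample(1:6, 1), replace = TRUE), ]
    expect_equal(dedupe_fragments(cl)$unique_fragments,
                 length(unique(cl$members$start)))
  }
})

test_that("event calling enforces the fragment and length bounds", {
  set.seed(605)
  # a 2-fragment cluster is never called
  jr <- make_junction_reads(REF_SEQ, "panel", 2500, "del", 60, n = 2)
  expect_equal(nrow(detect_large_indels(jr$reads, REF)), 0)
  # a 600 bp deletion is found but excluded by the length bound (the
  # donor is built by hand: the planting API itself enforces the bound)
  ref_long <- c(panel = random_dna_test(3000))
  hap600 <- paste0(substr(ref_long[["panel"]], 1, 1200),
                   substr(ref_long[["panel"]], 1801, 3000))
  starts <- seq(1085, 1169, by = 12)
  reads600 <- data.frame(read_id = sprintf("d600_%d", seq_along(starts)),
                         seq = substring(hap600, starts + 1, starts + 150),
                         stringsAsFactors = FALSE)
  clusters <- cluster_discordant(
    align_anchors(split_reads(reads600), ref_long), reads600, ref_long)
  expect_equal(length(clusters), 1)  # detected as a cluster ...
  expect_equal(nrow(call_large_indels(clusters, ref_long, reads600)),
               0)                    # ... but never called
})

test_that("a planted 99 bp tandem duplication is recovered with its sequence", {
  set.seed(606)
  jr <- make_junction_reads(REF_SEQ, "panel", 3500, "ins", 99, n = 8,
                            sequence_rule = "tandem")
  ev <- detect_large_indels(jr$reads, REF)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$type, "insertion")
  expect_equal(ev$length, 99)
  expect_gte(ev$unique_fragments, 3)
  # junction placement in repeat context is cyclically ambiguous, so the
  # recovered event must reproduce the planted haplotype, not necessarily
  # the identical (pos, seq) representation
  hap_called <- paste0(substr(REF_SEQ, 1, ev$left_bp), ev$seq,
                       substr(REF_SEQ, ev$left_bp + 1, nchar(REF_SEQ)))
  expect_equal(hap_called, jr$event$haplotype)
  # and the mechanism classifier agrees it is a tandem duplication
  expect_equal(classify_indel_mechanism(REF_SEQ, jr$event$pos,
                                        jr$event$ref, jr$event$alt),
               "tandem_duplication")
})

test_that("hard postcondition: no called event exceeds 500 bp or has < 3 fragments", {
  set.seed(607)
  all_reads <- list()
  for (spec in list(c(1500, 31), c(2500, 250), c(4000, 500))) {
    jr <- make_junction_reads(REF_SEQ, "panel", spec[1], "del", spec[2],
                              n = sample(3:10, 1))
    jr$reads$read_id <- paste0(spec[1], "_", jr$reads$read_id)
    all_reads[[length(all_reads) + 1]] <- jr$reads
  }
  ev <- detect_large_indels(do.call(rbind, all_reads), REF)
  expect_true(all(ev$length <= 500))
  expect_true(all(ev$length >= 1))
  expect_true(all(ev$unique_fragments >= 3))
  expect_equal(sort(ev$length), c(31, 250, 500))
})
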