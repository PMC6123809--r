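# Five-condition somatic caller over cfDNA pileups with a WBC-cohort
# background-error model.
#
# A candidate allele in a cfDNA sample is called somatic iff all of:
#   1. allele fraction >= 1%
#   2. at least 10 supporting reads
#   3. allele fraction >= 25 x the cohort background error rate (the
#      average allele fraction across all WBC samples, with a +1/+1
#      pseudocount so unseen alleles never yield a zero background)
#   4. allele fraction >= 3 x the allele fraction in the paired WBC sample
#   5. paired WBC depth >= 20 at the site

#' Build a pileup from aligned reads
#'
#' Walks each read's CIGAR against the reference: mismatching M bases
#' yield SNV alleles; I/D operations yield insertion/deletion alleles
#' anchored at the preceding reference base and left-aligned to the
#' normalized parsimonious representation; soft-clipped bases are
#' excluded. Depth counts reference-consuming operations (M/=/X/D), so a
#' deletion-supporting read covers the deleted positions.
#'
#' @param reads data.frame with columns `chrom`, `pos` (0-based), `cigar`,
#'   `seq`; unaligned rows (`is.na(pos)`) are ignored.
#' @param reference named character vector of contig sequences. A read on
#'   a contig absent from the reference is a hard error.
#' @return A `pileup` object (see [sim_pileup()] for the shape).
#' @export
build_pileup <- function(reads, reference) {
  aligned <- reads[!is.na(reads$pos), , drop = FALSE]
  bad <- setdiff(unique(aligned$chrom), names(reference))
  if (length(bad) > 0) {
    stop("reads reference contig(s) absent from the reference: ",
         paste(bad, collapse = ", "))
  }
  lens <- nchar(reference)
  covd <- lapply(lens, function(L) integer(L + 1L))  # +1 diff slot
  recs <- list()
  for (i in seq_len(nrow(aligned))) {
    chrom <- aligned$chrom[i]
    ref_seq <- reference[[chrom]]
    ops <- cigar_ops(aligned$cigar[i])
    rpos <- aligned$pos[i]   # 0-based reference cursor
    qpos <- 0L               # 0-based query cursor
    seq_ <- aligned$seq[i]
    for (k in seq_along(ops$op)) {
      op <- ops$op[k]; len <- ops$len[k]
      if (op %in% c("M", "=", "X")) {
        q <- substr(seq_, qpos + 1L, qpos + len)
        r <- substr(ref_seq, rpos + 1L, rpos + len)
        if (q != r) {
          qb <- strsplit(q, "")[[1]]
          rb <- strsplit(r, "")[[1]]
          mm <- which(qb != rb)
          for (m in mm) {
            recs[[length(recs) + 1L]] <- list(chrom, rpos + m - 1L,
                                              rb[m], qb[m])
          }
        }
        covd[[chrom]][rpos + 1L] <- covd[[chrom]][rpos + 1L] + 1L
        covd[[chrom]][rpos + len + 1L] <- covd[[chrom]][rpos + len + 1L] - 1L
        rpos <- rpos + len; qpos <- qpos + len
      } else if (op == "I") {
        if (rpos > 0L) {
          anchor <- substr(ref_seq, rpos, rpos)
          ins <- substr(seq_, qpos + 1L, qpos + len)
          nrm <- normalize_allele(ref_seq, rpos - 1L, anchor,
                                  paste0(anchor, ins))
          recs[[length(recs) + 1L]] <- list(chrom, nrm$pos, nrm$ref,
                                            nrm$alt)
        }
        qpos <- qpos + len
      } else if (op == "D") {
        if (rpos > 0L) {
          anchor <- substr(ref_seq, rpos, rpos)
          del <- substr(ref_seq, rpos + 1L, rpos + len)
          nrm <- normalize_allele(ref_seq, rpos - 1L,
                                  paste0(anchor, del), anchor)
          recs[[length(recs) + 1L]] <- list(chrom, nrm$pos, nrm$ref,
                                            nrm$alt)
        }
        covd[[chrom]][rpos + 1L] <- covd[[chrom]][rpos + 1L] + 1L
        covd[[chrom]][rpos + len + 1L] <- covd[[chrom]][rpos + len + 1L] - 1L
        rpos <- rpos + len
      } else if (op %in% c("S", "H", "P")) {
        if (op == "S") qpos <- qpos + len
      } else if (op == "N") {
        rpos <- rpos + len
      }
    }
  }
  sites <- data.frame(
    chrom = rep(names(reference), lens),
    pos = unlist(lapply(lens, function(L) seq_len(L) - 1L),
                 use.names = FALSE),
    ref = unlist(strsplit(paste(reference, collapse = ""), ""),
                 use.names = FALSE),
    depth = unlist(lapply(names(reference), function(ch)
      cumsum(covd[[ch]])[seq_len(lens[[ch]])]), use.names = FALSE),
    stringsAsFactors = FALSE)
  if (length(recs) > 0) {
    al <- data.frame(
      chrom = vapply(recs, `[[`, character(1), 1),
      pos = vapply(recs, `[[`, numeric(1), 2),
      ref = vapply(recs, `[[`, character(1), 3),
      alt = vapply(recs, `[[`, character(1), 4),
      stringsAsFactors = FALSE)
    k <- allele_key(al$chrom, al$pos, al$ref, al$alt)
    first <- !duplicated(k)
    counts <- as.vector(table(k)[k[first]])
    alleles <- al[first, , drop = FALSE]
    alleles$count <- counts
    alleles <- alleles[order(match(alleles$chrom, names(reference)),
                             alleles$pos, alleles$alt), , drop = FALSE]
    rownames(alleles) <- NULL
  } else {
    alleles <- data.frame(chrom = character(0), pos = integer(0),
                          ref = character(0), alt = character(0),
                          count = integer(0))
  }
  structure(list(sample_id = NA_character_, sites = sites,
                 alleles = alleles), class = "pileup")
}

#' Build the WBC-cohort background-error model
#'
#' The background error rate of an allele is its average allele fraction
#' across all WBC samples, estimated from pooled counts with a +1/+1
#' pseudocount: `(total alt reads + 1) / (total WBC depth + 1)`. The
#' pseudocount keeps the background strictly positive so that an allele
#' never observed in any WBC sample cannot trivially satisfy the 25x rule.
#'
#' @param x either a list of WBC `pileup` objects, or a `cfdna_cohort`
#'   (in which case all WBC samples, or `sample_ids`, are streamed from
#'   their per-sample seeds).
#' @param sample_ids optional subset of WBC sample ids when `x` is a
#'   cohort.
#' @return A `background_model` object.
#' @export
build_background <- function(x, sample_ids = NULL) {
  if (inherits(x, "cfdna_cohort")) {
    ids <- sample_ids %||%
      x$samples$sample_id[x$samples$type == "WBC"]
    reference <- x$reference
    get_pileup <- function(i) sim_pileup(x, ids[i])
    n_s <- length(ids)
  } else {
    stopifnot(is.list(x), length(x) > 0, inherits(x[[1]], "pileup"))
    first <- x[[1]]$sites
    reference <- NULL
    get_pileup <- function(i) x[[i]]
    n_s <- length(x)
  }
  p1 <- get_pileup(1)
  sites <- p1$sites
  chroms <- unique(sites$chrom)
  lens <- vapply(chroms, function(ch) sum(sites$chrom == ch), integer(1))
  offs <- setNames(c(0, cumsum(lens))[seq_along(lens)], chroms)
  n <- nrow(sites)
  depth_total <- numeric(n)
  snv_alt <- matrix(0, nrow = n, ncol = 4, dimnames = list(NULL, BASES))
  indel_alt <- new.env(parent = emptyenv())
  for (i in seq_len(n_s)) {
    p <- if (i == 1) p1 else get_pileup(i)
    stopifnot(nrow(p$sites) == n)
    depth_total <- depth_total + p$sites$depth
    a <- p$alleles
    if (nrow(a) == 0) next
    gi <- offs[a$chrom] + a$pos + 1L
    is_snv <- nchar(a$ref) == 1L & nchar(a$alt) == 1L
    if (any(is_snv)) {
      idx <- cbind(gi[is_snv], match(a$alt[is_snv], BASES))
      snv_alt[idx] <- snv_alt[idx] + a$count[is_snv]
    }
    if (any(!is_snv)) {
      keys <- allele_key(a$chrom[!is_snv], a$pos[!is_snv],
                         a$ref[!is_snv], a$alt[!is_snv])
      cnts <- a$count[!is_snv]
      for (j in seq_along(keys)) {
        indel_alt[[keys[j]]] <- (indel_alt[[keys[j]]] %||% 0) + cnts[j]
      }
    }
  }
  structure(list(chroms = chroms, offsets = offs, n_positions = n,
                 n_samples = n_s, depth_total = depth_total,
                 snv_alt = snv_alt, indel_alt = indel_alt),
            class = "background_model")
}

#' Background allele fraction for a set of alleles
#'
#' @param bg a `background_model`.
#' @param chrom,pos,ref,alt vectors describing normalized alleles.
#' @return Numeric vector of pseudocounted background allele fractions.
#' @export
background_af <- function(bg, chrom, pos, ref, alt) {
  stopifnot(inherits(bg, "background_model"))
  gi <- bg$offsets[chrom] + pos + 1L
  outside <- is.na(gi) | gi < 1 | gi > bg$n_positions
  if (any(outside)) {
    # no cohort data: the pseudocount rule gives (0+1)/(0+1) = 1, which
    # conservatively blocks the 25x condition at uncovered sites
    for (ch in unique(chrom[outside])) {
      message("background model has no territory for contig ", ch,
              "; pseudocount fallback applied")
    }
    gi[outside] <- NA_integer_
  }
  is_snv <- nchar(ref) == 1L & nchar(alt) == 1L
  alt_total <- numeric(length(gi))
  idx <- is_snv & !outside
  if (any(idx)) {
    alt_total[idx] <- bg$snv_alt[cbind(gi[idx], match(alt[idx], BASES))]
  }
  idx <- !is_snv & !outside
  if (any(idx)) {
    keys <- allele_key(chrom[idx], pos[idx], ref[idx], alt[idx])
    alt_total[idx] <- vapply(keys, function(k)
      bg$indel_alt[[k]] %||% 0, numeric(1))
  }
  depth <- ifelse(outside, 0, bg$depth_total[gi])
  (alt_total + 1) / (depth + 1)
}

#' Call somatic mutations in a cfDNA sample against its paired WBC sample
#'
#' Applies the five filter conditions (see the file header) to every
#' non-reference allele of the cfDNA pileup. Each condition's pass/fail is
#' reported per candidate for audit; a call is emitted iff all five pass.
#' Multi-allelic sites are evaluated per allele. With the paired WBC
#' allele fraction at 0, the 3x rule is satisfied by any allele fraction
#' (no pseudocount on the paired sample; the cohort background rule is the
#' noise guard).
#'
#' @param cfdna,wbc `pileup` objects for the paired samples.
#' @param background a `background_model` built from the WBC cohort.
#' @param min_af minimum alternate allele fraction (default 0.01).
#' @param min_reads minimum supporting reads (default 10).
#' @param bg_ratio required AF fold-change over the cohort background
#'   error rate (default 25).
#' @param wbc_ratio required AF fold-change over the paired WBC allele
#'   fraction (default 3).
#' @param min_wbc_depth minimum paired WBC depth at the site (default 20).
#' @param keep_filtered if TRUE, return every candidate allele with its
#'   filter flags; otherwise only emitted calls (default).
#' @return data.frame of class `somatic_calls`: `chrom`, `pos` (0-based),
#'   `ref`, `alt`, `alt_reads`, `depth`, `af`, `background_af`, `wbc_af`,
#'   `wbc_depth`, the five filter flags (`flag_af`, `flag_support`,
#'   `flag_background`, `flag_wbc_ratio`, `flag_wbc_depth`) and `pass`.
#' @export
call_somatic <- function(cfdna, wbc, background,
                         min_af = 0.01, min_reads = 10, bg_ratio = 25,
                         wbc_ratio = 3, min_wbc_depth = 20,
                         keep_filtered = FALSE) {
  stopifnot(inherits(cfdna, "pileup"), inherits(wbc, "pileup"),
            inherits(background, "background_model"))
  cand <- cfdna$alleles
  empty <- data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      alt_reads = integer(0), depth = integer(0),
                      af = numeric(0), background_af = numeric(0),
                      wbc_af = numeric(0), wbc_depth = integer(0),
                      flag_af = logical(0), flag_support = logical(0),
                      flag_background = logical(0),
                      flag_wbc_ratio = logical(0),
                      flag_wbc_depth = logical(0), pass = logical(0))
  if (nrow(cand) == 0) return(structure(empty, class = c("somatic_calls",
                                                         "data.frame")))
  site_key <- paste0(cfdna$sites$chrom, ":", cfdna$sites$pos)
  depth <- cfdna$sites$depth[match(paste0(cand$chrom, ":", cand$pos),
                                   site_key)]
  wbc_site_key <- paste0(wbc$sites$chrom, ":", wbc$sites$pos)
  wbc_depth <- wbc$sites$depth[match(paste0(cand$chrom, ":", cand$pos),
                                     wbc_site_key)]
  wbc_depth[is.na(wbc_depth)] <- 0L
  wk <- allele_key(wbc$alleles$chrom, wbc$alleles$pos, wbc$alleles$ref,
                   wbc$alleles$alt)
  wbc_count <- wbc$alleles$count[match(
    allele_key(cand$chrom, cand$pos, cand$ref, cand$alt), wk)]
  wbc_count[is.na(wbc_count)] <- 0L
  af <- cand$count / depth
  wbc_af <- ifelse(wbc_depth > 0, wbc_count / wbc_depth, 0)
  bg_af <- background_af(background, cand$chrom, cand$pos, cand$ref,
                         cand$alt)
  res <- data.frame(
    chrom = cand$chrom, pos = cand$pos, ref = cand$ref, alt = cand$alt,
    alt_reads = cand$count, depth = depth, af = af,
    background_af = as.numeric(bg_af), wbc_af = wbc_af,
    wbc_depth = wbc_depth,
    flag_af = af >= min_af,
    flag_support = cand$count >= min_reads,
    flag_background = af >= bg_ratio * bg_af,
    flag_wbc_ratio = af >= wbc_ratio * wbc_af,
    flag_wbc_depth = wbc_depth >= min_wbc_depth,
    stringsAsFactors = FALSE)
  res$pass <- res$flag_af & res$flag_support & res$flag_background &
    res$flag_wbc_ratio & res$flag_wbc_depth
  if (!keep_filtered) res <- res[res$pass, , drop = FALSE]
  rownames(res) <- NULL
  structure(res, class = c("somatic_calls", "data.frame"))
}
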