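# Read-level simulation: fixed-length 150 bp paired-end fragments with
# uniform start positions over each panel contig. Intended for small
# configurations (unit and integration tests); cohort-scale runs use the
# pileup channel.

#' Materialize aligned reads for one simulated sample
#'
#' Fragments of length `2 * read_len` are placed uniformly over each
#' contig; each fragment yields two abutting reads stored in reference
#' orientation. A fragment overlapping a planted variant carries it with
#' probability equal to the variant's allele fraction (0.5 for germline
#' SNPs; `ctdna * clonality / 2` for somatic events in cfDNA). Carried
#' SNVs and short indels are encoded in the sequence and CIGAR; reads
#' crossing a large-indel junction are emitted unaligned (or soft-clipped,
#' per `unaligned_fraction`). I.i.d. substitution errors are applied to
#' every read.
#'
#' @param sim a `cfdna_cohort`.
#' @param sample_id sample identifier.
#' @param contigs optional subset of contig names.
#' @return data.frame of reads: `read_id`, `mate`, `flag`, `chrom`, `pos`
#'   (0-based; NA for unaligned), `cigar`, `seq`, `qual`.
#' @export
sim_reads <- function(sim, sample_id, contigs = NULL) {
  stopifnot(inherits(sim, "cfdna_cohort"))
  info <- sim$samples[match(sample_id, sim$samples$sample_id), ]
  if (is.na(info$seed)) stop("unknown sample_id: ", sample_id)
  cfg <- sim$config
  set.seed(info$seed + 2L)
  rl <- cfg$read_len
  contigs <- contigs %||% names(sim$reference)

  # variants carried by this sample: germline SNPs + somatic events
  germ <- sim$germline[sim$germline$patient == info$patient, , drop = FALSE]
  vars <- data.frame(chrom = germ$chrom, pos = germ$pos, ref = germ$ref,
                     alt = germ$alt, af = rep(0.5, nrow(germ)),
                     large = FALSE, stringsAsFactors = FALSE)
  if (info$type == "cfDNA") {
    ev <- sim$events[sim$events$patient == info$patient &
                     sim$events$timepoint_from <= info$timepoint, ,
                     drop = FALSE]
    if (nrow(ev) > 0) {
      vars <- rbind(vars, data.frame(
        chrom = ev$chrom, pos = ev$pos, ref = ev$ref, alt = ev$alt,
        af = info$ctdna_fraction * ev$clonality / 2,
        large = ev$type != "SNV" & ev$length >= cfg$large_indel_min,
        stringsAsFactors = FALSE))
    }
  }

  out <- list()
  for (chrom in contigs) {
    ref_seq <- sim$reference[[chrom]]
    L <- nchar(ref_seq)
    fl <- 2L * rl
    # interior coverage ~ n_frag * fl / (L - fl + 1); solve for the mean
    n_frag <- round(cfg$panel_depth_mean * (L - fl + 1L) / fl)
    starts <- sample.int(L - fl + 1L, n_frag, replace = TRUE) - 1L
    frag_id <- sprintf("%s_%s_f%06d", sample_id, chrom, seq_len(n_frag))
    cv <- vars[vars$chrom == chrom, , drop = FALSE]
    # fragment -> carried variant (first overlapping variant that the
    # Bernoulli(af) draw assigns; variants are sparse so multi-overlap is
    # negligible and resolved in favor of the first)
    carried <- rep(NA_integer_, n_frag)
    if (nrow(cv) > 0) {
      for (vi in seq_len(nrow(cv))) {
        span_end <- cv$pos[vi] + max(nchar(cv$ref[vi]), 1L)
        hit <- which(is.na(carried) & starts < span_end &
                     starts + fl > cv$pos[vi])
        if (length(hit) == 0) next
        take <- hit[runif(length(hit)) < cv$af[vi]]
        carried[take] <- vi
      }
    }
    for (mate in 1:2) {
      r_start <- starts + (mate - 1L) * rl
      seqs <- substring(ref_seq, r_start + 1L, r_start + rl)
      reads <- data.frame(
        read_id = frag_id, mate = mate,
        flag = if (mate == 1) 0L else 16L, chrom = chrom, pos = r_start,
        cigar = paste0(rl, "M"), seq = seqs,
        stringsAsFactors = FALSE)
      idx <- which(!is.na(carried))
      for (fi in idx) {
        v <- cv[carried[fi], ]
        rd <- build_variant_read(ref_seq, r_start[fi], rl, v,
                                 cfg$unaligned_fraction)
        reads$pos[fi] <- rd$pos
        reads$cigar[fi] <- rd$cigar
        reads$seq[fi] <- rd$seq
        if (is.na(rd$pos)) reads$flag[fi] <- 4L
      }
      out[[length(out) + 1L]] <- reads
    }
  }
  reads <- do.call(rbind, out)
  # i.i.d. substitution errors
  n_err <- rbinom(1, nrow(reads) * rl, cfg$per_base_error)
  if (n_err > 0) {
    at <- sample.int(nrow(reads) * rl, n_err)
    ri <- (at - 1L) %/% rl + 1L
    off <- (at - 1L) %% rl + 1L
    for (k in seq_len(n_err)) {
      b <- substr(reads$seq[ri[k]], off[k], off[k])
      substr(reads$seq[ri[k]], off[k], off[k]) <-
        sample(setdiff(BASES, b), 1)
    }
  }
  reads$qual <- strrep(rawToChar(as.raw(37 + 33)), rl)
  rownames(reads) <- NULL
  reads
}

# Build one read of a variant-carrying fragment. v: one row with pos, ref,
# alt (normalized, shared anchor base for indels), af, large.
build_variant_read <- function(ref_seq, s, rl, v, unaligned_fraction) {
  jd <- v$pos + 1L  # donor coordinate of first base after the anchor
  ins <- substr(v$alt, 2L, nchar(v$alt))
  del_len <- nchar(v$ref) - 1L
  ins_len <- nchar(ins)
  if (nchar(v$ref) == 1L && nchar(v$alt) == 1L) {
    # SNV
    seq_ <- substr(ref_seq, s + 1L, s + rl)
    if (v$pos >= s && v$pos < s + rl) {
      substr(seq_, v$pos - s + 1L, v$pos - s + 1L) <- v$alt
    }
    return(list(pos = s, cigar = paste0(rl, "M"), seq = seq_))
  }
  if (del_len > 0L) {
    # deletion: donor = ref with [jd, jd + del_len) removed
    donor_base <- function(d) ifelse(d < jd, d, d + del_len)
    d <- s:(s + rl - 1L)
    refpos <- donor_base(d)
    seq_ <- paste(substring(ref_seq, refpos + 1L, refpos + 1L),
                  collapse = "")
    if (s + rl <= jd) {
      return(list(pos = s, cigar = paste0(rl, "M"), seq = seq_))
    }
    if (s >= jd) {
      return(list(pos = s + del_len, cigar = paste0(rl, "M"), seq = seq_))
    }
    if (v$large && runif(1) < unaligned_fraction) {
      return(list(pos = NA_integer_, cigar = "*", seq = seq_))
    }
    a <- jd - s
    if (v$large) {
      return(list(pos = s, cigar = paste0(a, "M", rl - a, "S"),
                  seq = seq_))
    }
    return(list(pos = s,
                cigar = paste0(a, "M", del_len, "D", rl - a, "M"),
                seq = seq_))
  }
  # insertion: donor = ref with `ins` inserted before ref position jd
  hap_at <- function(d) {
    ifelse(d < jd, substring(ref_seq, d + 1L, d + 1L),
      ifelse(d < jd + ins_len, substring(ins, d - jd + 1L, d - jd + 1L),
             substring(ref_seq, d - ins_len + 1L, d - ins_len + 1L)))
  }
  d <- s:(s + rl - 1L)
  seq_ <- paste(hap_at(d), collapse = "")
  if (s + rl <= jd) {
    return(list(pos = s, cigar = paste0(rl, "M"), seq = seq_))
  }
  if (s >= jd + ins_len) {
    return(list(pos = s - ins_len, cigar = paste0(rl, "M"), seq = seq_))
  }
  if (v$large && runif(1) < unaligned_fraction) {
    return(list(pos = NA_integer_, cigar = "*", seq = seq_))
  }
  if (s >= jd) {
    # starts inside the inserted bases: clip the inserted head
    c_ <- jd + ins_len - s
    return(list(pos = jd, cigar = paste0(c_, "S", rl - c_, "M"),
                seq = seq_))
  }
  a <- jd - s
  if (v$large || a + ins_len >= rl) {
    return(list(pos = s, cigar = paste0(a, "M", rl - a, "S"), seq = seq_))
  }
  return(list(pos = s,
              cigar = paste0(a, "M", ins_len, "I", rl - a - ins_len, "M"),
              seq = seq_))
}
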