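# Split-read large-indel detection: unaligned reads are split into two
# 30 bp anchors, anchors are placed by unique exact match against the
# reference, discordant anchor pairs are refined to a junction and grouped
# by breakpoint signature, fragments are deduplicated by read start
# position, and events supported by >= 3 unique fragments up to 500 bp are
# called.

#' Split unaligned reads into 5' and 3' anchors
#'
#' @param reads data.frame with `read_id` and `seq`; reads shorter than
#'   `2 * anchor_len` are skipped (counted in the `skipped` attribute).
#' @param anchor_len anchor length in bp (default 30).
#' @return data.frame of anchors: `read_id`, `side`
#'   (`five_prime`/`three_prime`), `seq`, `read_len`; attribute `skipped`
#'   counts the reads too short to split.
#' @export
split_reads <- function(reads, anchor_len = 30) {
  len <- nchar(reads$seq)
  ok <- len >= 2 * anchor_len
  r <- reads[ok, , drop = FALSE]
  out <- rbind(
    data.frame(read_id = r$read_id, side = "five_prime",
               seq = substr(r$seq, 1L, anchor_len),
               read_len = nchar(r$seq), stringsAsFactors = FALSE),
    data.frame(read_id = r$read_id, side = "three_prime",
               seq = substr(r$seq, nchar(r$seq) - anchor_len + 1L,
                            nchar(r$seq)),
               read_len = nchar(r$seq), stringsAsFactors = FALSE))
  out <- out[order(match(out$read_id, r$read_id)), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, skipped = sum(!ok), anchor_len = anchor_len)
}

#' Place anchors on the reference by unique exact match
#'
#' Exact matching on both strands (k-mer length = anchor length). Anchors
#' with exactly one hit across all contigs and strands are placed; anchors
#' with zero or multiple hits are dropped and counted.
#'
#' @param anchors data.frame from [split_reads()].
#' @param reference named character vector of contig sequences.
#' @return data.frame of placed anchors: input columns plus `chrom`, `pos`
#'   (0-based), `strand`; attributes `unmatched` and `ambiguous` count the
#'   dropped anchors.
#' @export
align_anchors <- function(anchors, reference) {
  dss <- Biostrings::DNAStringSet(reference)
  anchor_len <- unique(nchar(anchors$seq))
  stopifnot(length(anchor_len) == 1)
  place <- function(seqs) {
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(seqs))
    hits <- vector("list", length(seqs))
    for (ci in seq_along(dss)) {
      m <- Biostrings::matchPDict(pd, dss[[ci]])
      st <- Biostrings::startIndex(m)
      for (ai in seq_along(seqs)) {
        if (length(st[[ai]]) > 0) {
          hits[[ai]] <- rbind(hits[[ai]],
                              cbind(ci, st[[ai]] - 1L))
        }
      }
    }
    hits
  }
  fwd <- place(anchors$seq)
  rev_ <- place(revcomp(anchors$seq))
  n_hits <- vapply(fwd, NROW, integer(1)) + vapply(rev_, NROW, integer(1))
  placed <- which(n_hits == 1L)
  res <- anchors[placed, , drop = FALSE]
  if (length(placed) > 0) {
    hit <- lapply(placed, function(i) {
      if (NROW(fwd[[i]]) == 1) c(fwd[[i]], 1L) else c(rev_[[i]], -1L)
    })
    hit <- do.call(rbind, hit)
    res$chrom <- names(reference)[hit[, 1]]
    res$pos <- hit[, 2]
    res$strand <- ifelse(hit[, 3] == 1L, "+", "-")
  } else {
    res$chrom <- character(0); res$pos <- integer(0)
    res$strand <- character(0)
  }
  rownames(res) <- NULL
  structure(res, unmatched = sum(n_hits == 0L),
            ambiguous = sum(n_hits > 1L),
            anchor_len = attr(anchors, "anchor_len") %||% anchor_len)
}

#' Group discordant anchor pairs into breakpoint clusters
#'
#' A pair is concordant iff both anchors are placed on the same contig and
#' strand with reference gap equal to `read_len - 2 * anchor_len`;
#' anything else is discordant. For each same-strand discordant pair the
#' junction is refined by maximal forward extension of the 5' anchor along
#' the reference, giving the left breakpoint, and the implied event size
#' `delta` = reference gap - read gap (> 0 deletion, < 0 insertion).
#' Pairs are clustered by breakpoint signature: same contig, same event
#' orientation, junction and delta within `pos_tolerance`. Signatures that
#' are not a deletion/insertion geometry (e.g. strand-discordant anchors)
#' are reported as unclassified rearrangements.
#'
#' @param anchors placed anchors from [align_anchors()].
#' @param reads the original reads data.frame (for junction refinement).
#' @param reference named character vector.
#' @param pos_tolerance clustering tolerance in bp (default 5).
#' @return list of `breakpoint_cluster` objects: each a list with
#'   `chrom`, `left_bp`, `right_bp`, `event` (`deletion`/`insertion`/
#'   `unclassified`), `length`, and `members` (data.frame `read_id`,
#'   `start`, `left_bp`, `delta`).
#' @export
cluster_discordant <- function(anchors, reads, reference,
                               pos_tolerance = 5) {
  al <- attr(anchors, "anchor_len") %||% unique(nchar(anchors$seq))
  five <- anchors[anchors$side == "five_prime", , drop = FALSE]
  three <- anchors[anchors$side == "three_prime", , drop = FALSE]
  ids <- intersect(five$read_id, three$read_id)
  pairs <- list()
  for (id in ids) {
    a5 <- five[match(id, five$read_id), ]
    a3 <- three[match(id, three$read_id), ]
    read_seq <- reads$seq[match(id, reads$read_id)]
    rl <- nchar(read_seq)
    if (a5$strand != a3$strand || a5$chrom != a3$chrom) {
      pairs[[length(pairs) + 1L]] <- data.frame(
        read_id = id, chrom = a5$chrom, start = a5$pos,
        left_bp = a5$pos + al, delta = NA_integer_,
        stringsAsFactors = FALSE)
      next
    }
    if (a5$strand == "-") {
      # transform to forward coordinates: the read is the reverse
      # complement of a forward-strand donor segment
      read_seq <- revcomp(read_seq)
      tmp <- a5
      a5 <- data.frame(pos = a3$pos, chrom = a3$chrom)
      a3 <- data.frame(pos = tmp$pos, chrom = tmp$chrom)
    }
    gap_ref <- a3$pos - (a5$pos + al)
    gap_read <- rl - 2L * al
    delta <- gap_ref - gap_read
    if (delta == 0L) next  # concordant
    # refine junction: extend the 5' anchor match along the reference
    ref_seq <- reference[[a5$chrom]]
    j <- 0L
    max_ext <- rl - al
    while (j < max_ext &&
           a5$pos + al + j < nchar(ref_seq) &&
           substr(read_seq, al + j + 1L, al + j + 1L) ==
           substr(ref_seq, a5$pos + al + j + 1L, a5$pos + al + j + 1L)) {
      j <- j + 1L
    }
    pairs[[length(pairs) + 1L]] <- data.frame(
      read_id = id, chrom = a5$chrom, start = a5$pos,
      left_bp = a5$pos + al + j, delta = delta, stringsAsFactors = FALSE)
  }
  if (length(pairs) == 0L) return(list())
  pairs <- do.call(rbind, pairs)
  clusters <- list()
  grp <- paste0(pairs$chrom, "/",
                ifelse(is.na(pairs$delta), "unclassified",
                       ifelse(pairs$delta > 0, "deletion", "insertion")))
  for (g in unique(grp)) {
    sub <- pairs[grp == g, , drop = FALSE]
    sub <- sub[order(sub$left_bp, sub$delta), , drop = FALSE]
    take <- 1L
    cl_idx <- integer(nrow(sub))
    cl_idx[1] <- take
    for (i in seq_len(nrow(sub))[-1]) {
      prev <- sub[i - 1L, ]
      same <- abs(sub$left_bp[i] - prev$left_bp) <= pos_tolerance &&
        (is.na(sub$delta[i]) ||
         abs(sub$delta[i] - prev$delta) <= pos_tolerance)
      if (!same) take <- take + 1L
      cl_idx[i] <- take
    }
    for (ci in unique(cl_idx)) {
      members <- sub[cl_idx == ci, , drop = FALSE]
      event <- strsplit(g, "/", fixed = TRUE)[[1]][2]
      delta_med <- if (event == "unclassified") NA_integer_ else
        as.integer(round(median(members$delta)))
      left_bp <- as.integer(round(median(members$left_bp)))
      clusters[[length(clusters) + 1L]] <- structure(list(
        chrom = members$chrom[1], left_bp = left_bp,
        right_bp = if (!is.na(delta_med) && delta_med > 0)
          left_bp + delta_med else left_bp,
        event = event,
        length = if (is.na(delta_med)) NA_integer_ else abs(delta_med),
        members = members, unique_fragments = NA_integer_),
        class = "breakpoint_cluster")
    }
  }
  clusters
}

#' Deduplicate the fragments supporting a breakpoint cluster
#'
#' Reads arising from the same original cfDNA fragment are collapsed on
#' identical read start positions; `unique_fragments` is the collapsed
#' count.
#'
#' @param cluster a `breakpoint_cluster`.
#' @return The cluster with `members` collapsed and `unique_fragments`
#'   set.
#' @export
dedupe_fragments <- function(cluster) {
  stopifnot(inherits(cluster, "breakpoint_cluster"))
  keep <- !duplicated(cluster$members$start)
  cluster$members <- cluster$members[keep, , drop = FALSE]
  cluster$unique_fragments <- sum(keep)
  cluster
}

#' Call large indels from deduplicated breakpoint clusters
#'
#' Emits deletion/insertion events supported by at least `min_fragments`
#' unique cfDNA fragments with implied length between 1 and `max_len` bp
#' (longer events are excluded to keep the focus on localized mutational
#' processes). Deleted sequence is read off the reference; inserted
#' sequence is reconstructed by majority vote over the members' junction
#' segments when the insertion fits inside the reads, falling back to the
#' immediately preceding reference segment for tandem-duplication-
#' consistent geometries.
#'
#' @param clusters list of clusters (deduplicated with
#'   [dedupe_fragments()]; non-deduplicated clusters are deduplicated
#'   here).
#' @param reference named character vector.
#' @param reads original reads (for insertion-sequence reconstruction);
#'   optional.
#' @param min_fragments minimum unique fragments (default 3).
#' @param max_len maximum event length in bp (default 500).
#' @return data.frame of events: `chrom`, `left_bp`, `right_bp`, `type`,
#'   `length`, `unique_fragments`, `seq` (deleted/inserted bases when
#'   reconstructible), `seq_source`.
#' @export
call_large_indels <- function(clusters, reference, reads = NULL,
                              min_fragments = 3, max_len = 500) {
  out <- list()
  for (cl in clusters) {
    if (is.na(cl$unique_fragments)) cl <- dedupe_fragments(cl)
    if (cl$event == "unclassified") next
    if (cl$unique_fragments < min_fragments) next
    if (is.na(cl$length) || cl$length < 1 || cl$length > max_len) next
    seq_ <- NA_character_
    src <- NA_character_
    if (cl$event == "deletion") {
      seq_ <- substr(reference[[cl$chrom]], cl$left_bp + 1L,
                     cl$left_bp + cl$length)
      src <- "reference"
    } else {
      # insertion: vote over members whose read fully contains the
      # inserted bases
      if (!is.null(reads)) {
        cands <- character(0)
        for (mi in seq_len(nrow(cl$members))) {
          m <- cl$members[mi, ]
          rs <- reads$seq[match(m$read_id, reads$read_id)]
          off <- cl$left_bp - m$start  # junction offset in the read
          if (!is.na(rs) && off >= 0 && off + cl$length <= nchar(rs)) {
            cands <- c(cands, substr(rs, off + 1L, off + cl$length))
          }
        }
        if (length(cands) > 0) {
          tt <- sort(table(cands), decreasing = TRUE)
          seq_ <- names(tt)[1]
          src <- "reads"
        }
      }
      if (is.na(seq_) && cl$left_bp >= cl$length) {
        # tandem-duplication-consistent fallback
        seq_ <- substr(reference[[cl$chrom]],
                       cl$left_bp - cl$length + 1L, cl$left_bp)
        src <- "tandem_inferred"
      }
    }
    out[[length(out) + 1L]] <- data.frame(
      chrom = cl$chrom, left_bp = cl$left_bp, right_bp = cl$right_bp,
      type = cl$event, length = cl$length,
      unique_fragments = cl$unique_fragments, seq = seq_,
      seq_source = src, stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(chrom = character(0), left_bp = integer(0),
                      right_bp = integer(0), type = character(0),
                      length = integer(0), unique_fragments = integer(0),
                      seq = character(0), seq_source = character(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Detect large indels from unaligned reads (end-to-end)
#'
#' Convenience composition of [split_reads()], [align_anchors()],
#' [cluster_discordant()], [dedupe_fragments()] and
#' [call_large_indels()].
#'
#' @inheritParams split_reads
#' @inheritParams cluster_discordant
#' @inheritParams call_large_indels
#' @return Event data.frame as from [call_large_indels()].
#' @export
detect_large_indels <- function(reads, reference, anchor_len = 30,
                                pos_tolerance = 5, min_fragments = 3,
                                max_len = 500) {
  anchors <- split_reads(reads, anchor_len)
  placed <- align_anchors(anchors, reference)
  clusters <- cluster_discordant(placed, reads, reference, pos_tolerance)
  clusters <- lapply(clusters, dedupe_fragments)
  call_large_indels(clusters, reference, reads,
                    min_fragments = min_fragments, max_len = max_len)
}

#' Generate junction-spanning reads for a planted large indel
#'
#' Test and benchmarking helper: builds the donor haplotype with
#' [plant_large_indel()] and emits `n` unaligned reads with distinct start
#' positions spanning the junction (each anchor fully clear of it).
#'
#' @param reference contig sequence (character scalar).
#' @param chrom contig name to record.
#' @param position,type,length,sequence_rule passed to
#'   [plant_large_indel()].
#' @param n number of distinct-start reads.
#' @param read_len read length (default 150).
#' @param anchor_len anchor length (default 30).
#' @return list with `reads` (data.frame `read_id`, `seq`, `qual`) and
#'   `event` (the planted allele from [plant_large_indel()]).
#' @export
make_junction_reads <- function(reference, chrom, position, type, length,
                                sequence_rule = if (type == "ins")
                                  "tandem" else "random",
                                n = 8, read_len = 150, anchor_len = 30) {
  pl <- plant_large_indel(reference, position, type, length,
                          sequence_rule)
  jd <- pl$junction
  window <- (jd - (read_len - anchor_len)):(jd - anchor_len)
  window <- window[window >= 0 & window + read_len <= nchar(pl$haplotype)]
  stopifnot(length(window) >= n)
  starts <- sort(sample(window, n))
  reads <- data.frame(
    read_id = sprintf("%s_%s%d_r%03d", chrom, type, length, seq_len(n)),
    seq = substring(pl$haplotype, starts + 1L, starts + read_len),
    qual = strrep(rawToChar(as.raw(37 + 33)), read_len),
    stringsAsFactors = FALSE)
  list(reads = reads, event = pl)
}
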