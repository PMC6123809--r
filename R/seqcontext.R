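# Sequence-context characterization of indel loci: GC sliding windows,
# GC-vs-distance profiles around breakpoints, 4-mer neighborhood
# composition, indel mechanism classification, and conservation contrast.

#' GC fraction in a sliding window
#'
#' One value per window start position, step 1. Ambiguous bases (non-ACGT)
#' are excluded from both numerator and denominator; a window with no
#' unambiguous bases yields NA.
#'
#' @param seq DNA sequence (character scalar), at least `window` long.
#' @param window window width in bp (default 20).
#' @return Numeric vector of length `nchar(seq) - window + 1`.
#' @export
gc_sliding <- function(seq, window = 20) {
  n <- nchar(seq)
  stopifnot(n >= window)
  b <- strsplit(seq, "")[[1]]
  gc <- cumsum(c(0, b %in% c("G", "C")))
  valid <- cumsum(c(0, b %in% BASES))
  starts <- seq_len(n - window + 1L)
  num <- gc[starts + window] - gc[starts]
  den <- valid[starts + window] - valid[starts]
  ifelse(den > 0, num / den, NA_real_)
}

#' Mean GC fraction at signed distances around indel breakpoints
#'
#' For each distance d in `[-max_distance, max_distance]`, the mean GC
#' indicator over all breakpoints at offset d from the (left) breakpoint
#' position. Offsets falling outside the reference are excluded from the
#' mean, not padded.
#'
#' @param seq reference sequence of the region (character scalar).
#' @param breakpoints 0-based left-breakpoint positions on `seq`.
#' @param max_distance maximum |distance| in bp.
#' @return data.frame with `distance`, `gc` (mean GC indicator) and `n`
#'   (breakpoints contributing at that distance).
#' @export
gc_around_breakpoints <- function(seq, breakpoints, max_distance) {
  b <- strsplit(seq, "")[[1]]
  is_gc <- b %in% c("G", "C")
  is_valid <- b %in% BASES
  ds <- -max_distance:max_distance
  gc <- numeric(length(ds))
  n <- integer(length(ds))
  for (i in seq_along(ds)) {
    at <- breakpoints + ds[i]
    at <- at[at >= 0 & at < length(b)]
    at <- at[is_valid[at + 1L]]
    n[i] <- length(at)
    gc[i] <- if (length(at) > 0) mean(is_gc[at + 1L]) else NA_real_
  }
  data.frame(distance = ds, gc = gc, n = n)
}

#' k-mer composition of breakpoint neighborhoods vs the whole region
#'
#' Counts overlapping k-mers in the `[bp - flank, bp + flank)` windows
#' around each breakpoint (pooled over breakpoints, windows clipped to the
#' region) and across the entire region, and normalizes both to
#' frequencies. The paired frequencies support enrichment scatter plots
#' and a largest-deviation report. k-mers are counted on the given
#' (reference) strand only.
#'
#' @param seq region sequence (character scalar).
#' @param breakpoints 0-based breakpoint positions on `seq`.
#' @param k k-mer length (default 4).
#' @param flank neighborhood half-width in bp (default 20; must be >= k).
#' @return data.frame with `kmer`, `neighborhood_freq`, `region_freq`,
#'   sorted by decreasing |neighborhood - region| deviation.
#' @export
kmer_neighborhood <- function(seq, breakpoints, k = 4, flank = 20) {
  stopifnot(flank >= k)
  count_kmers <- function(seqs) {
    seqs <- seqs[nchar(seqs) >= k]
    if (length(seqs) == 0) {
      return(setNames(rep(0, 4^k), sort(Biostrings::mkAllStrings(BASES, k))))
    }
    m <- Biostrings::oligonucleotideFrequency(
      Biostrings::DNAStringSet(seqs), width = k)
    colSums(m)
  }
  nb <- substring(seq, pmax(breakpoints - flank, 0) + 1L,
                  pmin(breakpoints + flank, nchar(seq)))
  nb_counts <- count_kmers(nb)
  rg_counts <- count_kmers(seq)
  out <- data.frame(
    kmer = names(rg_counts),
    neighborhood_freq = as.numeric(nb_counts / max(sum(nb_counts), 1)),
    region_freq = as.numeric(rg_counts / max(sum(rg_counts), 1)),
    stringsAsFactors = FALSE)
  out$deviation <- out$neighborhood_freq - out$region_freq
  out[order(-abs(out$deviation)), ]
}

#' Classify the mechanism of a normalized indel
#'
#' A deletion is a `repeat_unit_deletion` iff the deleted sequence equals
#' the immediately adjacent reference segment of the same length on either
#' side (one unit of a tandem repeat removed, e.g. AATAATAAT -> AATAAT).
#' An insertion is a `tandem_duplication` iff the inserted sequence equals
#' the reference segment immediately adjacent to the insertion point (5'
#' in the original representation; after left-alignment the duplicated
#' unit sits immediately 3' of the insertion point, so both sides are
#' tested). Everything else (including SNVs) is `other`. The
#' classification is invariant under left-alignment re-normalization of
#' the same event.
#'
#' @param seq reference contig sequence (character scalar).
#' @param pos 0-based position of the normalized allele (anchor base for
#'   indels).
#' @param ref,alt normalized allele strings.
#' @return One of `"repeat_unit_deletion"`, `"tandem_duplication"`,
#'   `"other"`.
#' @export
classify_indel_mechanism <- function(seq, pos, ref, alt) {
  nrm <- normalize_allele(seq, pos, ref, alt)
  pos <- nrm$pos; ref <- nrm$ref; alt <- nrm$alt
  if (nchar(ref) > nchar(alt)) {
    del <- substr(ref, 2L, nchar(ref))
    L <- nchar(del)
    start <- pos + 1L  # 0-based first deleted base
    left <- if (start >= L) substr(seq, start - L + 1L, start) else ""
    right <- substr(seq, start + L + 1L, start + 2L * L)
    if (identical(del, left) || identical(del, right)) {
      return("repeat_unit_deletion")
    }
    return("other")
  }
  if (nchar(alt) > nchar(ref)) {
    ins <- substr(alt, 2L, nchar(alt))
    L <- nchar(ins)
    end <- pos + 1L  # insertion point: before seq[pos + 1]
    before <- if (end >= L) substr(seq, end - L + 1L, end) else ""
    after <- substr(seq, end + 1L, end + L)
    if (identical(ins, before) || identical(ins, after)) {
      return("tandem_duplication")
    }
    return("other")
  }
  "other"
}

#' Conservation contrast between mutation neighborhoods and the region
#'
#' Compares per-base conservation scores in the +/- `flank` neighborhoods
#' around mutation breakpoints with the region background using the
#' rank-sum test.
#'
#' The reported `mean_region` is the average over the whole region (the
#' natural "region average"); the rank-sum test contrasts the neighborhood
#' values against the *disjoint* background (region positions outside any
#' neighborhood), so that p-values are exactly uniform when neighborhoods
#' are exchangeable with the background.
#'
#' @param scores numeric vector of per-base conservation scores along the
#'   region (index 1 = region position 0).
#' @param breakpoints 0-based breakpoint positions within the region.
#' @param flank neighborhood half-width in bp (default 20).
#' @return list with `mean_neighborhood`, `mean_region` and `p` (rank-sum,
#'   two-sided).
#' @export
conservation_contrast <- function(scores, breakpoints, flank = 20) {
  n <- length(scores)
  idx <- unique(unlist(lapply(breakpoints, function(bp) {
    lo <- max(bp - flank, 0); hi <- min(bp + flank, n - 1L)
    lo:hi
  })))
  nb <- scores[idx + 1L]
  bgv <- scores[-(idx + 1L)]
  if (length(bgv) == 0) bgv <- scores
  list(mean_neighborhood = mean(nb), mean_region = mean(scores),
       p = ranksum_test(nb, bgv))
}
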