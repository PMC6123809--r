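# File interchange: VCF 4.2 output for somatic calls, minimal SAM
# read/write for the simulator's fixed-length reads, background-model and
# cohort TSVs, FASTA via Biostrings.

#' Write somatic calls as VCF 4.2
#'
#' One record per allele; positions are converted from the internal
#' 0-based convention to 1-based VCF coordinates. The five filter
#' quantities (and the region class, when annotated) are carried in INFO;
#' emitted calls have `FILTER=PASS`, audited non-calls carry the names of
#' their failing conditions.
#'
#' @param calls a `somatic_calls` data.frame (optionally with `gene` and
#'   `region` columns), sorted by (chrom, pos); unsorted input is an
#'   error, not silently reordered.
#' @param path output file path.
#' @param sample_id sample name recorded in the header.
#' @param reference optional named character vector to emit contig header
#'   lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, path, sample_id = "SAMPLE",
                      reference = NULL) {
  ord <- order(match(calls$chrom, unique(calls$chrom)), calls$pos)
  if (!identical(ord, seq_len(nrow(calls)))) {
    stop("calls must be sorted by (chrom, pos)")
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=utrscan"),
    sprintf("##sample=%s", sample_id),
    if (!is.null(reference)) {
      sprintf("##contig=<ID=%s,length=%d>", names(reference),
              nchar(reference))
    },
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##INFO=<ID=ALTR,Number=1,Type=Integer,Description=\"Supporting reads\">",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Allele fraction\">",
    "##INFO=<ID=BGAF,Number=1,Type=Float,Description=\"Cohort background allele fraction (pseudocounted)\">",
    "##INFO=<ID=WBCAF,Number=1,Type=Float,Description=\"Paired WBC allele fraction\">",
    "##INFO=<ID=WBCDP,Number=1,Type=Integer,Description=\"Paired WBC depth\">",
    "##INFO=<ID=REGION,Number=1,Type=String,Description=\"Region class\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  recs <- character(0)
  if (nrow(calls) > 0) {
    fail_names <- c(flag_af = "min_af", flag_support = "min_reads",
                    flag_background = "background25x",
                    flag_wbc_ratio = "wbc3x", flag_wbc_depth = "wbc_depth")
    filt <- vapply(seq_len(nrow(calls)), function(i) {
      if (isTRUE(calls$pass[i])) return("PASS")
      bad <- names(fail_names)[!unlist(calls[i, names(fail_names)])]
      paste(fail_names[bad], collapse = ";")
    }, character(1))
    info <- sprintf(
      "DP=%d;ALTR=%d;AF=%s;BGAF=%s;WBCAF=%s;WBCDP=%d",
      calls$depth, calls$alt_reads,
      format(calls$af, digits = 17, trim = TRUE, scientific = FALSE),
      format(calls$background_af, digits = 17, trim = TRUE,
             scientific = FALSE),
      format(calls$wbc_af, digits = 17, trim = TRUE, scientific = FALSE),
      calls$wbc_depth)
    if (!is.null(calls$region)) {
      info <- paste0(info, ";REGION=", calls$region)
    }
    if (!is.null(calls$gene)) {
      info <- paste0(info, ";GENE=", calls$gene)
    }
    recs <- sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\t%s",
                    calls$chrom, calls$pos + 1L, calls$ref, calls$alt,
                    filt, info)
  }
  writeLines(c(hdr, recs), path)
  invisible(path)
}

#' Read a VCF written by [write_vcf()] back into a calls data.frame
#'
#' Positions are converted back to the internal 0-based convention and
#' the five filter quantities are restored bit-exactly from INFO.
#'
#' @param path VCF file path.
#' @return data.frame with the call columns.
#' @export
read_vcf_calls <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      alt_reads = integer(0), depth = integer(0),
                      af = numeric(0), background_af = numeric(0),
                      wbc_af = numeric(0), wbc_depth = integer(0),
                      filter = character(0)))
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  info_get <- function(info, tag) {
    m <- regmatches(info, regexec(paste0("(^|;)", tag, "=([^;]+)"), info))
    vapply(m, function(x) if (length(x)) x[3] else NA_character_,
           character(1))
  }
  info <- vapply(f, `[[`, character(1), 8)
  out <- data.frame(
    chrom = vapply(f, `[[`, character(1), 1),
    pos = as.integer(vapply(f, `[[`, character(1), 2)) - 1L,
    ref = vapply(f, `[[`, character(1), 4),
    alt = vapply(f, `[[`, character(1), 5),
    alt_reads = as.integer(info_get(info, "ALTR")),
    depth = as.integer(info_get(info, "DP")),
    af = as.numeric(info_get(info, "AF")),
    background_af = as.numeric(info_get(info, "BGAF")),
    wbc_af = as.numeric(info_get(info, "WBCAF")),
    wbc_depth = as.integer(info_get(info, "WBCDP")),
    filter = vapply(f, `[[`, character(1), 7),
    stringsAsFactors = FALSE)
  region <- info_get(info, "REGION")
  if (!all(is.na(region))) out$region <- region
  gene <- info_get(info, "GENE")
  if (!all(is.na(gene))) out$gene <- gene
  out
}

#' Write reads as a minimal SAM file
#'
#' Mandatory columns only; soft-clips allowed; unaligned reads carry flag
#' 4 with `*` placeholders. Positions convert to 1-based.
#'
#' @param reads data.frame from [sim_reads()] (or with compatible
#'   columns).
#' @param reference named character vector for the `@SQ` header lines.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, reference, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(reference),
                   nchar(reference)))
  unal <- is.na(reads$pos)
  flag <- if (!is.null(reads$flag)) reads$flag else ifelse(unal, 4L, 0L)
  recs <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                  reads$read_id, flag,
                  ifelse(unal, "*", as.character(reads$chrom)),
                  ifelse(unal, 0L, reads$pos + 1L),
                  ifelse(unal, 0L, 60L),
                  ifelse(unal, "*", reads$cigar),
                  reads$seq, reads$qual)
  writeLines(c(hdr, recs), path)
  invisible(path)
}

#' Read a minimal SAM file
#'
#' @param path SAM file path.
#' @return data.frame with `read_id`, `flag`, `chrom`, `pos` (0-based, NA
#'   for unaligned), `cigar`, `seq`, `qual`.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "@")]
  f <- strsplit(body, "\t", fixed = TRUE)
  flag <- as.integer(vapply(f, `[[`, character(1), 2))
  unal <- bitwAnd(flag, 4L) > 0L
  data.frame(
    read_id = vapply(f, `[[`, character(1), 1), flag = flag,
    chrom = ifelse(unal, NA_character_, vapply(f, `[[`, character(1), 3)),
    pos = ifelse(unal, NA_integer_,
                 as.integer(vapply(f, `[[`, character(1), 4)) - 1L),
    cigar = vapply(f, `[[`, character(1), 6),
    seq = vapply(f, `[[`, character(1), 10),
    qual = vapply(f, `[[`, character(1), 11),
    stringsAsFactors = FALSE)
}

#' Convert between SAM quality strings and Phred score vectors
#'
#' @param qual a quality string (Phred+33).
#' @return Integer vector of Phred scores.
#' @export
qual_to_phred <- function(qual) {
  utf8ToInt(qual) - 33L
}

#' @rdname qual_to_phred
#' @param phred integer vector of Phred scores.
#' @return A quality string.
#' @export
phred_to_qual <- function(phred) {
  intToUtf8(phred + 33L)
}

#' Serialize a background model as TSV
#'
#' One row per (position, allele) with pooled WBC alt reads, plus depth
#' rows (`allele = "."`) recording pooled WBC depth for every position.
#'
#' @param bg a `background_model`.
#' @param path output path.
#' @param sites data.frame with `chrom`, `pos`, `ref` for the model's
#'   positions (e.g. a pileup's `sites`).
#' @return `path`, invisibly.
#' @export
write_background <- function(bg, path, sites) {
  stopifnot(nrow(sites) == bg$n_positions)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("chrom\tpos\tref\talt\tcohort_alt\tcohort_depth", con)
  nz <- which(bg$snv_alt > 0, arr.ind = TRUE)
  lines <- character(0)
  if (nrow(nz) > 0) {
    gi <- nz[, 1]
    lines <- sprintf("%s\t%d\t%s\t%s\t%d\t%d", sites$chrom[gi],
                     sites$pos[gi], sites$ref[gi], BASES[nz[, 2]],
                     as.integer(bg$snv_alt[nz]),
                     as.integer(bg$depth_total[gi]))
  }
  for (k in ls(bg$indel_alt)) {
    p <- strsplit(k, "[:>]")[[1]]  # chrom:pos:ref>alt
    gi <- bg$offsets[p[1]] + as.integer(p[2]) + 1L
    lines <- c(lines, sprintf("%s\t%s\t%s\t%s\t%d\t%d", p[1], p[2], p[3],
                              p[4], as.integer(bg$indel_alt[[k]]),
                              as.integer(bg$depth_total[gi])))
  }
  depth_lines <- sprintf("%s\t%d\t%s\t.\t0\t%d", sites$chrom, sites$pos,
                         sites$ref, as.integer(bg$depth_total))
  writeLines(c(sort(lines), depth_lines), con)
  invisible(path)
}

#' Write a simulated cohort to disk
#'
#' Emits the panel reference (FASTA), gene models (TSV, one row per
#' transcript feature), sample metadata (TSV), the planted truth set
#' (TSV), and per-sample pileup tables (sites + alleles TSVs) or SAM
#' reads. Regenerating with the same configuration produces byte-identical
#' files.
#'
#' @param sim a `cfdna_cohort`.
#' @param dir output directory (created if needed).
#' @param mode `"pileup"` (default) or `"reads"`.
#' @param sample_ids optional subset of samples to write.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir, mode = c("pileup", "reads"),
                         sample_ids = NULL) {
  mode <- match.arg(mode)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dna <- Biostrings::DNAStringSet(sim$reference)
  Biostrings::writeXStringSet(dna, file.path(dir, "reference.fa"))
  feats <- do.call(rbind, lapply(sim$models, function(m) {
    do.call(rbind, lapply(seq_along(m$transcripts), function(ti) {
      tx <- m$transcripts[[ti]]
      ex <- data.frame(gene = m$gene, chrom = m$chrom, strand = m$strand,
                       transcript = tx$id %||% paste0(m$gene, ".", ti),
                       feature = "exon", start = tx$exons[, 1],
                       end = tx$exons[, 2],
                       predominant = ti == m$predominant)
      if (!is.null(tx$cds)) {
        ex <- rbind(ex, data.frame(
          gene = m$gene, chrom = m$chrom, strand = m$strand,
          transcript = tx$id %||% paste0(m$gene, ".", ti),
          feature = "CDS", start = tx$cds[, 1], end = tx$cds[, 2],
          predominant = ti == m$predominant))
      }
      ex
    }))
  }))
  write.table(feats, file.path(dir, "genes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$samples, file.path(dir, "samples.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(truth_set(sim), file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  ids <- sample_ids %||% sim$samples$sample_id
  for (id in ids) {
    if (mode == "pileup") {
      p <- sim_pileup(sim, id)
      write.table(p$sites, file.path(dir, paste0(id, ".sites.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(p$alleles, file.path(dir, paste0(id, ".alleles.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    } else {
      reads <- sim_reads(sim, id)
      write_sam(reads, sim$reference, file.path(dir, paste0(id, ".sam")))
    }
  }
  invisible(dir)
}
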