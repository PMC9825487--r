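# Ribo-seq I/O: collapsed FASTA dialect, alignment ingestion, P-site offset
# calibration and per-transcript P-site profiles.
#
# Collapsed FASTA headers follow the ">ID_xCOUNT" dialect (e.g. ">seq1_x160"
# where 160 is the read multiplicity). Raw hits are rows of
# (transcript_id, tx_pos, read_length, count) with tx_pos the 0-based
# transcript position of the read 5' end.

#' Collapse a FASTA/FASTQ read file into collapsed FASTA
#'
#' Identical sequences (after uppercasing) are merged and their multiplicity
#' recorded in the header. Output order is deterministic: descending count,
#' then sequence.
#'
#' @param input path to a FASTA or FASTQ file (format detected from the
#'   extension, falling back to the first character).
#' @param output path for the collapsed FASTA.
#' @return data.frame (`read_id`, `seq`, `count`), invisibly.
#' @export
collapse_reads <- function(input, output) {
  fmt <- if (grepl("\\.(fastq|fq)(\\.gz)?$", input, ignore.case = TRUE)) {
    "fastq"
  } else if (grepl("\\.(fasta|fa|fna)(\\.gz)?$", input, ignore.case = TRUE)) {
    "fasta"
  } else {
    first <- readChar(input, 1L)
    if (identical(first, "@")) "fastq" else "fasta"
  }
  reads <- tryCatch(
    as.character(Biostrings::readDNAStringSet(input, format = fmt)),
    error = function(e) character(0))
  if (length(reads) == 0L) {
    warning("no reads in '", input, "'; writing empty collapsed FASTA")
    file.create(output)
    return(invisible(data.frame(read_id = character(0), seq = character(0),
                                count = integer(0))))
  }
  tab <- table(toupper(reads))
  df <- data.frame(seq = names(tab), count = as.integer(tab),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$count, df$seq, method = "radix"), , drop = FALSE]
  df$read_id <- sprintf("seq%d", seq_len(nrow(df)))
  df <- df[, c("read_id", "seq", "count")]
  rownames(df) <- NULL
  write_collapsed_fasta(df, output)
  invisible(df)
}

#' Read a collapsed FASTA file
#'
#' @param path collapsed FASTA with ">ID_xCOUNT" headers.
#' @return data.frame (`read_id`, `seq`, `count`); the total library size is
#'   `sum(count)`.
#' @export
read_collapsed_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  hdr <- names(ss)
  m <- regmatches(hdr, regexec("^(.*)_x([0-9]+)$", hdr))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad))
    stop("collapsed FASTA header without _x<count> suffix: '",
         hdr[which(bad)[1L]], "'")
  count <- as.integer(vapply(m, `[`, character(1), 3L))
  if (any(count < 1L))
    stop("collapsed read count must be >= 1 (record '",
         hdr[which(count < 1L)[1L]], "')")
  data.frame(read_id = vapply(m, `[`, character(1), 2L),
             seq = as.character(ss), count = count,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a collapsed FASTA file
#'
#' @param reads data.frame with `read_id`, `seq`, `count`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_collapsed_fasta <- function(reads, path) {
  stopifnot(all(reads$count >= 1L))
  lines <- character(2L * nrow(reads))
  if (nrow(reads) > 0L) {
    lines[c(TRUE, FALSE)] <- sprintf(">%s_x%d", reads$read_id, reads$count)
    lines[c(FALSE, TRUE)] <- reads$seq
  }
  writeLines(lines, path)
  invisible(path)
}

empty_hits <- function() {
  data.frame(transcript_id = character(0), tx_pos = integer(0),
             read_length = integer(0), count = integer(0),
             stringsAsFactors = FALSE)
}

aggregate_hits <- function(df) {
  if (nrow(df) == 0L) return(empty_hits())
  key <- paste(df$transcript_id, df$tx_pos, df$read_length, sep = "\r")
  agg <- rowsum(df$count, key)
  parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
  out <- data.frame(
    transcript_id = vapply(parts, `[`, character(1), 1L),
    tx_pos = as.integer(vapply(parts, `[`, character(1), 2L)),
    read_length = as.integer(vapply(parts, `[`, character(1), 3L)),
    count = as.integer(agg[, 1L]),
    stringsAsFactors = FALSE)
  out <- out[order(out$transcript_id, out$tx_pos, out$read_length,
                   method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Load Ribo-seq alignments into transcript-space raw hits
#'
#' Accepts either the plain P-site TSV dialect (columns `transcript_id`,
#' `tx_pos` (0-based read 5' end), `read_length`, `count`) or a BAM file.
#' BAM records with soft-clipped alignments are excluded, as are
#' multimappers (NH tag > 1; unique mapping by default). Collapsed-read
#' multiplicities are parsed from the read name (`_xCOUNT`) when present.
#' Genome-space records are projected through [genome_to_tx()] onto every
#' strand-matched transcript model; intronic/unmatched records are dropped
#' and counted in the `n_skipped` attribute.
#'
#' @param path TSV or BAM file.
#' @param space `"transcript"` or `"genome"` (alignment coordinate space;
#'   TSV input is always transcript space).
#' @param models named list of [transcript_model()] objects.
#' @param format `"auto"`, `"tsv"` or `"bam"`.
#' @return hits data.frame (`transcript_id`, `tx_pos`, `read_length`,
#'   `count`), aggregated; attribute `n_skipped` counts dropped records.
#' @export
load_alignments <- function(path, space = c("transcript", "genome"),
                            models, format = c("auto", "tsv", "bam")) {
  space <- match.arg(space)
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.bam$", path, ignore.case = TRUE)) "bam" else "tsv"
  if (format == "tsv") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("transcript_id", "tx_pos", "read_length", "count")
    if (!all(need %in% names(df)))
      stop("P-site TSV '", path, "' missing column(s): ",
           paste(setdiff(need, names(df)), collapse = ", "))
    known <- df$transcript_id %in% names(models)
    out <- aggregate_hits(df[known, need, drop = FALSE])
    attr(out, "n_skipped") <- sum(!known)
    return(out)
  }
  bam <- Rsamtools::scanBam(
    path,
    param = Rsamtools::ScanBamParam(
      what = c("qname", "rname", "strand", "pos", "qwidth", "cigar"),
      tag = "NH",
      flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                    isSecondaryAlignment = FALSE)))[[1]]
  n <- length(bam$qname)
  if (n == 0L) {
    out <- empty_hits(); attr(out, "n_skipped") <- 0L
    return(out)
  }
  keep <- !grepl("S", bam$cigar, fixed = TRUE)
  nh <- bam$tag$NH
  if (!is.null(nh)) keep <- keep & (is.na(nh) | nh == 1L)
  skipped <- sum(!keep)
  cnt <- suppressWarnings(
    as.integer(sub("^.*_x([0-9]+)$", "\\1", bam$qname)))
  cnt[is.na(cnt)] <- 1L
  rows <- list()
  idx <- which(keep)
  if (space == "transcript") {
    ok <- as.character(bam$rname[idx]) %in% names(models) &
      as.character(bam$strand[idx]) == "+"
    skipped <- skipped + sum(!ok)
    sel <- idx[ok]
    rows[[1L]] <- data.frame(
      transcript_id = as.character(bam$rname[sel]),
      tx_pos = bam$pos[sel] - 1L,
      read_length = bam$qwidth[sel],
      count = cnt[sel], stringsAsFactors = FALSE)
  } else {
    by_chrom <- split(seq_along(models), vapply(models, `[[`, "", "chrom"))
    for (i in idx) {
      chrom <- as.character(bam$rname[i])
      rstrand <- as.character(bam$strand[i])
      mods <- by_chrom[[chrom]]
      hit <- FALSE
      if (!is.null(mods)) {
        refw <- cigar_ref_width(bam$cigar[i])
        for (j in mods) {
          m <- models[[j]]
          if (m$strand != rstrand) next
          g5 <- if (rstrand == "+") bam$pos[i] - 1L
                else bam$pos[i] - 1L + refw - 1L
          tp <- genome_to_tx(m, g5)
          if (is.na(tp)) next
          rows[[length(rows) + 1L]] <- data.frame(
            transcript_id = m$transcript_id, tx_pos = tp,
            read_length = bam$qwidth[i], count = cnt[i],
            stringsAsFactors = FALSE)
          hit <- TRUE
        }
      }
      if (!hit) skipped <- skipped + 1L
    }
  }
  out <- aggregate_hits(do.call(rbind, c(rows, list(empty_hits()))))
  attr(out, "n_skipped") <- skipped
  out
}

#' Calibrate P-site offsets from CDS start positions
#'
#' For each read length L, the offset is the shift o in `[10, L - 10]` that
#' maximises the translation-boundary contrast: the number of reads whose
#' 5' end + o lands exactly on an annotated CDS start, minus the number
#' landing one codon upstream of it (a position ribosomes do not occupy).
#' The contrast term makes the estimate identifiable even for libraries with
#' flat coverage along the CDS, where the raw start-codon count alone ties
#' across offsets congruent modulo 3. Ties are broken toward the smaller
#' offset. Length classes with fewer than `min_reads` reads (or with no
#' positive contrast at all) fall back to the default offset.
#'
#' @param hits hits data.frame from [load_alignments()].
#' @param models named list of [transcript_model()] objects.
#' @param lengths read lengths to calibrate (default 27:32).
#' @param min_reads minimum reads per length class before estimating.
#' @param default_offset fallback offset (default 12 nt).
#' @return data.frame (`read_length`, `offset`, `n_reads`, `is_default`).
#' @export
estimate_offsets <- function(hits, models, lengths = 27:32,
                             min_reads = 500L, default_offset = 12L) {
  cds_start <- vapply(models, `[[`, integer(1), "cds_tx_start")
  anchored_any <- FALSE
  rows <- lapply(lengths, function(L) {
    sub <- hits[hits$read_length == L, , drop = FALSE]
    n <- sum(sub$count)
    offs <- seq.int(10L, L - 10L)
    if (n < min_reads)
      return(data.frame(read_length = L, offset = default_offset,
                        n_reads = n, is_default = TRUE))
    target <- cds_start[sub$transcript_id]
    score <- vapply(offs, function(o)
      sum(sub$count[sub$tx_pos + o == target]) -
        sum(sub$count[sub$tx_pos + o == target - 3L]), numeric(1))
    if (all(score <= 0))
      return(data.frame(read_length = L, offset = default_offset,
                        n_reads = n, is_default = TRUE))
    anchored_any <<- TRUE
    data.frame(read_length = L, offset = offs[which.max(score)],
               n_reads = n, is_default = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!anchored_any && sum(out$n_reads) > 0L)
    warning("no CDS-anchored reads; all offsets set to default ",
            default_offset)
  rownames(out) <- NULL
  out
}

#' Read/write an offset table as two-column TSV
#' @param path TSV with columns `read_length`, `offset`.
#' @return offset table data.frame.
#' @export
read_offset_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("read_length", "offset") %in% names(df)))
  stopifnot(all(df$offset >= 0L & df$offset < df$read_length))
  df
}

#' @rdname read_offset_table
#' @param offsets offset table data.frame.
#' @export
write_offset_table <- function(offsets, path) {
  utils::write.table(offsets, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Build per-transcript P-site profiles
#'
#' Applies the length-dependent P-site offset to each read's 5' end
#' (P-site = 5' position + offset) and drops reads outside the length
#' filter. Counts within the filter are conserved (no reads created or
#' lost), except reads whose offset P-site would fall outside the
#' transcript.
#'
#' @param hits hits data.frame.
#' @param offsets offset table from [estimate_offsets()] (or a user table).
#' @param models named list of [transcript_model()] objects.
#' @param length_filter read lengths retained (default 27:32).
#' @return named list of `psite_profile` objects, each with
#'   `transcript_id`, `counts` (data.frame `pos`, `read_length`, `count`)
#'   and `total`.
#' @export
build_psite_profiles <- function(hits, offsets, models,
                                 length_filter = 27:32) {
  stopifnot(all(length_filter %in% offsets$read_length))
  off <- stats::setNames(offsets$offset, offsets$read_length)
  sub <- hits[hits$read_length %in% length_filter, , drop = FALSE]
  if (nrow(sub) == 0L) return(structure(list(), names = character(0)))
  sub$pos <- sub$tx_pos + off[as.character(sub$read_length)]
  txlen <- vapply(models, `[[`, integer(1), "tx_length")
  sub <- sub[sub$pos >= 0L & sub$pos < txlen[sub$transcript_id], ,
             drop = FALSE]
  profs <- lapply(split(sub, sub$transcript_id), function(d) {
    key <- paste(d$pos, d$read_length, sep = "\r")
    agg <- rowsum(d$count, key)
    parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
    counts <- data.frame(
      pos = as.integer(vapply(parts, `[`, character(1), 1L)),
      read_length = as.integer(vapply(parts, `[`, character(1), 2L)),
      count = as.integer(agg[, 1L]))
    counts <- counts[order(counts$pos, counts$read_length), , drop = FALSE]
    rownames(counts) <- NULL
    structure(list(transcript_id = d$transcript_id[1L], counts = counts,
                   total = sum(counts$count)),
              class = "psite_profile")
  })
  profs[order(names(profs), method = "radix")]
}

#' @exportS3Method base::print
print.psite_profile <- function(x, ...) {
  cat(sprintf("<psite_profile> %s: %d P-sites at %d positions\n",
              x$transcript_id, x$total, length(unique(x$counts$pos))))
  invisible(x)
}

#' Sum P-site counts of a profile within a transcript interval
#' @param profile a `psite_profile`.
#' @param start,end transcript interval (0-based half-open).
#' @return integer count.
#' @export
psites_in <- function(profile, start, end) {
  if (is.null(profile)) return(0L)
  sel <- profile$counts$pos >= start & profile$counts$pos < end
  sum(profile$counts$count[sel])
}
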