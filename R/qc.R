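# Library-level quality control: read-length distribution, CDS reading-frame
# enrichment, library size, metagene profile, and the three admission gates.

#' Read-length gate
#'
#' Passes when at least `min_frac` of reads fall within
#' `[range_lo, range_hi]` (26-34 nt) *and* the modal length (the peak; ties
#' broken toward the smaller length) lies within `[peak_lo, peak_hi]`
#' (27-32 nt).
#'
#' @param length_hist named integer vector, names = read lengths.
#' @param range_lo,range_hi admissible footprint size range (default 26-34).
#' @param peak_lo,peak_hi admissible peak range (default 27-32).
#' @param min_frac minimum fraction of reads inside the size range
#'   (default 0.9).
#' @return list with `pass`, `peak_length`, `frac_in_range`, `reason`.
#' @export
length_gate <- function(length_hist, range_lo = 26L, range_hi = 34L,
                        peak_lo = 27L, peak_hi = 32L, min_frac = 0.9) {
  if (length(length_hist) == 0L || sum(length_hist) == 0L)
    return(list(pass = FALSE, peak_length = NA_integer_,
                frac_in_range = NA_real_, reason = "empty length histogram"))
  lens <- as.integer(names(length_hist))
  total <- sum(length_hist)
  frac <- sum(length_hist[lens >= range_lo & lens <= range_hi]) / total
  ord <- order(lens)
  lens <- lens[ord]; counts <- as.numeric(length_hist)[ord]
  peak <- lens[which.max(counts)]   # first maximum = smallest length
  pass <- frac >= min_frac && peak >= peak_lo && peak <= peak_hi
  reason <- if (pass) NA_character_
  else if (frac < min_frac)
    sprintf("only %.1f%% of reads within %d-%d nt", 100 * frac,
            range_lo, range_hi)
  else sprintf("peak length %d outside %d-%d nt", peak, peak_lo, peak_hi)
  list(pass = pass, peak_length = peak, frac_in_range = frac,
       reason = reason)
}

#' Reading-frame gate
#'
#' Passes when frame 0 holds the maximum of the three frame counts *and*
#' strictly more than 50% of CDS-mapped P-sites. Frame is defined as
#' `(p_site - cds_tx_start) mod 3` over CDS-internal P-sites only.
#'
#' @param frame_counts numeric vector of length 3 (frames 0, 1, 2).
#' @return list with `pass`, `frame0_fraction`, `reason`.
#' @export
frame_gate <- function(frame_counts) {
  stopifnot(length(frame_counts) == 3L)
  total <- sum(frame_counts)
  if (total <= 0)
    return(list(pass = FALSE, frame0_fraction = NA_real_,
                reason = "no CDS-mapped P-sites"))
  f0 <- frame_counts[[1L]]
  frac <- f0 / total
  pass <- f0 >= max(frame_counts) && frac > 0.5
  reason <- if (pass) NA_character_
  else if (f0 < max(frame_counts)) "frame 0 is not the modal frame"
  else sprintf("frame-0 fraction %.1f%% not larger than 50%%", 100 * frac)
  list(pass = pass, frame0_fraction = frac, reason = reason)
}

#' Library-size gate
#'
#' For a file path, passes when the collapsed FASTA is larger than 5 Mb
#' (5e6 bytes). For an in-memory read count, passes when the total number of
#' reads reaches `min_reads` (default 100,000) — the testable count proxy.
#'
#' @param x path to a collapsed FASTA (character) or total read count
#'   (numeric).
#' @param min_bytes file-size floor in bytes (default 5e6).
#' @param min_reads read-count floor for numeric input (default 1e5).
#' @return list with `pass`, `value`, `mode`.
#' @export
size_gate <- function(x, min_bytes = 5e6, min_reads = 1e5) {
  if (is.character(x)) {
    sz <- file.size(x)
    list(pass = isTRUE(sz > min_bytes), value = sz, mode = "file_bytes")
  } else {
    list(pass = isTRUE(x >= min_reads), value = x, mode = "read_count")
  }
}

# per-nt P-site density of one transcript (counts summed over read lengths)
psite_density <- function(profile, tx_length) {
  d <- numeric(tx_length)
  agg <- rowsum(profile$counts$count, profile$counts$pos)
  d[as.integer(rownames(agg)) + 1L] <- agg[, 1L]
  d
}

# resample a density vector to nbins values at equally spaced relative
# positions (linear interpolation)
rebin <- function(d, nbins) {
  L <- length(d)
  if (L == 0L) return(rep(NA_real_, nbins))
  if (L == 1L) return(rep(d, nbins))
  stats::approx(x = (seq_len(L) - 0.5) / L, y = d,
                xout = (seq_len(nbins) - 0.5) / nbins, rule = 2)$y
}

#' Metagene P-site profile over normalized 5'UTR/CDS/3'UTR bins
#'
#' Each transcript's per-nucleotide P-site density is normalized to mean 1
#' over the transcript, linearly rebinned per region, and averaged over
#' transcripts. Transcripts lacking a region contribute only to the regions
#' they have.
#'
#' @param profiles named list of `psite_profile` objects.
#' @param models named list of [transcript_model()] objects.
#' @param bins bins per region, `c(u5, cds, u3)` (default 50, 100, 50).
#' @return numeric vector of length `sum(bins)` named `u5_*`, `cds_*`,
#'   `u3_*`; attribute `n_transcripts` gives per-region transcript counts.
#' @export
metagene_profile <- function(profiles, models, bins = c(50L, 100L, 50L)) {
  stopifnot(length(bins) == 3L)
  acc <- list(u5 = numeric(bins[1L]), cds = numeric(bins[2L]),
              u3 = numeric(bins[3L]))
  nacc <- c(u5 = 0L, cds = 0L, u3 = 0L)
  for (tid in names(profiles)) {
    m <- models[[tid]]
    if (is.null(m)) next
    prof <- profiles[[tid]]
    if (prof$total == 0L) next
    d <- psite_density(prof, m$tx_length)
    d <- d / mean(d)
    if (m$cds_tx_start > 0L) {
      acc$u5 <- acc$u5 + rebin(d[seq_len(m$cds_tx_start)], bins[1L])
      nacc["u5"] <- nacc["u5"] + 1L
    }
    acc$cds <- acc$cds +
      rebin(d[(m$cds_tx_start + 1L):m$cds_tx_end], bins[2L])
    nacc["cds"] <- nacc["cds"] + 1L
    if (m$cds_tx_end < m$tx_length) {
      acc$u3 <- acc$u3 + rebin(d[(m$cds_tx_end + 1L):m$tx_length], bins[3L])
      nacc["u3"] <- nacc["u3"] + 1L
    }
  }
  out <- c(if (nacc["u5"] > 0L) acc$u5 / nacc["u5"] else acc$u5,
           if (nacc["cds"] > 0L) acc$cds / nacc["cds"] else acc$cds,
           if (nacc["u3"] > 0L) acc$u3 / nacc["u3"] else acc$u3)
  names(out) <- c(sprintf("u5_%d", seq_len(bins[1L])),
                  sprintf("cds_%d", seq_len(bins[2L])),
                  sprintf("u3_%d", seq_len(bins[3L])))
  attr(out, "n_transcripts") <- nacc
  out
}

# frame counts of CDS-internal P-sites across all profiles
cds_frame_counts <- function(profiles, models) {
  f <- c(0, 0, 0)
  for (tid in names(profiles)) {
    m <- models[[tid]]
    if (is.null(m)) next
    cnt <- profiles[[tid]]$counts
    sel <- cnt$pos >= m$cds_tx_start & cnt$pos < m$cds_tx_end
    if (!any(sel)) next
    fr <- (cnt$pos[sel] - m$cds_tx_start) %% 3L
    for (k in 0:2) f[k + 1L] <- f[k + 1L] + sum(cnt$count[sel][fr == k])
  }
  f
}

#' Assemble a library QC report and apply the three admission gates
#'
#' @param hits hits data.frame (read 5' ends; used for the length
#'   histogram and read totals).
#' @param profiles P-site profiles from [build_psite_profiles()].
#' @param models named list of [transcript_model()] objects.
#' @param fasta_path optional collapsed FASTA path; when given, the size
#'   gate uses the file-size rule, otherwise the read-count
#'   proxy.
#' @param bins metagene bins per region.
#' @param ... further arguments passed to [length_gate()] / [size_gate()].
#' @return object of class `qc_report`: read totals, length histogram,
#'   frame counts, metagene vector, the three gate results and the overall
#'   `pass` (conjunction of the gates).
#' @export
qc_report <- function(hits, profiles, models, fasta_path = NULL,
                      bins = c(50L, 100L, 50L), ...) {
  n_reads <- sum(hits$count)
  lh <- rowsum(hits$count, hits$read_length)
  length_hist <- stats::setNames(as.integer(lh[, 1L]), rownames(lh))
  fc <- cds_frame_counts(profiles, models)
  lg <- length_gate(length_hist)
  fg <- frame_gate(fc)
  sg <- if (!is.null(fasta_path)) size_gate(fasta_path) else size_gate(n_reads)
  mg <- metagene_profile(profiles, models, bins = bins)
  structure(list(
    n_reads = n_reads,
    length_hist = length_hist,
    peak_length = lg$peak_length,
    frame_counts = fc,
    frame0_fraction = fg$frame0_fraction,
    metagene = mg,
    gates = list(size_gate = sg$pass, length_gate = lg$pass,
                 frame_gate = fg$pass),
    reasons = list(size = sg, length = lg, frame = fg),
    pass = sg$pass && lg$pass && fg$pass), class = "qc_report")
}

#' @exportS3Method base::print
print.qc_report <- function(x, ...) {
  cat("<qc_report>\n")
  cat(sprintf("  reads: %d   peak length: %s nt   frame-0: %s\n",
              x$n_reads, x$peak_length,
              ifelse(is.na(x$frame0_fraction), "NA",
                     sprintf("%.1f%%", 100 * x$frame0_fraction))))
  g <- x$gates
  cat(sprintf("  gates: size %s | length %s | frame %s  =>  %s\n",
              ifelse(g$size_gate, "PASS", "FAIL"),
              ifelse(g$length_gate, "PASS", "FAIL"),
              ifelse(g$frame_gate, "PASS", "FAIL"),
              ifelse(x$pass, "PASS", "FAIL")))
  invisible(x)
}

#' Write a QC report as JSON (and optional TSV vectors for plotting)
#'
#' @param report a `qc_report`.
#' @param json_path output JSON path.
#' @param hist_tsv,metagene_tsv optional TSV paths for the histogram and
#'   metagene vectors.
#' @return `json_path`, invisibly.
#' @export
write_qc_report <- function(report, json_path, hist_tsv = NULL,
                            metagene_tsv = NULL) {
  obj <- list(
    n_reads = report$n_reads,
    peak_length = report$peak_length,
    frame_counts = as.numeric(report$frame_counts),
    frame0_fraction = report$frame0_fraction,
    gates = report$gates,
    pass = report$pass)
  jsonlite::write_json(obj, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  if (!is.null(hist_tsv)) {
    utils::write.table(
      data.frame(read_length = as.integer(names(report$length_hist)),
                 count = as.integer(report$length_hist)),
      hist_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(metagene_tsv)) {
    utils::write.table(
      data.frame(bin = names(report$metagene),
                 density = as.numeric(report$metagene)),
      metagene_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(json_path)
}
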