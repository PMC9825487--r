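# Candidate uORF enumeration, classification, translation, Kozak context
# annotation and isoform collapsing.
#
# A candidate uORF is a start-to-stop ORF whose start codon begins in the
# 5'UTR (tx_start < cds_tx_start). Recognised start codons are ATG plus the
# four most frequently used near-cognate codons (CTG/GTG/TTG/ACG); stop
# codons are TAG/TGA/TAA. ORFs starting at or after the CDS start are never
# uORFs. The minimum length (default 18 nt = 6 codons) applies to the coding
# portion, excluding the stop codon.

# Scan from start position p (0-based, in-frame) to the first stop codon.
# Returns list(tx_end, category, coding_len) or NULL when the ORF is
# discarded (no stop and out of CDS frame, or too short).
scan_orf_from <- function(seq, p, model, min_len_nt) {
  cds <- model$cds_tx_start
  cds_end <- model$cds_tx_end
  len <- nchar(seq)
  frame <- (p - cds) %% 3L
  s <- p
  tx_end <- NA_integer_
  while (s + 3L <= len) {
    if (codon_at(seq, s) %in% STOP_CODONS) { tx_end <- s + 3L; break }
    s <- s + 3L
  }
  if (is.na(tx_end)) {
    # no stop before transcript end: in-frame ORFs share the CDS stop
    # (N-terminal extension); out-of-frame runaway ORFs are discarded
    if (frame != 0L) return(NULL)
    tx_end <- cds_end
  }
  is_nte <- frame == 0L && tx_end > cds
  coding_len <- tx_end - 3L - p
  if (coding_len < min_len_nt) return(NULL)
  category <- classify_uorf(p, tx_end, model)
  list(tx_end = tx_end, category = category, coding_len = coding_len,
       frame = as.integer(frame))
}

#' Classify a uORF span against the host CDS
#'
#' Exactly one of three categories, decided only by the ORF end versus the
#' CDS start and the reading frame relative to the CDS: `non_overlapping`
#' (ends at or before the CDS start), `n_terminal_extension` (in frame with
#' the CDS and overlapping it, sharing its stop), `overlapping_out_of_frame`
#' (overlaps the CDS in a shifted frame).
#'
#' @param tx_start,tx_end uORF span in transcript coordinates (0-based
#'   half-open, stop codon included).
#' @param model the host [transcript_model()].
#' @return character scalar, one of the three categories.
#' @export
classify_uorf <- function(tx_start, tx_end, model) {
  cds <- model$cds_tx_start
  if (tx_start >= cds)
    stop("span does not start in the 5'UTR (tx_start >= cds_tx_start)")
  frame <- (tx_start - cds) %% 3L
  if (tx_end <= cds) return("non_overlapping")
  if (frame == 0L) return("n_terminal_extension")
  "overlapping_out_of_frame"
}

#' Translate a uORF to its peptide
#'
#' Standard genetic code; the first codon is translated as methionine
#' regardless of near-cognate identity (initiator tRNA delivers Met); the
#' stop codon is not included. For an N-terminal extension the "stop" is the
#' CDS stop and the peptide is the N-terminally extended CDS peptide.
#'
#' @param seq transcript sequence (character scalar, DNA letters).
#' @param tx_start,tx_end uORF span (0-based half-open, stop included).
#' @param category uORF category (internal stop checking is skipped for
#'   `n_terminal_extension` only in the sense that its stop is the CDS stop).
#' @return peptide string.
#' @export
translate_uorf <- function(seq, tx_start, tx_end, category = "non_overlapping") {
  stopifnot((tx_end - tx_start) %% 3L == 0L)
  cods <- codons_of(seq, tx_start, tx_end)
  aa <- translate_codons(cods)
  n <- length(aa)
  if (aa[n] == "*") aa <- aa[-n]
  else if (category != "n_terminal_extension")
    stop("uORF span does not end in a stop codon")
  if (any(aa == "*"))
    stop("internal stop codon within uORF span")
  aa[1L] <- "M"
  paste(aa, collapse = "")
}

#' Kozak context strength of a start codon
#'
#' Evaluated on the 7-mer covering positions -3..+4 around the start codon:
#' strong when the -3 base is A/G *and* the +4 base is G; moderate when
#' exactly one of the two holds; weak when neither. Non-ATG starts and
#' starts whose -3 base (or +4 base) lies outside the transcript are
#' `not_applicable` (the motif definitions are AUG-anchored).
#'
#' @param seq transcript sequence (character scalar).
#' @param tx_start 0-based position of the start codon's first base.
#' @param start_codon the start codon at `tx_start`.
#' @return one of `"strong"`, `"moderate"`, `"weak"`, `"not_applicable"`.
#' @export
kozak_strength <- function(seq, tx_start, start_codon) {
  if (start_codon != "ATG") return("not_applicable")
  if (tx_start < 3L || tx_start + 4L > nchar(seq)) return("not_applicable")
  m3 <- substr(seq, tx_start - 2L, tx_start - 2L)   # -3 base
  p4 <- substr(seq, tx_start + 4L, tx_start + 4L)   # +4 base
  a <- m3 %in% c("A", "G")
  b <- p4 == "G"
  if (a && b) "strong" else if (a || b) "moderate" else "weak"
}

# encode genomic blocks as "chrom:strand:s1-e1|s2-e2"
encode_blocks <- function(model, tx_start, tx_end) {
  b <- tx_to_genome(model, tx_start, tx_end)
  paste0(model$chrom, ":", model$strand, ":",
         paste(sprintf("%d-%d", b[, 1L], b[, 2L]), collapse = "|"))
}

empty_candidates <- function() {
  data.frame(uorf_id = character(0), transcript_id = character(0),
             gene_id = character(0), tx_start = integer(0),
             tx_end = integer(0), start_codon = character(0),
             category = character(0), frame_vs_cds = integer(0),
             coding_len = integer(0), cds_tx_start = integer(0),
             kozak = character(0), peptide = character(0),
             genomic_blocks = character(0),
             member_transcripts = character(0),
             stringsAsFactors = FALSE)
}

#' Enumerate candidate uORFs in a transcript's 5'UTR
#'
#' Finds every occurrence of a start codon upstream of the CDS start, scans
#' in frame to the first stop codon (TAG/TGA/TAA), and emits the ORF when
#' its coding length reaches `min_len_nt`. In-frame ORFs reaching the
#' transcript end without a stop share the CDS stop (N-terminal extension);
#' out-of-frame ORFs without a stop are discarded. ORFs that lie entirely
#' within the CDS are never emitted (the start must precede the CDS start).
#'
#' @param model a [transcript_model()].
#' @param seq the transcript sequence (character scalar, DNA letters,
#'   transcript orientation).
#' @param start_codons recognised start codons.
#' @param min_len_nt minimum coding length in nucleotides, excluding the
#'   stop codon (default 18 nt = 6 amino acids).
#' @return data.frame of candidates (possibly 0-row); columns include the
#'   span, category, reading frame relative to the CDS, Kozak strength,
#'   peptide and genomic blocks.
#' @export
enumerate_candidates <- function(model, seq,
                                 start_codons = START_CODONS,
                                 min_len_nt = 18L) {
  stopifnot(nchar(seq) == model$tx_length)
  cds <- model$cds_tx_start
  if (cds == 0L) return(empty_candidates())
  rows <- list()
  for (p in 0:(cds - 1L)) {
    if (p + 3L > model$tx_length) break
    sc <- codon_at(seq, p)
    if (!sc %in% start_codons) next
    orf <- scan_orf_from(seq, p, model, min_len_nt)
    if (is.null(orf)) next
    rows[[length(rows) + 1L]] <- data.frame(
      uorf_id = sprintf("%s:%d-%d:%s", model$transcript_id, p, orf$tx_end, sc),
      transcript_id = model$transcript_id,
      gene_id = model$gene_id,
      tx_start = p,
      tx_end = orf$tx_end,
      start_codon = sc,
      category = orf$category,
      frame_vs_cds = orf$frame,
      coding_len = orf$coding_len,
      cds_tx_start = cds,
      kozak = kozak_strength(seq, p, sc),
      peptide = translate_uorf(seq, p, orf$tx_end, orf$category),
      genomic_blocks = encode_blocks(model, p, orf$tx_end),
      member_transcripts = model$transcript_id,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) return(empty_candidates())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Enumerate candidates across a set of transcripts
#'
#' @param models named list of [transcript_model()] objects.
#' @param sequences named character vector of transcript sequences.
#' @inheritParams enumerate_candidates
#' @return combined candidate data.frame.
#' @export
enumerate_all_candidates <- function(models, sequences,
                                     start_codons = START_CODONS,
                                     min_len_nt = 18L) {
  dfs <- lapply(models, function(m) {
    s <- sequences[[m$transcript_id]]
    if (is.null(s)) return(empty_candidates())
    enumerate_candidates(m, s, start_codons, min_len_nt)
  })
  out <- do.call(rbind, dfs)
  rownames(out) <- NULL
  out
}

#' Collapse identical uORFs across isoforms
#'
#' uORFs whose genomic block lists (chromosome, strand and block
#' coordinates) are identical are merged into one record listing all
#' supporting transcripts; the merged `uorf_id` is taken from the
#' lexicographically smallest member transcript_id.
#'
#' @param candidates candidate data.frame (from [enumerate_candidates()]),
#'   typically over all transcripts of one gene or a whole annotation.
#' @return data.frame with one row per unique genomic uORF; the
#'   `member_transcripts` column lists supporting transcripts
#'   (comma-separated), `n_isoforms` counts them.
#' @export
collapse_isoforms <- function(candidates) {
  if (nrow(candidates) == 0L) {
    out <- candidates
    out$n_isoforms <- integer(0)
    return(out)
  }
  key <- paste(candidates$genomic_blocks, candidates$start_codon, sep = "@")
  pieces <- split(seq_len(nrow(candidates)), key)
  rows <- lapply(pieces, function(idx) {
    sub <- candidates[idx, , drop = FALSE]
    tids <- sort(unique(sub$transcript_id), method = "radix")
    rep_row <- sub[sub$transcript_id == tids[1L], , drop = FALSE][1L, ]
    rep_row$member_transcripts <- paste(tids, collapse = ",")
    rep_row$n_isoforms <- length(tids)
    rep_row
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$transcript_id, out$tx_start, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write candidate uORFs as TSV
#'
#' Columns mirror the identification table: uORF ID, genomic position,
#' type, start codon, transcript ID, transcript start/end, plus Kozak
#' strength and peptide.
#'
#' @param candidates candidate data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_candidates_tsv <- function(candidates, path) {
  cols <- c("uorf_id", "genomic_blocks", "category", "start_codon",
            "transcript_id", "tx_start", "tx_end", "frame_vs_cds",
            "kozak", "peptide", "member_transcripts")
  cols <- intersect(cols, names(candidates))
  utils::write.table(candidates[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write uORF peptides as FASTA
#'
#' @param candidates candidate data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_peptides_fasta <- function(candidates, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_len(nrow(candidates)))
    writeLines(c(paste0(">", candidates$uorf_id[i]), candidates$peptide[i]),
               con)
  invisible(path)
}
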