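# 5'UTR variant extraction from VCF and classification of variant effects
# on uORF structure.
#
# Effects (one record per variant x uORF, plus gained-start records):
#   uAUG_gained   - the variant creates a new in-UTR start codon that forms
#                   a valid candidate uORF (name retained for gained
#                   near-cognate starts too)
#   uSTART_lost   - an existing candidate's start codon is destroyed
#   uSTOP_lost    - a candidate's stop codon is destroyed (the ORF extends
#                   or disappears)
#   uSTOP_gained  - a new in-frame stop appears upstream of the old one
#   uFrameshift   - an indel of length not divisible by 3 inside a candidate
#                   (not touching its start/stop codons directly)
#   kozak_changed - the -3/+4 context class of an existing ATG start changes
#                   without any codon loss
#   no_uorf_effect otherwise
# Precedence within one uORF: direct start/stop-codon hits > frameshift >
# stop rescan (gain/loss via frame-preserving change) > kozak_changed.

VARIANT_EFFECTS <- c("uAUG_gained", "uSTART_lost", "uSTOP_gained",
                     "uSTOP_lost", "uFrameshift", "kozak_changed",
                     "no_uorf_effect")

# normalize contig naming between VCF and annotation ("chr1" vs "1")
match_chrom <- function(chrom, known) {
  if (chrom %in% known) return(chrom)
  alt <- if (startsWith(chrom, "chr")) sub("^chr", "", chrom)
         else paste0("chr", chrom)
  if (alt %in% known) return(alt)
  NA_character_
}

# project a genomic variant into transcript space for one model.
# Returns NULL when the REF span is not fully and contiguously exonic.
# tx-space convention: replace seq[tx_pos, tx_pos + nchar(ref_tx)) by alt_tx.
variant_to_tx <- function(model, pos1, ref, alt) {
  nref <- nchar(ref)
  g0 <- pos1 - 1L                       # 0-based genomic start of REF
  tpos <- vapply(seq_len(nref) - 1L, function(k) genome_to_tx(model, g0 + k),
                 integer(1))
  if (anyNA(tpos)) return(NULL)
  if (model$strand == "+") {
    if (nref > 1L && any(diff(tpos) != 1L)) return(NULL)  # spans an intron
    list(tx_pos = tpos[1L], ref_tx = ref, alt_tx = alt)
  } else {
    if (nref > 1L && any(diff(tpos) != -1L)) return(NULL)
    list(tx_pos = tpos[nref], ref_tx = revcomp(ref), alt_tx = revcomp(alt))
  }
}

#' Extract 5'UTR variants from a VCF against a transcript set
#'
#' Reads a VCF (SNVs and simple indels), splits multiallelic records per
#' alternate allele, reconciles contig names with the annotation
#' (chr-prefix normalization), and projects each variant onto every
#' transcript of the matching chromosome. One record is emitted per
#' (variant, transcript) pair whose projected REF span lies in the 5'UTR.
#' A deletion spanning the 5'UTR/CDS boundary is flagged
#' (`spans_cds_boundary`) rather than silently dropped.
#'
#' @param vcf_path path to a VCF 4.x file.
#' @param models named list of [transcript_model()] objects.
#' @return data.frame: `variant_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `transcript_id`, `tx_pos`, `ref_tx`, `alt_tx`, `in_5utr`,
#'   `spans_cds_boundary`; attribute `n_skipped_contig` counts variants on
#'   contigs absent from the annotation.
#' @export
extract_utr5_variants <- function(vcf_path, models) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(nrow(fix))) fix <- matrix(fix, nrow = 1,
                                        dimnames = list(NULL, names(fix)))
  known <- unique(vapply(models, `[[`, "", "chrom"))
  by_chrom <- split(names(models), vapply(models, `[[`, "", "chrom"))
  rows <- list()
  n_skip <- 0L
  for (i in seq_len(nrow(fix))) {
    chrom <- match_chrom(fix[i, "CHROM"], known)
    if (is.na(chrom)) { n_skip <- n_skip + 1L; next }
    pos1 <- as.integer(fix[i, "POS"])
    ref <- toupper(fix[i, "REF"])
    alts <- strsplit(toupper(fix[i, "ALT"]), ",", fixed = TRUE)[[1]]
    id <- fix[i, "ID"]
    for (alt in alts) {
      vid <- if (!is.na(id) && nzchar(id) && id != ".") id
             else sprintf("%s:%d:%s>%s", chrom, pos1, ref, alt)
      if (length(alts) > 1L) vid <- paste0(vid, "/", alt)
      for (tid in by_chrom[[chrom]]) {
        m <- models[[tid]]
        tx <- variant_to_tx(m, pos1, ref, alt)
        if (is.null(tx)) next
        span_end <- tx$tx_pos + nchar(tx$ref_tx)       # half-open in tx space
        spans_cds <- tx$tx_pos < m$cds_tx_start && span_end > m$cds_tx_start
        in_utr <- span_end <= m$cds_tx_start
        if (!in_utr && !spans_cds) next
        rows[[length(rows) + 1L]] <- data.frame(
          variant_id = vid, chrom = chrom, pos = pos1, ref = ref, alt = alt,
          transcript_id = tid, tx_pos = tx$tx_pos, ref_tx = tx$ref_tx,
          alt_tx = tx$alt_tx, in_5utr = in_utr,
          spans_cds_boundary = spans_cds, stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(variant_id = character(0), chrom = character(0),
               pos = integer(0), ref = character(0), alt = character(0),
               transcript_id = character(0), tx_pos = integer(0),
               ref_tx = character(0), alt_tx = character(0),
               in_5utr = logical(0), spans_cds_boundary = logical(0),
               stringsAsFactors = FALSE)
  attr(out, "n_skipped_contig") <- n_skip
  rownames(out) <- NULL
  out
}

# apply a tx-space variant to a sequence; returns the mutated sequence
apply_variant_tx <- function(seq, tx_pos, ref_tx, alt_tx) {
  obs <- substr(seq, tx_pos + 1L, tx_pos + nchar(ref_tx))
  if (obs != ref_tx)
    stop("reference allele mismatch at tx position ", tx_pos, ": VCF says '",
         ref_tx, "', transcript has '", obs,
         "' (annotation/genome inconsistency)")
  paste0(substr(seq, 1L, tx_pos),
         alt_tx,
         substr(seq, tx_pos + nchar(ref_tx) + 1L, nchar(seq)))
}

# map an original tx position through the variant (positions inside the
# replaced span map to its start)
map_pos_through <- function(p, tx_pos, nref, delta) {
  ifelse(p <= tx_pos, p, ifelse(p >= tx_pos + nref, p + delta, tx_pos))
}

effect_row <- function(v, uorf_id, effect, detail) {
  data.frame(variant_id = v$variant_id, transcript_id = v$transcript_id,
             uorf_id = uorf_id, effect = effect, detail = detail,
             nt_change = paste0(v$ref_tx, ">", v$alt_tx),
             affects_uorf = effect != "no_uorf_effect",
             stringsAsFactors = FALSE)
}

#' Classify the effect of one 5'UTR variant on uORF structure
#'
#' Applies the alternate allele to the transcript sequence, then evaluates
#' each existing candidate uORF (start-codon destruction, stop-codon
#' destruction, frameshift, in-frame stop gain/loss by rescanning, Kozak
#' class change) and scans the changed window for newly created start
#' codons that form valid candidates in the mutated 5'UTR. Effects on
#' different uORFs are all reported; when nothing is affected a single
#' `no_uorf_effect` record is returned.
#'
#' @param v one row of [extract_utr5_variants()] output (data.frame or list).
#' @param model the transcript's [transcript_model()].
#' @param seq the transcript sequence.
#' @param candidates candidate uORFs of this transcript
#'   (from [enumerate_candidates()]).
#' @param start_codons recognised start codons.
#' @param min_len_nt minimum coding length for a gained candidate.
#' @return data.frame of effect records (`variant_id`, `transcript_id`,
#'   `uorf_id`, `effect`, `detail`, `nt_change`, `affects_uorf`).
#' @export
annotate_effect <- function(v, model, seq, candidates,
                            start_codons = START_CODONS, min_len_nt = 18L) {
  if (isTRUE(v$spans_cds_boundary))
    return(effect_row(v, NA_character_, "no_uorf_effect",
                      "spans_cds_boundary"))
  tx_pos <- v$tx_pos
  nref <- nchar(v$ref_tx); nalt <- nchar(v$alt_tx)
  delta <- nalt - nref
  v_end <- tx_pos + nref                           # half-open REF span
  mut <- apply_variant_tx(seq, tx_pos, v$ref_tx, v$alt_tx)
  cds_new <- model$cds_tx_start + delta            # variant is 5'UTR-contained
  cds_end_new <- model$cds_tx_end + delta
  mut_model <- transcript_model(model$transcript_id, model$gene_id,
                                model$chrom, model$strand, model$exons,
                                0L, 1L)
  mut_model$cds_tx_start <- as.integer(cds_new)    # tx-space scan only; exon
  mut_model$cds_tx_end <- as.integer(cds_end_new)  # blocks are not re-used
  mut_model$tx_length <- nchar(mut)

  cand <- candidates[candidates$transcript_id == model$transcript_id, ,
                     drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(cand))) {
    u <- cand[i, ]
    m_start <- map_pos_through(u$tx_start, tx_pos, nref, delta)
    overlaps_start <- tx_pos < u$tx_start + 3L && v_end > u$tx_start
    stop_start <- u$tx_end - 3L
    overlaps_stop <- u$category != "n_terminal_extension" &&
      tx_pos < u$tx_end && v_end > stop_start
    inside <- tx_pos < u$tx_end && v_end > u$tx_start

    if (overlaps_start) {
      new_codon <- codon_at(mut, m_start)
      if (!new_codon %in% start_codons) {
        out[[length(out) + 1L]] <- effect_row(
          v, u$uorf_id, "uSTART_lost",
          paste0(u$start_codon, "->", new_codon))
        next
      }
    }
    if (overlaps_stop) {
      m_stop <- map_pos_through(stop_start, tx_pos, nref, delta)
      new_codon <- codon_at(mut, m_stop)
      if (!new_codon %in% STOP_CODONS) {
        out[[length(out) + 1L]] <- effect_row(
          v, u$uorf_id, "uSTOP_lost",
          paste0(codon_at(seq, stop_start), "->", new_codon))
        next
      }
    }
    if (inside && delta %% 3L != 0L) {
      out[[length(out) + 1L]] <- effect_row(
        v, u$uorf_id, "uFrameshift", sprintf("indel_%+d_nt", delta))
      next
    }
    if (inside && delta %% 3L == 0L) {
      # frame preserved: rescan from the (possibly shifted) start for the
      # first in-frame stop and compare with the mapped old stop
      orf <- scan_orf_from(mut, m_start, mut_model, 0L)
      old_end_mapped <- map_pos_through(u$tx_end, tx_pos, nref, delta)
      if (is.null(orf)) {
        out[[length(out) + 1L]] <- effect_row(
          v, u$uorf_id, "uSTOP_lost", "no_downstream_stop")
        next
      }
      if (orf$tx_end < old_end_mapped) {
        out[[length(out) + 1L]] <- effect_row(
          v, u$uorf_id, "uSTOP_gained",
          sprintf("stop_moved_%d_nt_upstream", old_end_mapped - orf$tx_end))
        next
      }
      if (orf$tx_end > old_end_mapped &&
          u$category != "n_terminal_extension") {
        out[[length(out) + 1L]] <- effect_row(
          v, u$uorf_id, "uSTOP_lost",
          sprintf("stop_moved_%d_nt_downstream", orf$tx_end - old_end_mapped))
        next
      }
    }
    # kozak context: -3..+4 window around a surviving ATG start
    if (u$start_codon == "ATG" && codon_at(mut, m_start) == "ATG" &&
        tx_pos < u$tx_start + 5L && v_end > u$tx_start - 3L) {
      old_k <- kozak_strength(seq, u$tx_start, "ATG")
      new_k <- kozak_strength(mut, m_start, "ATG")
      if (!identical(old_k, new_k)) {
        out[[length(out) + 1L]] <- effect_row(
          v, u$uorf_id, "kozak_changed", paste0(old_k, "->", new_k))
        next
      }
    }
  }

  # gained starts: codon windows overlapping the changed bases
  if (cds_new > 0L) {
    win_lo <- max(0L, tx_pos - 2L)
    win_hi <- min(cds_new - 1L, tx_pos + nalt + 1L)
    old_starts <- cand$tx_start
    if (win_hi >= win_lo) {
      for (w in win_lo:win_hi) {
        if (w + 3L > nchar(mut)) break
        sc <- codon_at(mut, w)
        if (!sc %in% start_codons) next
        # corresponding original codon (if the window maps cleanly back)
        inv <- w
        if (w > tx_pos) inv <- w - delta
        was_start <- inv >= 0L && inv + 3L <= nchar(seq) &&
          codon_at(seq, inv) %in% start_codons &&
          any(old_starts == inv)
        if (was_start) next
        orf <- scan_orf_from(mut, w, mut_model, min_len_nt)
        if (is.null(orf)) next
        out[[length(out) + 1L]] <- effect_row(
          v, sprintf("%s:%d-%d:%s(gained)", model$transcript_id, w,
                     orf$tx_end, sc),
          "uAUG_gained", sprintf("%s_at_%d", sc, w))
      }
    }
  }

  if (length(out) == 0L)
    return(effect_row(v, NA_character_, "no_uorf_effect", ""))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Annotate all extracted 5'UTR variants of a transcript set
#'
#' @param variants output of [extract_utr5_variants()].
#' @param models,sequences transcript models and sequences.
#' @param candidates candidate data.frame over all transcripts.
#' @inheritParams annotate_effect
#' @return combined effect data.frame.
#' @export
annotate_effects <- function(variants, models, sequences, candidates,
                             start_codons = START_CODONS,
                             min_len_nt = 18L) {
  empty <- data.frame(variant_id = character(0), transcript_id = character(0),
                      uorf_id = character(0), effect = character(0),
                      detail = character(0), nt_change = character(0),
                      affects_uorf = logical(0), stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    annotate_effect(v, models[[v$transcript_id]],
                    sequences[[v$transcript_id]], candidates,
                    start_codons = start_codons, min_len_nt = min_len_nt)
  })
  out <- do.call(rbind, c(rows, list(empty)))
  rownames(out) <- NULL
  out
}

#' Summarize variant effects
#'
#' @param effects effect data.frame from [annotate_effects()].
#' @return list: `class_counts` (named vector over all effect classes),
#'   `nt_change_counts` (table of nucleotide changes among affecting
#'   records), `n_affecting`, `n_total`.
#' @export
summarize_effects <- function(effects) {
  cls <- stats::setNames(integer(length(VARIANT_EFFECTS)), VARIANT_EFFECTS)
  if (nrow(effects) > 0L) {
    tab <- table(effects$effect)
    cls[names(tab)] <- as.integer(tab)
  }
  aff <- effects[effects$affects_uorf, , drop = FALSE]
  nt <- if (nrow(aff)) table(aff$nt_change) else table(character(0))
  list(class_counts = cls, nt_change_counts = nt,
       n_affecting = nrow(aff), n_total = nrow(effects))
}

#' Write variant effects as TSV
#' @param effects effect data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_effects_tsv <- function(effects, path) {
  utils::write.table(effects, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
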