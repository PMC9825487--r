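# Transcript models: exon structure, CDS span and coordinate projection
# between transcript space and genome space.
#
# Conventions: internal coordinates are 0-based half-open in both spaces;
# GTF I/O converts to/from the 1-based inclusive GTF dialect at the boundary.
# Exon rows are stored in transcript orientation (5'->3'), so for a
# minus-strand transcript row 1 is the genomically rightmost exon.

#' Construct a transcript model
#'
#' @param transcript_id,gene_id identifiers.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons two-column integer matrix of genomic intervals
#'   (0-based, half-open), rows ordered 5'->3' in transcript orientation.
#' @param cds_tx_start,cds_tx_end CDS span in transcript coordinates
#'   (0-based half-open, stop codon included).
#' @return an object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand, exons,
                             cds_tx_start, cds_tx_end) {
  exons <- matrix(as.integer(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  stopifnot(strand %in% c("+", "-"), nrow(exons) >= 1L,
            all(exons[, 2L] > exons[, 1L]))
  # non-overlap + 5'->3' order in transcript orientation
  g <- exons[order(exons[, 1L]), , drop = FALSE]
  if (nrow(g) > 1L && any(g[-1L, 1L] < g[-nrow(g), 2L]))
    stop("exons overlap in transcript '", transcript_id, "'")
  ord <- if (strand == "+") order(exons[, 1L]) else order(-exons[, 1L])
  exons <- exons[ord, , drop = FALSE]
  tx_length <- sum(exons[, 2L] - exons[, 1L])
  cds_tx_start <- as.integer(cds_tx_start)
  cds_tx_end <- as.integer(cds_tx_end)
  if (!(cds_tx_start >= 0L && cds_tx_start < cds_tx_end &&
        cds_tx_end <= tx_length))
    stop("invalid CDS span [", cds_tx_start, ", ", cds_tx_end,
         ") for transcript '", transcript_id, "' of length ", tx_length)
  structure(
    list(transcript_id = transcript_id, gene_id = gene_id, chrom = chrom,
         strand = strand, exons = exons, cds_tx_start = cds_tx_start,
         cds_tx_end = cds_tx_end, tx_length = tx_length),
    class = "transcript_model")
}

#' @exportS3Method base::print
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (%s) %s:%s [%d exon(s)] length %d nt\n",
              x$transcript_id, x$gene_id, x$chrom, x$strand,
              nrow(x$exons), x$tx_length))
  cat(sprintf("  CDS tx [%d, %d)  5'UTR %d nt  3'UTR %d nt\n",
              x$cds_tx_start, x$cds_tx_end, x$cds_tx_start,
              x$tx_length - x$cds_tx_end))
  invisible(x)
}

#' 5'UTR length of a transcript model
#' @param model a `transcript_model`.
#' @return integer, number of 5'UTR nucleotides (0 = no 5'UTR).
#' @export
utr5_length <- function(model) model$cds_tx_start

# cumulative transcript offsets of exon starts (internal)
tx_offsets <- function(model) {
  w <- model$exons[, 2L] - model$exons[, 1L]
  cumsum(c(0L, w))
}

#' Project a transcript interval onto the genome
#'
#' Maps a 0-based half-open transcript interval to its genomic blocks
#' (maximal runs within exons). Blocks are returned sorted by genomic start.
#'
#' @param model a `transcript_model`.
#' @param start,end transcript interval, 0-based half-open.
#' @return integer matrix with columns `start`, `end` (genomic, 0-based
#'   half-open); block lengths sum to `end - start`.
#' @export
tx_to_genome <- function(model, start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (!(start >= 0L && start < end && end <= model$tx_length))
    stop("interval [", start, ", ", end, ") outside transcript of length ",
         model$tx_length)
  offs <- tx_offsets(model)
  blocks <- list()
  for (i in seq_len(nrow(model$exons))) {
    ts <- offs[i]; te <- offs[i + 1L]
    a <- max(start, ts); b <- min(end, te)
    if (a >= b) next
    es <- model$exons[i, 1L]; ee <- model$exons[i, 2L]
    if (model$strand == "+") {
      blocks[[length(blocks) + 1L]] <- c(es + (a - ts), es + (b - ts))
    } else {
      blocks[[length(blocks) + 1L]] <- c(ee - (b - ts), ee - (a - ts))
    }
  }
  m <- do.call(rbind, blocks)
  m <- m[order(m[, 1L]), , drop = FALSE]
  dimnames(m) <- list(NULL, c("start", "end"))
  m
}

#' Project a genomic position into transcript coordinates
#'
#' @param model a `transcript_model`.
#' @param genomic_position 0-based genomic position.
#' @return 0-based transcript position, or `NA_integer_` for
#'   intronic/intergenic positions.
#' @export
genome_to_tx <- function(model, genomic_position) {
  g <- as.integer(genomic_position)
  offs <- tx_offsets(model)
  for (i in seq_len(nrow(model$exons))) {
    es <- model$exons[i, 1L]; ee <- model$exons[i, 2L]
    if (g >= es && g < ee) {
      return(unname(if (model$strand == "+") offs[i] + (g - es)
                    else offs[i] + (ee - 1L - g)))
    }
  }
  NA_integer_
}

#' Parse a GTF annotation plus genome FASTA into transcript models
#'
#' Reads exon, CDS and stop_codon features (GENCODE/Ensembl GTF dialect) and
#' extracts spliced transcript sequences from the genome. The CDS span per
#' transcript is the min-max of CDS features; stop_codon features lying
#' outside it are appended (GENCODE convention). Minus-strand sequences are
#' reverse-complemented into transcript orientation. Transcripts lacking
#' exon or CDS features are skipped with a warning; transcripts on
#' chromosomes absent from the FASTA are skipped with a warning. Transcripts
#' without a 5'UTR are retained (they yield no candidate uORFs) and flagged
#' in the returned `no_utr5` vector.
#'
#' @param gtf_path path to a GTF file.
#' @param genome_fasta path to the genome FASTA (or `NULL` to skip
#'   sequence extraction).
#' @return list with `models` (named list of [transcript_model()]),
#'   `sequences` (named character vector, transcript orientation) and
#'   `no_utr5` (named logical).
#' @export
parse_annotation <- function(gtf_path, genome_fasta = NULL) {
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  keep <- S4Vectors::mcols(gr)$type %in% c("exon", "CDS", "stop_codon")
  gr <- gr[keep]
  if (length(gr) == 0L) stop("no exon/CDS features found in '", gtf_path, "'")
  md <- S4Vectors::mcols(gr)
  tid <- as.character(md$transcript_id)
  if (all(is.na(tid))) stop("GTF lacks transcript_id attributes: ", gtf_path)

  genome <- NULL
  if (!is.null(genome_fasta)) {
    genome <- Biostrings::readDNAStringSet(genome_fasta)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }

  models <- list(); seqs <- character(0)
  for (t in unique(tid[!is.na(tid)])) {
    sub <- gr[!is.na(tid) & tid == t]
    type <- as.character(S4Vectors::mcols(sub)$type)
    ex <- sub[type == "exon"]
    cd <- sub[type == "CDS"]
    sc <- sub[type == "stop_codon"]
    if (length(ex) == 0L || length(cd) == 0L) {
      warning("transcript '", t, "' lacks exon or CDS features; skipped")
      next
    }
    chrom <- as.character(GenomicRanges::seqnames(ex))[1]
    strand <- as.character(GenomicRanges::strand(ex))[1]
    if (!strand %in% c("+", "-")) {
      warning("transcript '", t, "' has no strand; skipped")
      next
    }
    gene <- as.character(S4Vectors::mcols(ex)$gene_id)[1]
    if (is.na(gene)) gene <- t
    # GTF 1-based inclusive -> 0-based half-open
    e0 <- cbind(GenomicRanges::start(ex) - 1L, GenomicRanges::end(ex))
    cmin <- min(GenomicRanges::start(cd)) - 1L
    cmax <- max(GenomicRanges::end(cd))
    if (length(sc) > 0L) {
      cmin <- min(cmin, min(GenomicRanges::start(sc)) - 1L)
      cmax <- max(cmax, max(GenomicRanges::end(sc)))
    }
    m <- tryCatch(
      {
        mm <- transcript_model(t, gene, chrom, strand, e0, 0L, 1L)
        five <- if (strand == "+") cmin else cmax - 1L
        three <- if (strand == "+") cmax - 1L else cmin
        cs <- genome_to_tx(mm, five)
        ce <- genome_to_tx(mm, three)
        if (is.na(cs) || is.na(ce))
          stop("CDS span of '", t, "' not contained in its exons")
        transcript_model(t, gene, chrom, strand, e0, cs, ce + 1L)
      },
      error = function(e) { warning(conditionMessage(e)); NULL })
    if (is.null(m)) next
    if (!is.null(genome)) {
      if (!chrom %in% names(genome)) {
        warning("chromosome '", chrom, "' absent from FASTA; transcript '",
                t, "' skipped")
        next
      }
      chromseq <- genome[[chrom]]
      g <- e0[order(e0[, 1L]), , drop = FALSE]
      pieces <- vapply(seq_len(nrow(g)), function(i)
        as.character(Biostrings::subseq(chromseq, g[i, 1L] + 1L, g[i, 2L])),
        character(1))
      s <- paste(pieces, collapse = "")
      if (strand == "-") s <- revcomp(s)
      seqs[[t]] <- toupper(s)
    }
    models[[t]] <- m
  }
  no_utr5 <- vapply(models, function(m) m$cds_tx_start == 0L, logical(1))
  list(models = models, sequences = seqs, no_utr5 = no_utr5)
}

#' Write transcript models back to GTF
#'
#' Emits exon and CDS lines (1-based inclusive). The CDS lines cover the
#' full stored CDS span (stop codon included), so re-parsing with
#' [parse_annotation()] reproduces the model exactly.
#'
#' @param models list of [transcript_model()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_models_gtf <- function(models, path) {
  rows <- lapply(models, function(m) {
    ex <- m$exons[order(m$exons[, 1L]), , drop = FALSE]
    cds_blocks <- tx_to_genome(m, m$cds_tx_start, m$cds_tx_end)
    n_ex <- nrow(ex); n_cd <- nrow(cds_blocks)
    # GTF frame column: offset to the next codon start, per block in
    # transcript order (genome order reversed on the minus strand)
    w <- cds_blocks[, 2L] - cds_blocks[, 1L]
    if (m$strand == "-") w <- rev(w)
    ph <- (3L - cumsum(c(0L, w[-length(w)])) %% 3L) %% 3L
    if (m$strand == "-") ph <- rev(ph)
    data.frame(
      chrom = m$chrom,
      start = c(ex[, 1L] + 1L, cds_blocks[, 1L] + 1L),
      end = c(ex[, 2L], cds_blocks[, 2L]),
      strand = m$strand,
      type = c(rep("exon", n_ex), rep("CDS", n_cd)),
      phase = c(rep(NA_integer_, n_ex), ph),
      transcript_id = m$transcript_id,
      gene_id = m$gene_id,
      stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = df$strand,
    type = df$type, source = "uorfkit", phase = df$phase,
    transcript_id = df$transcript_id, gene_id = df$gene_id)
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Write transcript models or uORF candidates as BED12
#'
#' @param models list of [transcript_model()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_models_bed12 <- function(models, path) {
  lines <- vapply(models, function(m) {
    ex <- m$exons[order(m$exons[, 1L]), , drop = FALSE]
    chrom_start <- ex[1L, 1L]
    thick <- tx_to_genome(m, m$cds_tx_start, m$cds_tx_end)
    paste(m$chrom, chrom_start, ex[nrow(ex), 2L], m$transcript_id, 0L,
          m$strand, thick[1L, 1L], thick[nrow(thick), 2L], "0", nrow(ex),
          paste0(paste(ex[, 2L] - ex[, 1L], collapse = ","), ","),
          paste0(paste(ex[, 1L] - chrom_start, collapse = ","), ","),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
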