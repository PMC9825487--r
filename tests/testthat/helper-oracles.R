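# Independent oracles and fixture builders used across the suite.
# Oracles are deliberately written in a different style from the package
# internals (per-base / per-position brute force) so they cannot share bugs.

STOPS <- c("TAG", "TGA", "TAA")
STARTS5 <- c("ATG", "CTG", "GTG", "TTG", "ACG")

# ---- fixtures ---------------------------------------------------------------

# single-exon plus-strand toy transcript from region strings
make_tx <- function(utr5, cds, utr3 = "", id = "T1", chrom = "c1",
                    strand = "+", gstart = 0L) {
  seq <- paste0(utr5, cds, utr3)
  n <- nchar(seq)
  m <- transcript_model(id, paste0("g_", id), chrom, strand,
                        cbind(gstart, gstart + n),
                        nchar(utr5), nchar(utr5) + nchar(cds))
  list(model = m, seq = seq)
}

# random multi-exon transcript model (structure only, no sequence)
random_model <- function(id = "R1") {
  n_ex <- sample(1:4, 1)
  widths <- sample(10:80, n_ex, replace = TRUE)
  gaps <- if (n_ex > 1) sample(5:50, n_ex - 1, replace = TRUE) else integer(0)
  starts <- cumsum(c(sample(0:100, 1), head(widths, -1) + gaps))
  exons <- cbind(starts, starts + widths)
  L <- sum(widths)
  cs <- sample(0:(L - 2), 1)
  ce <- sample((cs + 1):L, 1)
  transcript_model(id, "g", "chr1", sample(c("+", "-"), 1), exons, cs, ce)
}

# psite_profile from parallel vectors
make_profile <- function(tid, pos, count = 1L, read_length = 28L) {
  if (length(pos) == 0L) {
    return(structure(list(transcript_id = tid,
                          counts = data.frame(pos = integer(0),
                                              read_length = integer(0),
                                              count = integer(0)),
                          total = 0L), class = "psite_profile"))
  }
  df <- data.frame(pos = as.integer(pos),
                   read_length = rep_len(as.integer(read_length), length(pos)),
                   count = rep_len(as.integer(count), length(pos)))
  agg <- stats::aggregate(count ~ pos + read_length, df, sum)
  structure(list(transcript_id = tid,
                 counts = agg[order(agg$pos, agg$read_length), ],
                 total = sum(agg$count)),
            class = "psite_profile")
}

# random 5'UTR/CDS/3'UTR transcript with unconstrained sequence (all 4 bases)
random_seq_tx <- function(id, utr5_max = 600L) {
  u5 <- sample(0:utr5_max, 1)
  n_cod <- sample(10:60, 1)
  cds <- paste0("ATG",
                paste(sample(setdiff(names(Biostrings::GENETIC_CODE),
                                     STOPS), n_cod, replace = TRUE),
                      collapse = ""),
                sample(STOPS, 1))
  u3 <- sample(0:120, 1)
  rand <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                            collapse = "")
  make_tx(rand(u5), cds, rand(u3), id = id,
          strand = sample(c("+", "-"), 1))
}

# ---- coordinate projection oracle ------------------------------------------

# per-base transcript -> genome map built by direct iteration over exon rows
oracle_tx2g_map <- function(model) {
  g <- integer(0)
  for (i in seq_len(nrow(model$exons))) {
    es <- model$exons[i, 1]; ee <- model$exons[i, 2]
    g <- c(g, if (model$strand == "+") seq.int(es, ee - 1L)
           else seq.int(ee - 1L, es))
  }
  g   # g[p + 1] = genomic base of transcript position p
}

# ---- enumeration oracle -----------------------------------------------------

# brute force: tests every upstream position independently; returns a
# data.frame with tx_start, tx_end, start_codon, category
oracle_enumerate <- function(seq, cds_start, cds_end,
                             start_codons = STARTS5, min_len = 18L) {
  n <- nchar(seq)
  out <- list()
  p <- 0L
  while (p < cds_start) {
    if (p + 3L <= n) {
      cod <- substr(seq, p + 1L, p + 3L)
      if (cod %in% start_codons) {
        # walk forward codon by codon for the first stop
        q <- p
        stop_at <- NA_integer_
        while (q + 3L <= n) {
          if (substr(seq, q + 1L, q + 3L) %in% STOPS) { stop_at <- q; break }
          q <- q + 3L
        }
        in_cds_frame <- ((p - cds_start) %% 3L) == 0L
        tx_end <- if (!is.na(stop_at)) stop_at + 3L
                  else if (in_cds_frame) cds_end else NA_integer_
        if (!is.na(tx_end) && (tx_end - 3L - p) >= min_len) {
          category <- if (tx_end <= cds_start) "non_overlapping"
                      else if (in_cds_frame) "n_terminal_extension"
                      else "overlapping_out_of_frame"
          out[[length(out) + 1L]] <- data.frame(
            tx_start = p, tx_end = tx_end, start_codon = cod,
            category = category, stringsAsFactors = FALSE)
        }
      }
    }
    p <- p + 1L
  }
  if (length(out) == 0L)
    return(data.frame(tx_start = integer(0), tx_end = integer(0),
                      start_codon = character(0), category = character(0)))
  do.call(rbind, out)
}

cand_key <- function(d) {
  if (nrow(d) == 0L) return(character(0))
  sort(paste(d$tx_start, d$tx_end, d$start_codon, d$category))
}

# ---- misc -------------------------------------------------------------------

write_lines_tmp <- function(lines, ext) {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

md5_tree <- function(dir) {
  fs <- sort(list.files(dir, recursive = TRUE, full.names = TRUE))
  stats::setNames(as.character(tools::md5sum(fs)),
                  basename(fs))
}
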