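# Synthetic-data generation with known ground truth: transcript models and
# sequences with planted uORFs, ribosome-protected-fragment libraries with
# configurable length distribution / frame periodicity / noise, and VCFs
# engineered to produce each variant-effect class.
#
# Background composition is start-codon suppressed so that truth is exact:
# 5'UTR and 3'UTR backgrounds use the {A,C,T} alphabet (every recognised
# start codon contains G, so no accidental starts arise), CDS interiors use
# {A,C,G} (no T, so no stop codons in any reading frame inside the CDS).
# Planted elements are the only start codons upstream of the CDS, hence
# candidate enumeration on a simulated transcript must return exactly the
# planted set.

rand_bases <- function(n, alphabet = c("A", "C", "T")) {
  if (n <= 0L) return(character(0))
  sample(alphabet, n, replace = TRUE)
}

# one planted uORF inside a 5'UTR character vector `utr` (modified in place
# semantics via return). Returns list(utr, tx_start, tx_end, start_codon).
plant_uorf_in_utr <- function(utr, cds_len, category, start_codon, U) {
  if (category == "non_overlapping") {
    lo <- 33L                                    # leave room for a gain site
    k_hi <- min(10L, (U - lo - 6L) %/% 3L)       # interior codons that fit
    if (k_hi < 6L) stop("5'UTR too short to plant a non-overlapping uORF ",
                        "(need >= ", lo + 24L, " nt)")
    k <- if (k_hi == 6L) 6L else sample(6:k_hi, 1L)
    need <- 3L + 3L * k + 3L
    hi <- U - need
    p <- if (hi == lo) lo else sample(lo:hi, 1L)
    interior <- c("A", "A", "A",                 # armed codon for stop gain
                  rand_bases(3L * (k - 1L), c("A", "C")))
    body <- c(strsplit(start_codon, "")[[1]], interior, c("T", "A", "A"))
    utr[(p + 1L):(p + length(body))] <- body
    tx_end <- p + length(body)
  } else if (category == "n_terminal_extension") {
    d <- 3L * sample(2:6, 1L)                    # start d nt upstream, frame 0
    if (U < d + 3L) d <- 3L * (U %/% 3L - 1L)
    if (d < 3L) stop("5'UTR too short to plant an N-terminal extension")
    p <- U - d
    utr[(p + 1L):(p + 3L)] <- strsplit(start_codon, "")[[1]]
    if (d > 3L)
      utr[(p + 4L):U] <- rand_bases(d - 3L, c("A", "C"))
    tx_end <- NA_integer_                        # filled in by caller (CDS end)
  } else {                                       # overlapping_out_of_frame
    f <- sample(1:2, 1L)
    d_opts <- seq.int(4L, min(U - 3L, 30L))
    d_opts <- d_opts[d_opts %% 3L == (3L - f) %% 3L]
    if (length(d_opts) == 0L)
      stop("5'UTR too short to plant an overlapping uORF")
    d <- if (length(d_opts) == 1L) d_opts else sample(d_opts, 1L)
    p <- U - d
    utr[(p + 1L):(p + 3L)] <- strsplit(start_codon, "")[[1]]
    if (d > 3L)
      utr[(p + 4L):U] <- rand_bases(d - 3L, c("A", "C"))
    tx_end <- NA_integer_                        # shifted stop planted in CDS
    attr(utr, "overlap_frame") <- f
    attr(utr, "overlap_d") <- d
  }
  if (p >= 3L) utr[p - 2L] <- "C"                # weak -3 context (kozak arm)
  if (start_codon == "GTG" && p >= 2L)           # avoid xxG windows becoming
    utr[(p - 1L):p] <- c("C", "C")               # accidental starts
  list(utr = utr, tx_start = p, tx_end = tx_end)
}

#' Simulate a transcriptome with planted uORFs and known truth
#'
#' Generates random multi-exon transcripts (both strands) whose 5'UTRs carry
#' planted uORFs of requested categories, with start-codon-suppressed
#' background so enumeration truth is exact. Optionally writes the genome
#' FASTA and GTF to disk.
#'
#' @param n_tx number of transcripts.
#' @param utr5_len_range,cds_len_range,utr3_len_range length ranges in nt
#'   (CDS lengths are rounded to codon multiples, start and stop included).
#' @param n_exons_range exon-count range.
#' @param plant category planted per transcript, recycled over transcripts:
#'   `"non_overlapping"`, `"overlapping_out_of_frame"`,
#'   `"n_terminal_extension"` or `"none"`.
#' @param plant_start_codons start codon per planted uORF, recycled.
#' @param translated logical, recycled: is the planted uORF translated
#'   (drives the RPF simulator).
#' @param plant_gain_sites also plant an armed near-start site (`ATA` plus
#'   in-frame downstream stop) per transcript with a 5'UTR long enough; a
#'   single A>G substitution at the recorded position creates a valid new
#'   ATG uORF (used by [simulate_vcf()]).
#' @param out_dir optional directory for `genome.fa` and `annotation.gtf`.
#' @param seed integer seed; a single seed governs all randomness and is
#'   stream-split per transcript, so outputs are byte-identical across runs.
#' @return list: `models`, `sequences` (transcript orientation), `genome`
#'   (named chromosome sequences), `truth` (list with `planted_uorfs` and
#'   `gain_sites` data.frames, plus the seed), `paths` (when written).
#' @export
simulate_transcriptome <- function(n_tx = 20L,
                                   utr5_len_range = c(90L, 240L),
                                   cds_len_range = c(120L, 300L),
                                   utr3_len_range = c(30L, 90L),
                                   n_exons_range = c(1L, 3L),
                                   plant = "non_overlapping",
                                   plant_start_codons = "ATG",
                                   translated = TRUE,
                                   plant_gain_sites = FALSE,
                                   out_dir = NULL,
                                   seed = 1L) {
  stopifnot(n_tx >= 1L, all(utr5_len_range >= 0L), all(cds_len_range >= 30L))
  plant <- rep_len(plant, n_tx)
  plant_start_codons <- rep_len(plant_start_codons, n_tx)
  translated <- rep_len(translated, n_tx)
  if (any(plant != "none") && max(utr5_len_range) < 45L)
    stop("utr5_len_range too short to plant uORFs (need >= 45 nt)")
  set.seed(seed)
  tx_seeds <- sample.int(.Machine$integer.max - 1L, n_tx)

  models <- list(); seqs <- character(0); genome <- character(0)
  planted <- list(); gains <- list()
  for (i in seq_len(n_tx)) {
    set.seed(tx_seeds[i])
    tid <- sprintf("TX%04d", i)
    gid <- sprintf("G%04d", i)
    chrom <- sprintf("chrS%04d", i)
    U <- sample(utr5_len_range[1L]:utr5_len_range[2L], 1L)
    if (plant[i] != "none") U <- max(U, 60L)
    if (plant_gain_sites) U <- max(U, 75L)
    cds_len <- sample(seq.int(cds_len_range[1L], cds_len_range[2L]), 1L)
    cds_len <- 3L * (cds_len %/% 3L)
    U3 <- sample(utr3_len_range[1L]:utr3_len_range[2L], 1L)

    utr <- rand_bases(U)
    # CDS: ATG + interior {A,C,G} (first interior base C/G) + TAA
    interior_len <- cds_len - 6L
    interior <- rand_bases(interior_len, c("A", "C", "G"))
    if (interior_len > 0L) interior[1L] <- sample(c("C", "G"), 1L)
    cds <- c("A", "T", "G", interior, "T", "A", "A")
    utr3 <- rand_bases(U3)

    gain <- NULL
    if (plant_gain_sites && U >= 30L) {
      # ATA + 6 interior {A,C} codons + TAA at positions [3, 27)
      site <- c("A", "T", "A", rand_bases(18L, c("A", "C")), "T", "A", "A")
      utr[4:27] <- site
      gain <- data.frame(transcript_id = tid, site_start = 3L,
                         mut_tx_pos = 5L, gained_tx_end = 27L,
                         stringsAsFactors = FALSE)
    }

    pl <- NULL
    if (plant[i] != "none") {
      res <- plant_uorf_in_utr(utr, cds_len, plant[i],
                               plant_start_codons[i], U)
      utr <- res$utr
      tx_start <- res$tx_start
      if (plant[i] == "non_overlapping") {
        tx_end <- res$tx_end
      } else if (plant[i] == "n_terminal_extension") {
        tx_end <- U + cds_len
      } else {
        f <- attr(res$utr, "overlap_frame")
        d <- attr(res$utr, "overlap_d")
        # plant a shifted-frame stop at CDS codon boundary c0 = U + 3*j
        j <- max(3L, as.integer(ceiling((18L - d - f) / 3)) + 1L)
        c0 <- U + 3L * j
        stopifnot(c0 + 6L <= U + cds_len - 3L)
        pair <- if (f == 1L) c("A", "T", "A", "A", "C", "C")
                else c("A", "A", "T", "A", "A", "C")
        cds[(3L * j + 1L):(3L * j + 6L)] <- pair
        tx_end <- c0 + f + 3L
      }
      pl <- data.frame(transcript_id = tid, tx_start = tx_start,
                       tx_end = tx_end, start_codon = plant_start_codons[i],
                       category = plant[i], translated = translated[i],
                       stringsAsFactors = FALSE)
    }

    txseq <- paste(c(utr, cds, utr3), collapse = "")
    txlen <- nchar(txseq)

    # exon structure: split at random transcript breakpoints
    n_ex <- sample(n_exons_range[1L]:n_exons_range[2L], 1L)
    n_ex <- min(n_ex, max(1L, txlen %/% 30L))
    cuts <- if (n_ex > 1L) sort(sample(seq.int(20L, txlen - 20L), n_ex - 1L))
            else integer(0)
    bounds <- c(0L, cuts, txlen)                  # tx-space exon bounds
    introns <- if (n_ex > 1L) sample(40:120, n_ex - 1L, replace = TRUE)
               else integer(0)
    flank <- 50L
    strand <- sample(c("+", "-"), 1L)
    # plus-orientation chromosome layout
    layout <- character(0)
    ex_plus <- matrix(0L, nrow = n_ex, ncol = 2L)
    gpos <- flank
    layout <- c(layout, paste(rand_bases(flank), collapse = ""))
    for (e in seq_len(n_ex)) {
      piece <- substr(txseq, bounds[e] + 1L, bounds[e + 1L])
      ex_plus[e, ] <- c(gpos, gpos + nchar(piece))
      layout <- c(layout, piece)
      gpos <- gpos + nchar(piece)
      if (e < n_ex) {
        layout <- c(layout, paste(rand_bases(introns[e]), collapse = ""))
        gpos <- gpos + introns[e]
      }
    }
    layout <- c(layout, paste(rand_bases(flank), collapse = ""))
    chromseq <- paste(layout, collapse = "")
    L <- nchar(chromseq)
    if (strand == "-") {
      chromseq <- revcomp(chromseq)
      ex_plus <- cbind(L - ex_plus[, 2L], L - ex_plus[, 1L])
    }
    m <- transcript_model(tid, gid, chrom, strand, ex_plus, U, U + cds_len)
    models[[tid]] <- m
    seqs[[tid]] <- txseq
    genome[[chrom]] <- chromseq
    if (!is.null(pl)) planted[[length(planted) + 1L]] <- pl
    if (!is.null(gain)) gains[[length(gains) + 1L]] <- gain
  }

  truth <- list(
    planted_uorfs = if (length(planted)) do.call(rbind, planted) else
      data.frame(transcript_id = character(0), tx_start = integer(0),
                 tx_end = integer(0), start_codon = character(0),
                 category = character(0), translated = logical(0)),
    gain_sites = if (length(gains)) do.call(rbind, gains) else
      data.frame(transcript_id = character(0), site_start = integer(0),
                 mut_tx_pos = integer(0), gained_tx_end = integer(0)),
    seed = seed)

  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    fa <- file.path(out_dir, "genome.fa")
    gtf <- file.path(out_dir, "annotation.gtf")
    gss <- Biostrings::DNAStringSet(genome)
    Biostrings::writeXStringSet(gss, fa)
    write_models_gtf(models, gtf)
    paths <- list(genome = fa, gtf = gtf)
  }
  list(models = models, sequences = seqs, genome = genome, truth = truth,
       paths = paths)
}

default_length_probs <- function() {
  c(`27` = 0.05, `28` = 0.35, `29` = 0.30, `30` = 0.15, `31` = 0.10,
    `32` = 0.05)
}

#' Simulate a ribosome-protected-fragment library with known P-sites
#'
#' P-sites are drawn per translated region (the CDS and every translated
#' planted uORF): codon positions multinomial-uniform over the coding span,
#' in-frame with probability `frame0_prob` (the remainder split equally
#' between frames 1 and 2). Non-translated planted uORFs receive
#' frame-uniform background at `uorf_bg_rate` P-sites/nt; `noise_rate`
#' P-sites/nt of frame-uniform noise cover the whole transcript. Read 5'
#' ends are P-site minus the length-dependent offset; lengths are drawn
#' from `length_probs`.
#'
#' @param sim result of [simulate_transcriptome()] (uses `models`,
#'   `sequences`, `truth`).
#' @param depth P-sites per coding nucleotide for translated regions.
#' @param frame0_prob in-frame probability, in `[1/3, 1]`.
#' @param length_probs named probability vector over read lengths.
#' @param offsets offset table (`read_length`, `offset`); default offset 12
#'   for every length in `length_probs`.
#' @param noise_rate,uorf_bg_rate background P-site rates per nt.
#' @param out_dir optional directory for `psites.tsv` (true 5'-end hits) and
#'   `reads_collapsed.fa`.
#' @param seed integer seed.
#' @return list: `hits` (transcript_id, tx_pos, read_length, count),
#'   `true_psites` (with the P-site positions), `paths`, `offsets`.
#' @export
simulate_rpf_library <- function(sim, depth = 1, frame0_prob = 0.9,
                                 length_probs = default_length_probs(),
                                 offsets = NULL, noise_rate = 0.02,
                                 uorf_bg_rate = 0.2, out_dir = NULL,
                                 seed = 1L) {
  stopifnot(frame0_prob >= 1 / 3, frame0_prob <= 1)
  models <- sim$models; seqs <- sim$sequences
  lens <- as.integer(names(length_probs))
  if (is.null(offsets))
    offsets <- data.frame(read_length = lens, offset = 12L)
  off <- stats::setNames(offsets$offset, offsets$read_length)
  stopifnot(all(lens %in% offsets$read_length))
  set.seed(seed)
  tx_seeds <- sample.int(.Machine$integer.max - 1L, length(models))
  names(tx_seeds) <- names(models)
  planted <- sim$truth$planted_uorfs

  draw_psites <- function(start, end, n, f0) {
    # coding span [start, end), codon-uniform, frame 0 w.p. f0
    n_cod <- (end - start) %/% 3L
    if (n <= 0L || n_cod <= 0L) return(integer(0))
    cod <- sample.int(n_cod, n, replace = TRUE) - 1L
    fr <- sample(0:2, n, replace = TRUE,
                 prob = c(f0, (1 - f0) / 2, (1 - f0) / 2))
    start + 3L * cod + fr
  }

  rows <- list()
  for (tid in names(models)) {
    set.seed(tx_seeds[[tid]])
    m <- models[[tid]]
    ps <- integer(0)
    cds_span <- c(m$cds_tx_start, m$cds_tx_end - 3L)
    ps <- c(ps, draw_psites(cds_span[1L], cds_span[2L],
                            stats::rpois(1L, depth * diff(cds_span)),
                            frame0_prob))
    pu <- planted[planted$transcript_id == tid, , drop = FALSE]
    for (k in seq_len(nrow(pu))) {
      u <- pu[k, ]
      cod_end <- min(u$tx_end - 3L, m$tx_length)
      if (u$translated) {
        ps <- c(ps, draw_psites(u$tx_start, cod_end,
                                stats::rpois(1L, depth * (cod_end - u$tx_start)),
                                frame0_prob))
      } else {
        n_bg <- stats::rpois(1L, uorf_bg_rate * (cod_end - u$tx_start))
        if (n_bg > 0L)
          ps <- c(ps, u$tx_start +
                    sample.int(cod_end - u$tx_start, n_bg, replace = TRUE) - 1L)
      }
    }
    n_noise <- stats::rpois(1L, noise_rate * m$tx_length)
    if (n_noise > 0L)
      ps <- c(ps, sample.int(m$tx_length, n_noise, replace = TRUE) - 1L)
    if (length(ps) == 0L) next
    L <- sample(lens, length(ps), replace = TRUE, prob = length_probs)
    five <- ps - off[as.character(L)]
    keep <- five >= 0L & five + L <= m$tx_length
    if (!any(keep)) next
    rows[[length(rows) + 1L]] <- data.frame(
      transcript_id = tid, tx_pos = as.integer(five[keep]),
      read_length = L[keep], psite = ps[keep], count = 1L,
      stringsAsFactors = FALSE)
  }
  all <- do.call(rbind, c(rows, list(
    data.frame(transcript_id = character(0), tx_pos = integer(0),
               read_length = integer(0), psite = integer(0),
               count = integer(0)))))
  hits <- aggregate_hits(all[, c("transcript_id", "tx_pos", "read_length",
                                 "count")])
  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    tsv <- file.path(out_dir, "psites.tsv")
    utils::write.table(hits, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    # read sequences -> collapsed FASTA
    fa <- file.path(out_dir, "reads_collapsed.fa")
    rs <- substring(seqs[all$transcript_id], all$tx_pos + 1L,
                    all$tx_pos + all$read_length)
    tab <- table(rs)
    df <- data.frame(seq = names(tab), count = as.integer(tab),
                     stringsAsFactors = FALSE)
    df <- df[order(-df$count, df$seq, method = "radix"), , drop = FALSE]
    df$read_id <- sprintf("seq%d", seq_len(nrow(df)))
    write_collapsed_fasta(df[, c("read_id", "seq", "count")], fa)
    paths <- list(psites = tsv, reads = fa)
  }
  list(hits = hits, true_psites = all, paths = paths, offsets = offsets)
}

#' Simulate a VCF of 5'UTR variants with known uORF effects
#'
#' Engineers variants against the planted structures of a simulated
#' transcriptome so that each requested effect class is produced: gained
#' starts use armed gain sites (`plant_gain_sites = TRUE` in
#' [simulate_transcriptome()]); start/stop losses, stop gains, frameshifts
#' and Kozak changes target planted uORFs (stop gains use the armed `AAA`
#' interior codon of non-overlapping plants; Kozak changes use the forced
#' weak `-3` context). Alleles avoid introducing G so no incidental start
#' codons appear.
#'
#' @param sim result of [simulate_transcriptome()].
#' @param effect_mix named integer vector, e.g.
#'   `c(uAUG_gained = 5, uSTART_lost = 5, ...)`; an infeasible request
#'   (more variants than plantable sites) is an error.
#' @param out_path path for the VCF (written even when empty: header only).
#' @param seed integer seed.
#' @return data.frame of truth labels: `variant_id`, `chrom`, `pos`,
#'   `ref`, `alt`, `transcript_id`, `expected_effect`, `uorf_id`.
#' @export
simulate_vcf <- function(sim, effect_mix = integer(0), out_path,
                         seed = 1L) {
  models <- sim$models; seqs <- sim$sequences
  planted <- sim$truth$planted_uorfs
  gains <- sim$truth$gain_sites
  set.seed(seed)

  # genome-space record for a tx-space substitution on one transcript
  to_genome <- function(m, tx_pos, ref_tx, alt_tx) {
    nref <- nchar(ref_tx)
    blocks <- tx_to_genome(m, tx_pos, tx_pos + nref)
    if (nrow(blocks) != 1L)
      stop("engineered variant spans an exon junction")
    if (m$strand == "+") {
      list(pos = blocks[1L, 1L] + 1L, ref = ref_tx, alt = alt_tx)
    } else {
      list(pos = blocks[1L, 1L] + 1L, ref = revcomp(ref_tx),
           alt = revcomp(alt_tx))
    }
  }

  specs <- list()
  add <- function(effect, tid, tx_pos, ref_tx, alt_tx, uorf_id) {
    specs[[length(specs) + 1L]] <<- list(
      effect = effect, tid = tid, tx_pos = tx_pos, ref_tx = ref_tx,
      alt_tx = alt_tx, uorf_id = uorf_id)
  }
  nonov <- planted[planted$category == "non_overlapping", , drop = FALSE]
  atg <- planted[planted$start_codon == "ATG", , drop = FALSE]
  for (eff in names(effect_mix)) {
    n <- effect_mix[[eff]]
    if (n == 0L) next
    if (eff == "uAUG_gained") {
      if (nrow(gains) < n)
        stop("infeasible effect request: ", n, " uAUG_gained but only ",
             nrow(gains), " gain sites (plant_gain_sites = TRUE?)")
      for (k in seq_len(n))
        add(eff, gains$transcript_id[k], gains$mut_tx_pos[k], "A", "G",
            NA_character_)
    } else if (eff == "uSTART_lost") {
      if (nrow(atg) < n)
        stop("infeasible effect request: ", n, " uSTART_lost but only ",
             nrow(atg), " planted ATG uORFs")
      for (k in seq_len(n))
        add(eff, atg$transcript_id[k], atg$tx_start[k] + 1L, "T", "A",
            sprintf("%s:%d-%d:%s", atg$transcript_id[k], atg$tx_start[k],
                    atg$tx_end[k], atg$start_codon[k]))
    } else if (eff %in% c("uSTOP_lost", "uSTOP_gained", "uFrameshift",
                          "kozak_changed")) {
      if (nrow(nonov) < n)
        stop("infeasible effect request: ", n, " ", eff, " but only ",
             nrow(nonov), " planted non-overlapping uORFs")
      for (k in seq_len(n)) {
        u <- nonov[k, ]
        uid <- sprintf("%s:%d-%d:%s", u$transcript_id, u$tx_start,
                       u$tx_end, u$start_codon)
        if (eff == "uSTOP_lost") {
          add(eff, u$transcript_id, u$tx_end - 1L, "A", "C", uid)
        } else if (eff == "uSTOP_gained") {
          add(eff, u$transcript_id, u$tx_start + 3L, "A", "T", uid)
        } else if (eff == "uFrameshift") {
          t <- u$tx_start + 7L
          base <- substr(seqs[[u$transcript_id]], t + 1L, t + 1L)
          add(eff, u$transcript_id, t, base, paste0(base, "A"), uid)
        } else {                                  # kozak_changed
          if (u$tx_start < 3L) stop("planted uORF lacks -3 context")
          add(eff, u$transcript_id, u$tx_start - 3L, "C", "A", uid)
        }
      }
    } else stop("unknown effect class '", eff, "'")
  }

  rows <- lapply(seq_along(specs), function(i) {
    s <- specs[[i]]
    m <- models[[s$tid]]
    obs <- substr(seqs[[s$tid]], s$tx_pos + 1L, s$tx_pos + nchar(s$ref_tx))
    stopifnot(identical(obs, s$ref_tx))
    g <- to_genome(m, s$tx_pos, s$ref_tx, s$alt_tx)
    data.frame(variant_id = sprintf("var%03d", i), chrom = m$chrom,
               pos = g$pos, ref = g$ref, alt = g$alt,
               transcript_id = s$tid, expected_effect = s$effect,
               uorf_id = s$uorf_id, stringsAsFactors = FALSE)
  })
  truth <- if (length(rows)) do.call(rbind, rows) else
    data.frame(variant_id = character(0), chrom = character(0),
               pos = integer(0), ref = character(0), alt = character(0),
               transcript_id = character(0), expected_effect = character(0),
               uorf_id = character(0), stringsAsFactors = FALSE)

  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>",
                   unique(vapply(models, `[[`, "", "chrom")),
                   vapply(models[!duplicated(vapply(models, `[[`, "",
                                                    "chrom"))],
                          function(m) max(m$exons) + 50L, integer(1))),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- character(0)
  if (nrow(truth) > 0L) {
    ord <- order(truth$chrom, truth$pos, method = "radix")
    truth <- truth[ord, , drop = FALSE]
    body <- sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t.", truth$chrom,
                    truth$pos, truth$variant_id, truth$ref, truth$alt)
  }
  writeLines(c(hdr, body), out_path)
  rownames(truth) <- NULL
  truth
}
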