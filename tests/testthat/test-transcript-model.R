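test_that("GTF parsing converts 1-based inclusive features to transcript coordinates", {
  # exon 100-400, CDS 200-350 (1-based inclusive), single exon, plus strand:
  # transcript length 301; CDS occupies tx [100, 251) (151 bases)
  gtf <- write_lines_tmp(c(
    paste("c1", "src", "exon", 100, 400, ".", "+", ".",
          'gene_id "g1"; transcript_id "t1";', sep = "\t"),
    paste("c1", "src", "CDS", 200, 350, ".", "+", ".",
          'gene_id "g1"; transcript_id "t1";', sep = "\t")), ".gtf")
  fa <- write_lines_tmp(c(">c1", paste(rep("ACGT", 150), collapse = "")),
                        ".fa")
  ann <- parse_annotation(gtf, fa)
  m <- ann$models[["t1"]]
  expect_equal(m$tx_length, 301L)
  expect_equal(m$cds_tx_start, 100L)
  expect_equal(m$cds_tx_end, 251L)
  expect_equal(utr5_length(m), 100L)
  expect_equal(nchar(ann$sequences[["t1"]]), 301L)
  expect_false(ann$no_utr5[["t1"]])
})

test_that("stop_codon features outside the CDS are appended to the span", {
  gtf <- write_lines_tmp(c(
    paste("c1", "s", "exon", 1, 100, ".", "+", ".",
          'gene_id "g"; transcript_id "t";', sep = "\t"),
    paste("c1", "s", "CDS", 31, 87, ".", "+", ".",
          'gene_id "g"; transcript_id "t";', sep = "\t"),
    paste("c1", "s", "stop_codon", 88, 90, ".", "+", ".",
          'gene_id "g"; transcript_id "t";', sep = "\t")), ".gtf")
  ann <- parse_annotation(gtf)
  expect_equal(ann$models$t$cds_tx_end, 90L)
  expect_equal((ann$models$t$cds_tx_end - ann$models$t$cds_tx_start) %% 3L, 0L)
})

test_that("minus-strand sequence is the reverse complement of genomic-order exons", {
  chromseq <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                    collapse = "")
  gtf <- write_lines_tmp(c(
    paste("c1", "s", "exon", 11, 70, ".", "-", ".",
          'gene_id "g"; transcript_id "t";', sep = "\t"),
    paste("c1", "s", "exon", 101, 160, ".", "-", ".",
          'gene_id "g"; transcript_id "t";', sep = "\t"),
    paste("c1", "s", "CDS", 31, 150, ".", "-", ".",
          'gene_id "g"; transcript_id "t";', sep = "\t")), ".gtf")
  fa <- write_lines_tmp(c(">c1", chromseq), ".fa")
  ann <- parse_annotation(gtf, fa)
  concat <- paste0(substr(chromseq, 11, 70), substr(chromseq, 101, 160))
  expect_equal(ann$sequences[["t"]],
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(concat))))
  # 5'UTR of a minus-strand transcript is the genomically rightmost part
  expect_equal(ann$models$t$cds_tx_start, 10L)
})

test_that("transcripts lacking exon or CDS features are skipped with a warning", {
  gtf <- write_lines_tmp(c(
    paste("c1", "s", "CDS", 31, 87, ".", "+", ".",
          'gene_id "g"; transcript_id "broken";', sep = "\t"),
    paste("c1", "s", "exon", 1, 100, ".", "+", ".",
          'gene_id "g"; transcript_id "ok";', sep = "\t"),
    paste("c1", "s", "CDS", 31, 87, ".", "+", ".",
          'gene_id "g"; transcript_id "ok";', sep = "\t")), ".gtf")
  expect_warning(ann <- parse_annotation(gtf), "broken")
  expect_named(ann$models, "ok")
})

test_that("missing chromosome in the FASTA skips the transcript with a warning", {
  gtf <- write_lines_tmp(c(
    paste("cX", "s", "exon", 1, 60, ".", "+", ".",
          'gene_id "g"; transcript_id "t";', sep = "\t"),
    paste("cX", "s", "CDS", 10, 51, ".", "+", ".",
          'gene_id "g"; transcript_id "t";', sep = "\t")), ".gtf")
  fa <- write_lines_tmp(c(">c1", "ACGTACGT"), ".fa")
  expect_warning(ann <- parse_annotation(gtf, fa), "absent from FASTA")
  expect_length(ann$models, 0L)
})

test_that("interval projection yields single or junction-spanning blocks", {
  m <- transcript_model("t", "g", "c", "+",
                        rbind(c(100, 160), c(200, 240), c(300, 330)), 10, 100)
  expect_equal(tx_to_genome(m, 5, 20),
               matrix(c(105L, 120L), 1, dimnames = list(NULL, c("start", "end"))))
  b <- tx_to_genome(m, 50, 70)   # spans exon1/exon2 junction
  expect_equal(nrow(b), 2L)
  expect_equal(sum(b[, 2] - b[, 1]), 20L)
  expect_error(tx_to_genome(m, 100, 200), "outside transcript")
})

test_that("genome_to_tx inverts tx_to_genome per base; intronic positions are NA", {
  m <- transcript_model("t", "g", "c", "-",
                        rbind(c(100, 160), c(200, 240), c(300, 330)), 10, 100)
  tx <- 0:(m$tx_length - 1L)
  fwd <- vapply(tx, function(p) unname(tx_to_genome(m, p, p + 1L)[1L, 1L]),
                integer(1))
  expect_identical(vapply(fwd, function(g) genome_to_tx(m, g), integer(1)),
                   tx)
  expect_true(is.na(genome_to_tx(m, 170)))   # intron
  expect_true(is.na(genome_to_tx(m, 50)))    # intergenic
})

test_that("projection matches the per-base oracle on random multi-exon models", {
  set.seed(42)
  for (i in 1:100) {
    m <- random_model(sprintf("R%03d", i))
    gmap <- oracle_tx2g_map(m)
    tx <- 0:(m$tx_length - 1L)
    fwd <- vapply(tx, function(p) unname(tx_to_genome(m, p, p + 1L)[1L, 1L]),
                  integer(1))
    expect_identical(fwd, gmap, info = m$transcript_id)
    back <- vapply(gmap, function(g) genome_to_tx(m, g), integer(1))
    expect_identical(back, tx, info = m$transcript_id)
  }
})

test_that("writing a model to GTF and re-parsing yields an identical model", {
  set.seed(7)
  models <- lapply(1:10, function(i) {
    m <- random_model(sprintf("T%02d", i))
    # CDS spans of length >= 3 keep the toy realistic
    if (m$cds_tx_end - m$cds_tx_start < 3L && m$tx_length >= 3L) {
      m$cds_tx_start <- 0L; m$cds_tx_end <- 3L
    }
    m
  })
  names(models) <- vapply(models, `[[`, "", "transcript_id")
  gtf <- tempfile(fileext = ".gtf")
  write_models_gtf(models, gtf)
  ann <- parse_annotation(gtf)
  expect_setequal(names(ann$models), names(models))
  for (id in names(models)) {
    a <- models[[id]]; b <- ann$models[[id]]
    expect_equal(unname(a$exons), unname(b$exons), info = id)
    expect_identical(a$strand, b$strand, info = id)
    expect_identical(a$cds_tx_start, b$cds_tx_start, info = id)
    expect_identical(a$cds_tx_end, b$cds_tx_end, info = id)
  }
})

test_that("BED12 output carries exon blocks and the CDS as the thick region", {
  m <- transcript_model("t", "g", "c", "+",
                        rbind(c(100, 160), c(200, 240)), 10, 80)
  f <- tempfile(fileext = ".bed")
  write_models_bed12(list(t = m), f)
  fields <- strsplit(readLines(f), "\t")[[1]]
  expect_equal(fields[1:3], c("c", "100", "240"))
  expect_equal(fields[10], "2")
  expect_equal(fields[11], "60,40,")
  expect_equal(fields[12], "0,100,")
})
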