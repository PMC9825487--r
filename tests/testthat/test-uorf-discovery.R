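# The minimum-length rule follows "18 nucleotides (six amino acids)": 18 nt
# of coding sequence, stop codon excluded, so the shortest emitted uORF spans
# 21 nt including its stop.

test_that("a 5'UTR without start codons yields no candidates", {
  tx <- make_tx(strrep("AC", 30), paste0("ATG", strrep("GCC", 10), "TAA"))
  expect_equal(nrow(enumerate_candidates(tx$model, tx$seq)), 0L)
})

test_that("a transcript without a 5'UTR yields no candidates", {
  tx <- make_tx("", paste0("ATG", strrep("GCC", 10), "TAA"))
  expect_equal(nrow(enumerate_candidates(tx$model, tx$seq)), 0L)
})

test_that("the 18-nt coding minimum is enforced at the boundary", {
  pad <- function(orf) make_tx(paste0(strrep("CC", 10), orf, strrep("CA", 5)),
                               paste0("ATG", strrep("GCC", 10), "TAA"))
  # ATG + 5 sense codons + TAA = 18 coding nt -> emitted
  tx_ok <- pad(paste0("ATG", strrep("GCC", 5), "TAA"))
  got <- enumerate_candidates(tx_ok$model, tx_ok$seq)
  expect_equal(nrow(got), 1L)
  expect_equal(got$coding_len, 18L)
  expect_equal(got$category, "non_overlapping")
  expect_equal(got$tx_end - got$tx_start, 21L)
  # ATG + 4 sense codons + TAA = 15 coding nt -> below the minimum
  tx_short <- pad(paste0("ATG", strrep("GCC", 4), "TAA"))
  expect_equal(nrow(enumerate_candidates(tx_short$model, tx_short$seq)), 0L)
  # the minimum is configurable
  expect_equal(nrow(enumerate_candidates(tx_short$model, tx_short$seq,
                                         min_len_nt = 15L)), 1L)
})

test_that("an in-frame upstream ATG without an intervening stop is an N-terminal extension", {
  # ATG 9 nt upstream of the CDS, same frame, {A,C} spacer has no stops
  tx <- make_tx(paste0(strrep("CA", 10), "ATG", "ACCACC"),
                paste0("ATG", strrep("GCC", 10), "TAA"))
  got <- enumerate_candidates(tx$model, tx$seq)
  expect_equal(nrow(got), 1L)
  expect_equal(got$category, "n_terminal_extension")
  expect_equal(got$tx_end, tx$model$cds_tx_end)
  expect_equal(got$frame_vs_cds, 0L)
  # peptide is the N-terminally extended CDS peptide
  cds_pep <- translate_uorf(tx$seq, tx$model$cds_tx_start,
                            tx$model$cds_tx_end)
  expect_match(got$peptide, paste0(substr(cds_pep, 2, nchar(cds_pep)), "$"))
  expect_equal(nchar(got$peptide), nchar(cds_pep) + 3L)
})

test_that("an upstream start with its stop inside the CDS in a shifted frame is overlapping_out_of_frame", {
  # ATG 13 nt upstream of the CDS start (frame +2); the CDS carries a TAA in
  # that shifted frame (chars 7-9 of "ATGCCTAAC..."), while its own frame-0
  # codons (CCT, AAC) stay sense codons
  utr <- strrep("CA", 12)
  substr(utr, 12, 14) <- "ATG"                # 0-based tx position 11
  cds <- paste0("ATG", "CCT", "AAC", strrep("GCC", 5), "TAA")
  tx <- make_tx(utr, cds)
  got <- enumerate_candidates(tx$model, tx$seq)
  expect_equal(nrow(got), 1L)
  expect_equal(got$tx_start, 11L)
  expect_equal(got$category, "overlapping_out_of_frame")
  expect_equal(got$frame_vs_cds, 2L)
  expect_equal(got$tx_end, 32L)               # stop inside the CDS
  expect_gt(got$tx_end, tx$model$cds_tx_start)
  expect_equal(got$coding_len, 18L)
})

test_that("out-of-frame ORFs reaching the transcript end without a stop are discarded", {
  # CTG in frame +2; no stop codon exists in that frame through the CDS and
  # there is no 3'UTR, so the ORF never terminates and is not emitted
  tx <- make_tx(paste0(strrep("CC", 10), "CTGGCCGCCC"),
                paste0("ATG", strrep("GCC", 10), "TAA"), utr3 = "")
  expect_equal((20L - tx$model$cds_tx_start) %% 3L, 2L)
  got <- enumerate_candidates(tx$model, tx$seq)
  expect_equal(nrow(got), 0L)
})

test_that("classification is decided by overlap and frame only", {
  tx <- make_tx(strrep("C", 60), paste0("ATG", strrep("GCC", 10), "TAA"))
  m <- tx$model
  expect_equal(classify_uorf(0L, 30L, m), "non_overlapping")
  expect_equal(classify_uorf(0L, 60L, m), "non_overlapping")   # abuts the CDS
  expect_equal(classify_uorf(1L, 70L, m), "overlapping_out_of_frame")
  expect_equal(classify_uorf(57L, m$cds_tx_end, m), "n_terminal_extension")
  expect_error(classify_uorf(60L, 90L, m), "5'UTR")
})

test_that("translation uses the standard code with initiator Met for near-cognate starts", {
  seq <- "CTGGCCGATTTTAAAGGGTAA"
  expect_equal(translate_uorf(seq, 0L, nchar(seq)), "MADFKG")
  expect_equal(translate_uorf("ATGGCCTAA", 0L, 9L), "MA")
  expect_error(translate_uorf("ATGTAAGCCTAA", 0L, 12L), "internal stop")
  expect_error(translate_uorf("ATGGCCGCC", 0L, 9L), "stop codon")
})

test_that("Kozak strength follows the -3/+4 motif classes", {
  # context "ACCATGG": -3 = A, +4 = G -> strong
  expect_equal(kozak_strength("ACCATGGCC", 3L, "ATG"), "strong")
  # "TTTATGG": -3 = T, +4 = G -> moderate
  expect_equal(kozak_strength("TTTATGGCC", 3L, "ATG"), "moderate")
  # "GCCATGC": -3 = G, +4 = C -> moderate
  expect_equal(kozak_strength("GCCATGCCC", 3L, "ATG"), "moderate")
  # "TTTATGC": neither -> weak
  expect_equal(kozak_strength("TTTATGCCC", 3L, "ATG"), "weak")
  # non-ATG starts and truncated -3 context are not classified
  expect_equal(kozak_strength("ACCCTGGCC", 3L, "CTG"), "not_applicable")
  expect_equal(kozak_strength("ATGGCCGCC", 0L, "ATG"), "not_applicable")
})

test_that("isoform collapsing merges identical genomic uORFs only", {
  # two isoforms of one gene sharing the 5'UTR exon carrying the uORF
  utr <- paste0(strrep("CC", 6), "ATG", strrep("GCC", 6), "TAA", "CACA")
  cds <- paste0("ATG", strrep("GCC", 8), "TAA")
  t1 <- make_tx(utr, cds, id = "tA", gstart = 1000L)
  t2m <- transcript_model("tB", "g_tA", "c1", "+",
                          rbind(c(1000, 1000 + nchar(utr)),
                                c(2000, 2000 + nchar(cds))),
                          nchar(utr), nchar(utr) + nchar(cds))
  c1 <- enumerate_candidates(t1$model, t1$seq)
  c2 <- enumerate_candidates(t2m, paste0(utr, cds))
  merged <- collapse_isoforms(rbind(c1, c2))
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$member_transcripts, "tA,tB")
  expect_equal(merged$n_isoforms, 2L)
  expect_equal(merged$transcript_id, "tA")   # lexicographically smallest

  # same transcript-space coordinates, different genomic blocks: kept apart
  t3 <- make_tx(utr, cds, id = "tC", gstart = 5000L)
  c3 <- enumerate_candidates(t3$model, t3$seq)
  kept <- collapse_isoforms(rbind(c1, c3))
  expect_equal(nrow(kept), 2L)

  # single isoform: identity
  solo <- collapse_isoforms(c1)
  expect_equal(solo$uorf_id, c1$uorf_id)
})

test_that("enumeration matches the brute-force oracle on random transcripts", {
  set.seed(101)
  for (i in 1:60) {
    tx <- random_seq_tx(sprintf("S%03d", i), utr5_max = 300L)
    got <- enumerate_candidates(tx$model, tx$seq)
    exp <- oracle_enumerate(tx$seq, tx$model$cds_tx_start,
                            tx$model$cds_tx_end)
    expect_identical(cand_key(got), cand_key(exp), info = tx$model$transcript_id)
  }
})

test_that("restricting start codons yields a subset, and invariants hold", {
  set.seed(202)
  for (i in 1:25) {
    tx <- random_seq_tx(sprintf("M%03d", i), utr5_max = 300L)
    full <- enumerate_candidates(tx$model, tx$seq)
    atg <- enumerate_candidates(tx$model, tx$seq, start_codons = "ATG")
    expect_true(all(atg$uorf_id %in% full$uorf_id))
    if (nrow(full) == 0L) next
    m <- tx$model
    expect_true(all(full$tx_start < m$cds_tx_start))
    expect_true(all((full$tx_end - full$tx_start) %% 3L == 0L))
    expect_true(all(full$tx_end - full$tx_start >= 18L))
    expect_true(all(full$coding_len >= 18L))
    # category partition: mutually exclusive and exhaustive
    expect_true(all(full$category %in% c("non_overlapping",
                                         "overlapping_out_of_frame",
                                         "n_terminal_extension")))
    expect_identical(full$category == "non_overlapping",
                     full$tx_end <= m$cds_tx_start)
    expect_identical(full$category == "n_terminal_extension",
                     full$frame_vs_cds == 0L & full$tx_end > m$cds_tx_start)
    # stop codon identity (except extensions, which share the CDS stop)
    non_ext <- full[full$category != "n_terminal_extension", ]
    if (nrow(non_ext) > 0L)
      expect_true(all(substr(tx$seq, non_ext$tx_end - 2L, non_ext$tx_end)
                      %in% c("TAG", "TGA", "TAA")))
  }
})
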