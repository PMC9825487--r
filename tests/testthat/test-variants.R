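# A plus-strand two-exon transcript whose 5'UTR carries one ATG uORF with a
# weak Kozak context (-3 = C, +4 = A) and an armed "ATA" gain site.
#   tx layout: [0,12) CA background | [12,15) ATA gain | [15,33) {A,C} codons
#              | [33,36) TAA (gain-site stop) | [36,39) CC C | [39,42) ATG
#              | [42,45) AAA | [45,63) {AC} codons | [63,66) TAA | [66,72) CA
vr_utr <- paste0(strrep("CA", 6), "ATA", strrep("AC", 9), "TAA", "CCC",
                 "ATG", "AAA", strrep("CA", 9), "TAA", strrep("CA", 3))
vr_cds <- paste0("ATG", strrep("GCC", 12), "TAA")
vr_seq <- paste0(vr_utr, vr_cds)

make_variant_tx <- function(strand = "+") {
  n <- nchar(vr_seq)
  intron <- 40L
  cut <- 30L   # exon junction inside the 5'UTR
  if (strand == "+") {
    exons <- rbind(c(100L, 100L + cut), c(100L + cut + intron, 100L + n + intron))
  } else {
    L <- 400L
    e <- rbind(c(100L, 100L + cut), c(100L + cut + intron, 100L + n + intron))
    exons <- cbind(L - e[, 2L], L - e[, 1L])
  }
  transcript_model("T1", "g1", "c1", strand, exons,
                   nchar(vr_utr), nchar(vr_utr) + nchar(vr_cds))
}

# tx-space variant row in the shape extract_utr5_variants() emits
tx_variant <- function(tx_pos, ref_tx, alt_tx, id = "v1") {
  data.frame(variant_id = id, chrom = "c1", pos = 0L, ref = ref_tx,
             alt = alt_tx, transcript_id = "T1", tx_pos = tx_pos,
             ref_tx = ref_tx, alt_tx = alt_tx, in_5utr = TRUE,
             spans_cds_boundary = FALSE, stringsAsFactors = FALSE)
}

vr_model <- make_variant_tx("+")
vr_cand <- enumerate_candidates(vr_model, vr_seq)
stopifnot(nrow(vr_cand) == 1L, vr_cand$tx_start == 39L, vr_cand$tx_end == 66L)

test_that("VCF extraction keeps only exonic 5'UTR-projected variants", {
  m <- make_variant_tx("+")
  vcf <- write_lines_tmp(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=c1,length=400>",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    sprintf("c1\t%d\t.\t%s\tT\t.\tPASS\t.", 105L,
            substr(vr_seq, 5L, 5L)),          # tx pos 4, in 5'UTR
    sprintf("c1\t%d\t.\tA\tC\t.\tPASS\t.", 140L),   # intronic
    sprintf("c1\t%d\t.\t%s\tA\t.\tPASS\t.", 100L + 40L + 80L + 1L,
            substr(vr_seq, 81L, 81L)),        # tx pos 80, inside CDS
    sprintf("chrc1\t%d\t.\t%s\tT\t.\tPASS\t.", 107L,
            substr(vr_seq, 7L, 7L))),         # chr-prefixed contig
    ".vcf")
  got <- extract_utr5_variants(vcf, list(T1 = m))
  expect_equal(nrow(got), 2L)
  expect_setequal(got$tx_pos, c(4L, 6L))
  expect_true(all(got$in_5utr))
})

test_that("multiallelic records are split per alternate allele", {
  m <- make_variant_tx("+")
  ref <- substr(vr_seq, 5L, 5L)
  alts <- setdiff(c("A", "C", "G", "T"), ref)
  vcf <- write_lines_tmp(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    sprintf("c1\t105\trs1\t%s\t%s\t.\tPASS\t.", ref,
            paste(alts, collapse = ","))), ".vcf")
  got <- extract_utr5_variants(vcf, list(T1 = m))
  expect_equal(nrow(got), 3L)
  expect_setequal(got$alt, alts)
})

test_that("reference-allele mismatch stops annotation", {
  v <- tx_variant(39L, "C", "T")   # transcript has "A" at 39
  expect_error(annotate_effect(v, vr_model, vr_seq, vr_cand),
               "reference allele mismatch")
})

test_that("destroying the start codon is uSTART_lost", {
  v <- tx_variant(40L, "T", "A")   # ATG -> AAG
  eff <- annotate_effect(v, vr_model, vr_seq, vr_cand)
  expect_equal(eff$effect, "uSTART_lost")
  expect_equal(eff$uorf_id, vr_cand$uorf_id)
  expect_true(eff$affects_uorf)
})

test_that("a start-codon change to another valid start is not a loss", {
  v <- tx_variant(39L, "A", "C")   # ATG -> CTG (near-cognate, still a start)
  eff <- annotate_effect(v, vr_model, vr_seq, vr_cand)
  expect_equal(eff$effect, "no_uorf_effect")
})

test_that("destroying the stop codon is uSTOP_lost", {
  v <- tx_variant(65L, "A", "C")   # TAA -> TAC
  eff <- annotate_effect(v, vr_model, vr_seq, vr_cand)
  expect_equal(eff$effect, "uSTOP_lost")
})

test_that("an in-frame stop created inside the uORF is uSTOP_gained", {
  v <- tx_variant(42L, "A", "T")   # armed AAA -> TAA, in frame
  eff <- annotate_effect(v, vr_model, vr_seq, vr_cand)
  expect_equal(eff$effect, "uSTOP_gained")
})

test_that("a length-changing indel inside the uORF is uFrameshift", {
  base <- substr(vr_seq, 47L, 47L)
  v <- tx_variant(46L, base, paste0(base, "A"))   # 1-nt insertion
  eff <- annotate_effect(v, vr_model, vr_seq, vr_cand)
  expect_equal(eff$effect, "uFrameshift")
  # a 3-nt (in-frame) insertion of sense bases is not a frameshift
  v3 <- tx_variant(46L, base, paste0(base, "ACC"))
  eff3 <- annotate_effect(v3, vr_model, vr_seq, vr_cand)
  expect_false(any(eff3$effect == "uFrameshift"))
})

test_that("a -3 context change without codon loss is kozak_changed", {
  v <- tx_variant(36L, "C", "A")   # -3: C -> A, weak -> moderate
  eff <- annotate_effect(v, vr_model, vr_seq, vr_cand)
  expect_equal(eff$effect, "kozak_changed")
  expect_match(eff$detail, "weak->moderate")
})

test_that("creating a start codon that forms a valid candidate is uAUG_gained", {
  v <- tx_variant(14L, "A", "G")   # gain site ATA -> ATG at tx 12
  eff <- annotate_effect(v, vr_model, vr_seq, vr_cand)
  expect_equal(eff$effect, "uAUG_gained")
  expect_match(eff$uorf_id, "gained")
  # the same mutation confirmed by full re-enumeration
  mut <- paste0(substr(vr_seq, 1, 14), "G",
                substr(vr_seq, 16, nchar(vr_seq)))
  re <- enumerate_candidates(vr_model, mut)
  expect_true(12L %in% re$tx_start)
})

test_that("a variant outside any uORF and context is no_uorf_effect", {
  v <- tx_variant(0L, "C", "T")
  eff <- annotate_effect(v, vr_model, vr_seq, vr_cand)
  expect_equal(eff$effect, "no_uorf_effect")
  expect_false(eff$affects_uorf)
})

test_that("deletions spanning the CDS boundary are flagged, not classified", {
  v <- tx_variant(70L, substr(vr_seq, 71L, 75L), substr(vr_seq, 71L, 71L))
  v$spans_cds_boundary <- TRUE
  eff <- annotate_effect(v, vr_model, vr_seq, vr_cand)
  expect_equal(eff$effect, "no_uorf_effect")
  expect_equal(eff$detail, "spans_cds_boundary")
})

test_that("minus-strand genome variants produce the same transcript-space effects", {
  mp <- make_variant_tx("+"); mm <- make_variant_tx("-")
  # genome coordinates of the uSTART_lost substitution on both strands
  for (m in list(mp, mm)) {
    b <- tx_to_genome(m, 40L, 41L)
    ref_g <- if (m$strand == "+") "T" else "A"
    alt_g <- if (m$strand == "+") "A" else "T"
    vcf <- write_lines_tmp(c(
      "##fileformat=VCFv4.2",
      "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
      sprintf("c1\t%d\t.\t%s\t%s\t.\tPASS\t.", b[1, 1] + 1L, ref_g, alt_g)),
      ".vcf")
    got <- extract_utr5_variants(vcf, list(T1 = m))
    expect_equal(got$tx_pos, 40L)
    expect_equal(got$ref_tx, "T")
    eff <- annotate_effect(got, m, vr_seq, vr_cand)
    expect_equal(eff$effect, "uSTART_lost")
  }
})

test_that("effect summaries count classes and conserve totals", {
  effs <- rbind(
    annotate_effect(tx_variant(40L, "T", "A", "v1"), vr_model, vr_seq, vr_cand),
    annotate_effect(tx_variant(14L, "A", "G", "v2"), vr_model, vr_seq, vr_cand),
    annotate_effect(tx_variant(0L, "C", "T", "v3"), vr_model, vr_seq, vr_cand))
  s <- summarize_effects(effs)
  expect_equal(unname(s$class_counts["uSTART_lost"]), 1L)
  expect_equal(unname(s$class_counts["uAUG_gained"]), 1L)
  expect_equal(unname(s$class_counts["no_uorf_effect"]), 1L)
  expect_equal(s$n_affecting, 2L)
  expect_equal(s$n_total, 3L)
  expect_equal(sum(s$class_counts), nrow(effs))
  s0 <- summarize_effects(effs[0, ])
  expect_true(all(s0$class_counts == 0L))
})
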