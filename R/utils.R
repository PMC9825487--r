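# Shared small helpers. All sequences are DNA letters (ACGT), transcript
# orientation; all internal coordinates 0-based half-open.

STOP_CODONS <- c("TAG", "TGA", "TAA")
START_CODONS <- c("ATG", "CTG", "GTG", "TTG", "ACG")

#' Reverse complement of a DNA string
#' @param x character scalar (ACGTN)
#' @return character scalar
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# codon at 0-based position p of transcript sequence (character scalar)
codon_at <- function(seq, p) substr(seq, p + 1L, p + 3L)

# all codons of seq[start, end), end - start divisible by 3
codons_of <- function(seq, start, end) {
  if (end <= start) return(character(0))
  starts <- seq.int(start, end - 3L, by = 3L)
  substring(seq, starts + 1L, starts + 3L)
}

# translate a codon vector with the standard genetic code; stops -> "*"
translate_codons <- function(codons) {
  gc <- Biostrings::GENETIC_CODE
  aa <- unname(gc[codons])
  if (anyNA(aa)) aa[is.na(aa)] <- "X"
  aa
}

# width on the reference of a CIGAR string (M/D/N/=/X consume reference)
cigar_ref_width <- function(cigar) {
  vapply(cigar, function(cg) {
    ops <- gregexpr("[0-9]+[MIDNSHP=X]", cg)[[1]]
    if (ops[1] == -1L) return(NA_integer_)
    toks <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1]]
    n <- as.integer(sub("[A-Z=]$", "", toks))
    op <- sub("^[0-9]+", "", toks)
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

# stable, locale-independent string ordering (C collation)
c_order <- function(x) order(x, method = "radix")

`%||%` <- function(a, b) if (is.null(a)) b else a
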