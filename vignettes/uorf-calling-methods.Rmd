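---
title: "Methods: uORF discovery, translation calling, and 5'UTR variant annotation"
author: "uorfkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: uORF discovery, translation calling, and 5'UTR variant annotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models and procedures implemented in `uorfkit`,
the parameters that matter, the design choices made where the design was
genuinely open, and what the simulation-based tests do and do not show
about real data.

## Coordinates and sequences

All internal coordinates are 0-based half-open in transcript orientation;
the GTF reader/writer and the VCF reader convert between this and their
1-based inclusive dialects at the I/O boundary only, so off-by-one
reasoning is confined to two functions. Transcript-to-genome projection is
implemented directly on the exon structure (a cumulative-offset walk) and
is checked per base against an independent iteration oracle on randomly
generated multi-exon models on both strands.

Sequences are held as DNA letters (`ATG`, not `AUG`) everywhere, including
the Kozak motif definitions; this avoids U/T mismatches between genome
FASTA, reads, and VCF alleles. When a GTF carries `stop_codon` features
outside the CDS span (the GENCODE convention), the stop codon is appended
to the CDS; when a transcript has several CDS fragments, the CDS span is
their min–max. Transcripts with no 5'UTR are retained — they simply yield
no candidates — and flagged, as are transcripts with annotated-incomplete
CDS ends, which are treated at face value.

## Candidate enumeration

Every occurrence of a start codon (ATG, CTG, GTG, TTG, ACG by default)
strictly upstream of the CDS start is extended in frame to the first stop
codon (TAG/TGA/TAA). In-frame ORFs that reach the transcript end without a
stop share the CDS stop codon and are N-terminal extensions; out-of-frame
ORFs without a stop are not start-to-stop ORFs and are discarded. An ORF
whose start lies at or after the CDS start is never a uORF.

**Minimum length.** The minimum of 18 nt corresponds to six amino acids and
is therefore applied to the coding portion of the ORF, excluding the stop
codon (the shortest emitted uORF spans 21 nt including its stop). The
parameter (`min_len_nt`) is configurable for users who prefer the
stop-inclusive convention.

**Classification** uses only two facts — whether the ORF end passes the CDS
start, and the reading frame relative to the CDS — so the three categories
(non-overlapping, out-of-frame overlapping, N-terminal extension) are
mutually exclusive and exhaustive by construction. This is verified as a
property over random transcripts against a brute-force per-position oracle.

**Peptides.** The first codon is translated as methionine regardless of
near-cognate identity, because the initiator tRNA delivers Met; without
this rule the peptide of a CTG-start uORF would be ill-defined.

**Kozak context** is classified on the 7-mer covering −3..+4: strong when
−3 is A/G *and* +4 is G, moderate when exactly one holds, weak otherwise.
The motif classes are AUG-anchored, so non-ATG starts are
`not_applicable` rather than being given invented context rules; likewise
a start too close to the transcript 5' end to have a −3 base.

**Isoform collapsing** merges candidates whose genomic block lists are
identical; transcript-space coordinates are not sufficient (two isoforms
can place the same transcript interval on different exons).

## P-site processing

Collapsed FASTA follows the `>id_xCOUNT` dialect; multiplicities propagate
through alignment ingestion via the read name. BAM records are dropped if
soft-clipped (end-to-end alignments only) or multimapping (NH tag > 1);
genome-space records are projected through the exon structure onto
strand-matched transcripts, and intronic positions are dropped with a
counter. A plain four-column TSV (`transcript_id`, `tx_pos`, `read_length`,
`count`) serves as an aligner-independent interchange format.

**Offset calibration.** The P-site of a ribosome-protected fragment sits at
a length-dependent offset from the read 5' end. For each read length in
27–32 nt, the offset is chosen in `[10, L − 10]` to maximize the
translation-boundary contrast: reads whose offset P-site lands exactly on
an annotated CDS start, minus reads landing one codon upstream (a position
initiating ribosomes do not protect). The subtraction makes the estimate
identifiable even for libraries with flat coverage along the CDS, where the
raw start-codon count alone ties across offsets congruent modulo 3. Ties
break toward the smaller offset; length classes with fewer than 500 reads,
or without positive contrast, fall back to 12 nt and are flagged. A
user-supplied two-column offset table overrides calibration entirely.
Offsetting conserves counts within the length filter except for the rare
read whose P-site would leave the transcript.

## Quality control

Three admission gates, applied per library:

* **size**: collapsed FASTA larger than 5 Mb (5×10⁶ bytes, the file as
  given), or — in count mode, the testable in-memory proxy — at least
  100,000 reads;
* **length**: at least 90% of reads within 26–34 nt *and* the modal length
  within 27–32 nt, argmax ties resolved toward the smaller length. The 90%
  tolerance is a choice this package makes explicit (and configurable): a
  literal "all reads within 26–34" would reject every real library;
* **frame**: frame 0 — defined as `(p_site − cds_start) mod 3` over
  CDS-internal P-sites only — must be the modal frame *and* hold strictly
  more than 50% of CDS P-sites (a fraction of exactly 0.5 fails).

The overall verdict is the conjunction of the three gates, tested
exhaustively over all eight boolean combinations and the boundary cases.

The metagene profile normalizes each transcript's per-nucleotide P-site
density to mean 1 over the transcript, resamples each region (5'UTR, CDS,
3'UTR) to fixed bin counts (50/100/50) by linear interpolation, and
averages across transcripts; transcripts lacking a region contribute only
to the regions they have. Under this normalization a uniform library gives
a flat profile at 1 and a CDS-confined library gives zero UTR bins with CDS
bins above 1 (by the transcript/CDS length ratio); the per-region mean is
*not* separately normalized to 1.

## Active-translation calling

Widely used uORF-calling pipelines delegate the translation call to an
externally trained classifier whose score is not reproducible from its
printed description. `uorfkit` instead defines a
transparent score with the same two ingredients — 3-nt periodicity and
read uniformity — and the same 0.5 default threshold:

* `f0u`: fraction of P-sites in the uORF's own frame among P-sites in the
  scored span, with an exact upper-tail binomial test against p = 1/3;
* `PME`: Shannon entropy of the per-codon count distribution divided by
  `log(n_codons)` (1 = perfectly uniform, 0 = a single-codon point mass;
  zero-count codons enter via 0·log 0 = 0);
* `score = f0u × PME`; a call is active when the span holds at least
  `min_reads` (10) P-sites, the binomial p-value is below 0.05, and the
  score reaches 0.5.

The scored span excludes the stop codon, and for CDS-overlapping uORFs
(out-of-frame and N-terminal extensions) it is truncated at the CDS start:
mixing CDS P-sites into an extension uORF would trivially inflate its
score. A consequence users should expect: an N-terminal extension starting
very close to the CDS has a short scored span and will rarely reach
`min_reads` — such uORFs are better interrogated with initiation-enriched
protocols, which are out of scope here. The `min_reads` floor of 10 is this
package's own guard against calling on one or two reads. Both `f0u` and
`PME` are invariant to scaling all counts by a positive constant; the
binomial test is not, which is intentional — evidence should grow with
depth.

Equivalence with externally trained classifiers is explicitly not claimed;
the calibration and power of this score are measured directly (below).

**Representative selection.** Among active uORFs sharing a stop codon on
one transcript, candidates are ordered AUG starts first (each by ascending
start position), then near-cognate starts — the selection rule is defined for AUG starts,
and the same closest-to-5' logic is applied to near-cognate groups as the
natural extension. Starting from the first candidate,
selection advances to the next whenever zero P-sites (offset P-sites, not
raw 5' ends — a convention this package fixes explicitly)
fall between the current and next start; the first candidate that fails to
advance is the representative. Exactly one representative per group, by
construction and by property test.

## Variant-effect annotation

Variants from a VCF are projected per transcript; records whose REF span is
intronic or crosses an exon junction are not annotatable in transcript
space and are skipped, and a deletion spanning the 5'UTR/CDS boundary is
flagged (`spans_cds_boundary`) rather than silently dropped or
misclassified. Annotation proceeds only when the VCF REF matches the
transcript sequence — a mismatch raises an error naming the position, since
it means the VCF and annotation disagree about the genome.

The alternate allele is applied to the transcript sequence and each
existing candidate is examined in a fixed precedence: a direct hit
destroying the start codon (`uSTART_lost`) or the stop codon
(`uSTOP_lost`); a length-changing indel inside the candidate that touches
neither (`uFrameshift`); for frame-preserving changes, a rescan from the
start detecting an earlier (`uSTOP_gained`) or later/absent (`uSTOP_lost`)
first in-frame stop; finally a Kozak class change of a surviving ATG start
(`kozak_changed`). The precedence order puts direct start/stop hits first
because an indel through the start codon is primarily a start loss, but a
frameshifting indel *not* touching the stop is reported as `uFrameshift`,
not as the stop displacement it implies — otherwise the frameshift class
could never occur. Newly created start codons are detected by local
re-enumeration of the codon windows overlapping the changed bases; a gain
is reported (`uAUG_gained`, the class name covering gained near-cognate
starts too) only when the new start extends to a valid candidate under the
same rules as primary enumeration.

A known boundary: a variant whose only consequence is to rescue an ORF
that was previously below the minimum length (for example, a stop loss
extending a 15-nt ORF to 24 nt) is reported as `no_uorf_effect`, because no
*candidate* uORF was affected. The acceptance tests check the implications
of every reported effect against a full re-enumeration of the mutated
transcript; completeness is claimed for effects on candidates and for
gained starts, not for effects on sub-threshold ORFs.

## The synthetic-data generator

The generator exists so that every claim above is testable with exact
ground truth. Its key device is start-codon-suppressed background
composition: 5'UTR and 3'UTR backgrounds are drawn from {A, C, T} — every
recognised start codon contains G, so no start codon can arise outside the
planted elements — and CDS interiors from {A, C, G}, so no stop codon can
arise inside the CDS in any reading frame. Planted uORFs (any of the three
categories, any start codon), armed gain sites (an `ATA` one substitution
away from creating a valid ATG uORF), weak Kozak contexts, and
shifted-frame stops inside the CDS for overlapping uORFs are therefore the
*only* structures present, and enumeration on a simulated transcript must
return exactly the planted set — which is asserted, not assumed.

The RPF simulator draws P-sites per translated region (codon positions
multinomial-uniform, in-frame with probability `frame0_prob`, the rest
split equally between the other frames), assigns read lengths from a
configurable distribution (default peaked at 28–29 nt within 27–32), and
derives 5' ends by subtracting per-length offsets. Untranslated planted
uORFs receive frame-uniform background at a stated rate, and low-rate
frame-uniform noise covers the whole transcript. The VCF simulator
engineers one variant per requested effect class against the planted
structures, using alleles that avoid introducing G so the effect classes
stay pure; an infeasible request (more variants than plantable sites) is a
parameter error, not a silent truncation.

What the simulations do **not** emulate: nuclease and ligation biases,
nucleotide-composition realism (the suppressed alphabets are deliberately
artificial), contaminant reads, UMI duplication structure, multimapping
ambiguity, or annotation errors. Passing the simulation-based tests
demonstrates the correctness of the algorithms under their stated model,
not the biological error rate on real libraries.

A single integer seed governs all randomness; per-transcript generator
streams are split from it, so outputs are byte-identical across runs of
the same configuration.

## Problem sizes and measured behaviour

The test suite and the acceptance script run at sizes chosen to make the
statistical checks meaningful while staying desk-scale: 500 random
transcripts (5'UTRs up to 600 nt) for the enumeration oracle; 1000 random
exon models for exhaustive per-base coordinate round-trips; 1000 planted
uORFs each for caller calibration (frame-uniform background, ~25–40
P-sites per uORF) and power (frame-0 probability 0.9, ≥ 30 P-sites);
60-transcript pipelines for end-to-end truth recovery at 1 P-site/nt; and
five planted variants per effect class plus 200 random variants for the
variant-annotation oracle. Calibration is asserted as a false-positive
rate at most 5% plus three binomial standard errors; power as at least
95% of qualifying uORFs called active; end-to-end sensitivity and
precision as at least 95% each. The end-to-end tests supply the
simulator's own offset table to the pipeline, isolating caller behaviour
from offset-estimation noise on small libraries; offset estimation is
validated separately at 500+ reads per length class, where planted
per-length offsets in 10–14 nt are recovered exactly.

## Defaults

| parameter | default | meaning |
|---|---|---|
| `start_codons` | ATG, CTG, GTG, TTG, ACG | recognised initiation codons |
| `min_len_nt` | 18 | minimum coding length, nt, stop excluded |
| `length_filter` | 27–32 | RPF lengths entering P-site profiles, nt |
| offset fallback | 12 | P-site offset when calibration is not possible, nt |
| `score_threshold` | 0.5 | minimum `f0u × PME` for an active call |
| `periodicity_alpha` | 0.05 | binomial test significance level |
| `min_reads` | 10 | minimum P-sites in the scored span |
| size gate | > 5 Mb / ≥ 1e5 reads | library admission floor |
| length gate | ≥ 90% in 26–34 nt, peak in 27–32 nt | footprint size rule |
| frame gate | frame 0 modal and > 50% | periodicity admission rule |

Every default is overridable per call, via the pipeline configuration file,
or by command-line flag (flag beats file beats default).
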