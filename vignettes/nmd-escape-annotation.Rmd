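---
title: "Predicting escape from nonsense-mediated decay for PTC variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting escape from nonsense-mediated decay for PTC variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmdescape)
library(tibble)
```

## The model

Nonsense-mediated mRNA decay (NMD) degrades transcripts whose translation
terminates prematurely. The dominant mechanistic account is the
exon-junction-complex (EJC) model: EJCs deposited ~20–24 nt upstream of
each exon–exon junction are normally displaced by the ribosome; a
termination event that leaves an EJC on the mRNA recruits the NMD
machinery. Several well-replicated exceptions let a premature termination
codon (PTC) escape:

* **Last coding exon** — no junction, hence no EJC, downstream of
  termination.
* **Penultimate exon, ≤ `d_pen` bp from its 3' boundary** (default 50 bp,
  the "50-nt rule") — the terminating ribosome physically displaces the
  last EJC.
* **Close to the coding start site, ≤ `d_css` bp** (default 150 bp) —
  translation reinitiation and inefficient termination near the start
  blunt NMD.
* **Exon spanning more than 407 bp** — empirically, long exons harbour
  NMD-escaping PTCs.
* **Intronless transcript** — no EJC is ever deposited.

`nmdescape` evaluates all five rules for every variant–transcript pair
where they are applicable and reports them individually; `escape_any` is
the disjunction over an arbitrary enabled subset, so users who trust only
the EJC-related rules can restrict to them without recomputation.

## From variant to PTC location

The unit of annotation is a *(normalized biallelic variant, transcript)*
pair. The pipeline is:

1. **Normalization.** Indels are left-aligned and made parsimonious
   (truncate shared trailing bases, extending leftward from the genome
   when an allele empties; then trim shared leading bases down to the
   anchor). The operation is idempotent and preserves the edit; SNVs are
   fixed points.
2. **Overlap classification.** A variant is analyzable on a transcript
   only when its reference span lies entirely inside one CDS interval.
   Spans crossing an exon–intron boundary, or touching the intronic
   splice-region margin, are excluded from analysis rather than guessed
   at — splice-disruption prediction is out of scope. The margin defaults
   to the 2 canonical donor/acceptor bases; exonic bases adjacent to a
   junction are *not* excluded. This is deliberately the minimal
   defensible exclusion; it is a parameter (`splice_margin`) for users
   who prefer a wider definition.
3. **Mutant sequence reconstruction.** The spliced reference sequence
   from the coding start site through the annotated transcript 3' end is
   built (CDS plus 3'UTR), and the alternate allele is substituted at the
   spliced-CDS position of the variant's transcript-5'-most affected base
   (alleles reverse-complemented on minus-strand transcripts). Extending
   the scan space through the 3'UTR is what lets frameshift-induced PTCs
   downstream of the canonical stop be found. The scan stops at the
   annotated transcript end: a frameshifted ribosome that reaches the
   poly(A) without terminating yields "no PTC", since stop-loss
   consequences are out of scope.
4. **PTC location.** The mutant sequence is scanned codon by codon from
   position 1; the first stop codon is the candidate PTC. If that stop
   occupies the canonical stop's position (after adjusting for the
   variant's length change), termination is not premature and no PTC is
   reported — a variant that recreates or retains the canonical stop
   in-frame is not a PTC.
5. **Rule evaluation.** The PTC codon's three nucleotides are mapped back
   to reference-CDS coordinates (identity upstream of the variant, clamp
   to the anchor inside an inserted span, shift by the length difference
   downstream), and the rules are applied.

### Coordinate and boundary conventions

All interval inputs (GTF, VCF) are 1-based and closed. Spliced-CDS
position 1 is the first base of the start codon. Two boundary readings
were genuinely open and are fixed as follows:

* "within d bp" is **inclusive** (≤ d) for the penultimate and CSS rules;
  "more than 407 bp" is **strict** (> 407). The latter is forced by the
  wording of the rule; the former is a documented choice.
* The CSS distance is measured in **mutant** CDS coordinates
  (`alt_first_nt`), because the PTC may lie inside inserted sequence that
  has no reference coordinate at all. It is the package's view that a
  reinitiation-based mechanism sees the mutant message; the parameter
  `d_css` remains adjustable for users who disagree.
* The penultimate-rule distance is measured **along the spliced CDS**
  from the junction-proximal PTC nucleotide, not restricted to PTCs
  physically inside the penultimate exon: EJC logic concerns the distance
  to the last junction, and a short penultimate exon lets a PTC in an
  earlier exon qualify.
* The exon-size rule uses the **full annotated genomic exon width**, UTR
  included — the rule is stated for "an exon spanning more than 407 bp"
  without qualification. This is switchable in principle by filtering
  annotation inputs; the package keeps the literal reading.
* A PTC's exon ordinal counts all exons in transcript orientation,
  including pure-UTR first exons.

### Transcript set

Rules are only as good as the transcript models they are evaluated on.
`filter_criteria()` defaults to the stringent high-confidence selection:
protein-coding transcripts on standard chromosomes (chr1–22, X, Y, M and
their non-"chr" aliases) with transcript support level 1 — or missing TSL
for single-exon transcripts, which never receive one — and a CDS length
divisible by three. Additionally, transcripts whose *reference* CDS
contains an internal in-frame stop (annotated readthrough,
selenoproteins) are dropped by default, because the 5'-most *novel* stop
is undefined when the reference already stops early. GENCODE-dialect
annotations keep the terminal stop codon out of the CDS features; the
loader merges `stop_codon` records back in, so all coordinates treat the
CDS as including its stop.

### The SNV index

All PTC-generating SNVs of a transcript set are enumerable: for each CDS
position and each of three alternative bases, a single substitution can
create a stop only in its own codon (given a clean reference ORF), so the
index is built codon-wise; the nine possible edits of the canonical stop
codon itself are the one subtle case and go through full reconstruction
(destroying the stop can expose a downstream one). Entries are keyed
`contig:zero-padded-pos:REF>ALT` — the zero-padding makes lexicographic
order equal numeric order, so the serialized flat file is sorted and
prefix-searchable. A fingerprint of the transcript identifiers and CDS
spans is stored with the index; loading against a different transcript
set fails rather than silently mis-annotating. Lookup results are
identical to on-the-fly reconstruction by construction, and this is
verified exhaustively in the tests.

## What the synthetic fixtures emulate

The package's generator builds deterministic (seeded) fixtures: multi-exon
protein-coding transcripts on both strands with valid CDS structure (ATG
start, single terminal stop, no internal in-frame stop, CDS length
divisible by three), UTRs, introns, GENCODE-style GTF output with separate
`stop_codon` features, and variant sets placed to trigger exactly one
target rule — verified at generation time against the independent oracle.
Engineered layouts (poly-lysine CDS, every codon one substitution from
`TAA`) make exhaustive boundary scans possible.

Default generator conditions: exon counts 1–6, exon widths 120–400 bp
(below the 407 bp threshold, so the large-exon rule fires only in
dedicated layouts), introns 60–200 bp, 5'UTRs 12–90 bp, 3'UTRs 40–110 bp,
half the transcripts on the minus strand. These are compact but
structurally realistic gene models; sizes were chosen so exhaustive scans
(every coding SNV; every codon near a junction) complete in seconds.

What the fixtures do **not** emulate: real exon-size and intron-size
distributions, overlapping genes and shared exons, alternative isoforms of
one locus, NAGNAG/non-canonical splice sites, reference genomes with
ambiguity codes inside CDS, and population allele-frequency structure.
Passing tests therefore demonstrate correctness of the coordinate
arithmetic, reconstruction and rule logic — not calibration of the rules
themselves on biological data, which is taken from the literature.

## Numerical and degenerate-input choices

* Multiallelic records are split before annotation; symbolic alleles
  (`<DEL>`, breakends), spanning-deletion `*` alleles and alleles with
  non-ACGT characters are skipped and counted, never guessed.
* REF/genome mismatches (after uppercasing) and identity records
  (REF == ALT) are per-record errors: dropped and counted, not fatal.
* Left-normalization that would underflow the contig start is an error.
* A variant whose reference span leaves the CDS (including into the
  5'UTR or across the canonical stop into the 3'UTR) is "noncoding" for
  annotation purposes; only fully-CDS-contained spans are assessed.
* `escape_any` over a restricted rule subset zeroes disabled rules only
  in the disjunction; individual flags are always reported in full.
* Annotation is computed per normalized biallelic variant but written
  back onto the original VCF record, keyed by the record's ID (or
  CHROM:POS:REF:ALT); originally multiallelic records carry an `#k`
  allele-index suffix on the transcript field, keeping output
  round-trippable.

## Verification strategy

Two fully independent implementations are compared. The main pipeline
works in spliced coordinates with substring surgery; the oracle edits the
genome sequence itself, shifts annotation intervals, rebuilds the mutant
transcript from a per-base genomic walk, translates through the standard
genetic-code table, and re-derives exon membership from per-base
membership vectors. Agreement is exact over thousands of generated pairs
of all variant classes on both strands (see `scripts/acceptance.R`, which
recomputes this at ≥ 5000 pairs, plus exhaustive per-SNV index checks and
≥ 1000-indel normalization checks; the test suite runs the same checks at
slightly smaller sizes).

Boundary verification exploits the fixtures: penultimate-rule distances
take every integer value across three transcripts whose junction position
covers all residues mod 3, so the 50/51 flip is observed directly. A
PTC's 5'-most nucleotide is always a mutant-frame codon start (1 mod 3),
so mutant-CDS positions 149/150 are unreachable by any variant; the CSS
boundary is therefore verified with bracketing probes at 148 and 151 and
a parameter sweep recovering 150 as the largest `d_css` that leaves the
151-probe unflagged. Exon widths are fully controllable, giving the
407/408 flip directly.

## Known limitations

* Boolean flags only — no continuous NMD-efficacy score, and no
  tissue-specific adjustment.
* Splice-region and boundary-crossing variants are excluded, not
  annotated; no splice-disruption prediction.
* No start-loss or stop-loss consequence calling; a frameshift that never
  terminates before the annotated transcript end reports no PTC.
* Transcripts whose CDS is discontiguous in spliced coordinates, or whose
  reference ORF contains internal stops, are skipped or filtered.
* The rules themselves are heuristics with unequal, context-dependent
  accuracy; rule-specific output exists precisely so downstream users can
  weight them.
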