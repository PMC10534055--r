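# nmdescape

Annotate premature-termination-codon (PTC) variants for predicted escape
from nonsense-mediated mRNA decay (NMD).

## The problem

Variants that put a premature stop codon into a transcript — stop-gain
SNVs, but also frameshifting insertions and deletions whose new stop
appears far downstream of the variant site — usually trigger NMD and act
as loss-of-function alleles. A substantial minority of PTC-bearing
transcripts *escape* NMD: the truncated protein is made, opening the door
to dominant-negative and gain-of-function disease mechanisms. Whether a
given PTC escapes is well predicted by where it falls in the transcript's
intron–exon structure.

`nmdescape` evaluates five established escape rules for every
variant–transcript pair, and reports each rule separately so users can
restrict attention to the subset they trust (for example, only the
exon-junction-complex rules):

| rule | predicted escape when |
|---|---|
| last exon | the PTC lies in the last coding exon (no EJC downstream of termination) |
| penultimate exon | the PTC lies within d_pen = 50 bp upstream of the 3' boundary of the penultimate coding exon, measured along the spliced CDS |
| CSS proximal | the PTC's 5'-most nucleotide lies within d_css = 150 bp of the coding start site, in mutant-CDS coordinates |
| 407 bp exon | the PTC lies in an exon spanning more than 407 bp |
| single exon | the transcript is intronless |

Distances use the PTC nucleotide closest to the relevant anchor; "within
d bp" is inclusive, "more than 407 bp" is strict. A pair conforming to any
enabled rule is annotated `escape_any`.

What sets the method apart from stop-gain-only annotators: the mutant
coding sequence is reconstructed explicitly for every non-SNV variant, so
frameshifts with downstream PTCs are found (the scan continues through the
3'UTR), and both the **size and the content** of inserted sequence count —
an insertion carrying an in-frame `TAA` is recognized as placing the PTC
inside the inserted bases. Stop-gain SNVs can be resolved through a
precomputed index of every PTC-generating SNV of the transcript set,
stored under `contig:zero-padded-pos:REF>ALT` string keys.

## Worked example

Everything below is synthetic and generated in code — the package ships a
fixture generator that emits a genome FASTA, a GENCODE-dialect GTF and
rule-targeted variants with known structure.

```r
library(nmdescape)
library(tibble)

fx <- synth_genome_and_annotation(fixture_spec(n_transcripts = 6, seed = 1))
g  <- load_genome(fx$fasta)
ts <- filter_transcript_set(load_transcript_models(fx$gtf), genome = g)

pl <- tibble(transcript_id = c("TX002", "TX003", "TX005"),
             target_rule   = c("last_exon", "penultimate", "css_proximal"),
             variant_class = c("snv", "snv", "ins"))
vs <- synth_variants(ts, g, pl, seed = 3)

vs |>
  left_normalize(g) |>
  annotate_variants(ts, g) |>
  dplyr::select(source_id, transcript_id, variant_class,
                is_ptc, last_exon, penultimate, css_proximal, escape_any)
```

```
           source_id transcript_id variant_class is_ptc last_exon penultimate css_proximal escape_any
1 TX002:stopgain:664         TX002           snv   TRUE      TRUE       FALSE        FALSE       TRUE
2 TX003:stopgain:946         TX003           snv   TRUE     FALSE        TRUE        FALSE       TRUE
3       TX005:ins:42         TX005           ins   TRUE     FALSE       FALSE         TRUE       TRUE
```

Each row is one variant–transcript pair. The first is a stop-gain SNV in
the last coding exon of TX002 (escapes by the last-exon rule); the second
sits within 50 bp of TX003's penultimate exon junction; the third is an
insertion on the minus-strand transcript TX005 carrying an in-frame stop —
the PTC lies inside the inserted sequence, 42 bp into the mutant CDS, so
it escapes by the CSS-proximity rule. `summarize_annotation()` gives
one-row totals and `plot_rule_summary()` a per-rule bar chart.

End-to-end VCF annotation (the same operation the `exec/nmdescape` CLI
wrapper exposes):

```r
cmd_annotate(fx$fasta, fx$gtf, "variants.vcf", "annotated.vcf")
```

adds to each annotated record an INFO entry such as

```
AENMD=TX002|1|1|0|0|0|0
```

(`transcript_id|is_ptc|last_exon|penultimate|css_proximal|exon407|single_exon`),
leaves all other records untouched, and writes a key=value summary
sidecar. `cmd_build_index()` precomputes the stop-gain SNV index; an
index is fingerprinted against its transcript set and refuses to load
against any other.

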