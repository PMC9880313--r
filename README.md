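# stopfate

NMD-aware re-annotation of premature termination codon (PTC) variants.

## The problem

Standard annotation pipelines describe every stop-gained or frameshift
variant as a *protein truncation* (`p.Trp24Ter`, `p.Lys199Thrfs*3`). But most
PTC-containing mRNAs are recognised and degraded by nonsense-mediated decay
(NMD), so no protein — full-length or truncated — is ever made. A
non-existent protein cannot be truncated: the correct annotation in that case
is *missing RNA* / *missing protein* (HGVS `r.(0)` / `p.(0)`, VariO:0245 /
VariO:0240), and the truncation annotation (VariO:0015) is only right when
the transcript *escapes* NMD. The distinction matters clinically: a truncated
protein can retain residual activity or mislocalise, a missing protein
cannot.

`stopfate` decides, per variant, which of those outcomes is predicted:

1. **Consequence engine** — applies the HGVS c. edit to the coding sequence
   and scans codon by codon. An edit whose net length change is not divisible
   by 3 shifts the reading frame and typically introduces a PTC soon after
   the edit site; the scan walks the new frame (through the 3' UTR if
   needed) to the first stop, yielding the `fs*N` offset.
2. **NMD classifier** — locates the PTC on the exon scaffold and applies the
   escape/attenuation rules in a declared precedence:
   - *single-exon / last-exon rule*: PTCs in the final exon escape NMD →
     **ESCAPE**;
   - *50 nt rule*: PTCs in the last 50 nt of the penultimate exon escape →
     **ESCAPE**;
   - *start-proximal rule*: PTCs within 150 nt of the start codon may evade
     degradation → **INTERMEDIATE**;
   - *long-exon rule*: a PTC exon longer than 400 bp reduces NMD efficiency
     → **INTERMEDIATE**;
   - otherwise → **TRIGGER** (efficient NMD).
3. **Emitter** — writes the corrected HGVS r./p. strings and VariO terms,
   a predicted-loss-of-function *type* tag (stop_gained / frameshift /
   essential_splice — a variant-type label, never a functional claim), and
   caveats. Apparently-synonymous substitutions within a few nt of a splice
   junction are flagged as candidate *unsense* variants (VariO:0514).

All thresholds are configurable (`NmdRuleConfig`, YAML/JSON config, CLI
flags). Everything runs on self-contained JSON transcript fixtures — no
downloads — and equally on GTF/GFF3 + FASTA and VCF input.

## Worked example

Two bundled synthetic fixtures mirror classic cases: a dystrophin-like
transcript (3,685 aa, 79 exons) and a Bruton-tyrosine-kinase-like transcript
(659 aa, 19 exons).

```r
library(stopfate)

btk <- loadFixture(system.file("extdata", "btk_like_tx.json", package = "stopfate"))
annotateVariants(btk, "c.592_595delinsCTAACTACATA")[[1]]
#> AnnotationRecord: c.592_595delinsCTAACTACATA on BTK_like
#>   consequence: frameshift_with_ptc; NMD fate: TRIGGER [none]
#>   r.(0) / p.(0)
#>   VariO: rna=VariO:0245 missing RNA protein=VariO:0240 missing protein; plof=frameshift
```

The out-of-frame indel (net +7 nt) shifts the frame at Lys199 and stops
three codons into the new frame — conventionally `p.Lys199Thrfs*3`. The PTC
sits mid-transcript in exon 8 of 19, no escape rule applies, so NMD degrades
the transcript: the corrected annotations are `r.(0)` and `p.(0)` with
*missing RNA* / *missing protein*.

```r
dmd <- loadFixture(system.file("extdata", "dmd_like_tx.json", package = "stopfate"))
annotateVariants(dmd, "c.72G>A")[[1]]
#> AnnotationRecord: c.72G>A on DMD_like
#>   consequence: nonsense; NMD fate: INTERMEDIATE [start_proximal]
#>   r.(72g>a) / p.(Trp24*)
#>   VariO: rna=NA protein=VariO:0015 protein truncation; plof=stop_gained
```

Here the stop at codon 24 lies 70 nt into the CDS — inside the 150 nt
start-proximal window — so degradation may be incomplete: the record keeps
the truncation form with an explicit residual-expression caveat.

Command line:

```sh
stopfate annotate --transcripts btk_like_tx.json --variants variants.txt --out annotated.tsv
stopfate sweep --rule penultimate_50nt
```

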