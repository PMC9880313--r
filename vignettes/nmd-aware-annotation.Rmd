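---
title: "Methods: NMD-aware consequence annotation"
author: "stopfate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: NMD-aware consequence annotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stopfate)
```

## The model

A premature termination codon (PTC) is a stop codon (TAA/TAG/TGA) arising
upstream of the reference stop, through a nonsense substitution or through a
frame-shifting indel. Whether such a variant yields a *truncated protein* or
*no protein at all* is decided not by the codon change but by its context on
the transcript: nonsense-mediated decay (NMD) degrades most PTC-bearing
mRNAs, and only transcripts matching one of a small set of escape geometries
survive to be translated.

`stopfate` models this in three stages, all in 1-based, inclusive
transcript/CDS coordinates — the same frame HGVS c. notation uses. Genomic
coordinates are converted once at ingestion (GTF/GFF3 or VCF) and never used
downstream, because every rule in the classifier is transcript-relative.

### Consequence scan

The variant is applied to the coding sequence as a pure string edit; the
reference and mutated sequences are then compared codon by codon from codon
1. The net length change modulo 3 determines the frame offset. For
frame-preserving edits a premature in-frame stop is a stop-gained
(nonsense) outcome; for frame-shifting edits the scan walks the shifted
frame until the first stop. Two details matter:

* **The scan extends past the reference stop into the 3' UTR.** A shifted
  frame does not see the old stop codon, so the `fs*N` offset can only be
  computed on the spliced sequence beyond the CDS. A shifted frame reaching
  the transcript 3' end without a stop is reported as
  `frameshift_no_ptc`; so is the (rare) frameshift whose first new-frame
  stop maps at or downstream of the reference stop, with a caveat — neither
  is a premature termination.
* **PTC position convention.** NMD rules need the stop's position on the
  exon scaffold. `ptcCdsPos` is the first nucleotide of the new stop codon
  in reference-CDS coordinates. For frameshifts the mutated-mRNA position is
  mapped back through the edit: positions 5' of the edit are shared,
  positions 3' of it shift by the net length change, and positions falling
  *inside* an inserted block clamp to the edit start (with a caveat on the
  record). The clamp is the conservative choice: it keeps the measurement on
  the exon that physically contains the edit.

Degenerate inputs fail loudly rather than guess: any codon containing N
aborts the scan with a typed condition; a reference CDS with an internal
stop (a fixture bug) is a validation error; a lost reference stop
(`stop_lost`) is classified and passed through with a caveat but never fed
to the NMD rules, which are defined only for premature stops.

A frame-preserving multi-nucleotide edit that creates an in-frame premature
stop is classed `nonsense` as well — the mRNA-level outcome (a stop-gained
codon) is identical to the single-base case.

### NMD rule set and precedence

Four published geometries are evaluated, with thresholds in
`NmdRuleConfig`:

| rule | threshold (default) | fate |
|---|---|---|
| single-exon / last-exon | — | ESCAPE |
| penultimate-exon 3' window ("50 nt rule") | `penultimateWindowNt` = 50 nt | ESCAPE |
| start-proximal | `startProximalNt` = 150 nt | INTERMEDIATE |
| long exon | `longExonNt` = 400 bp | INTERMEDIATE |

The literature lists these rules without an ordering, so the precedence is
this package's own design: **escape rules are evaluated before attenuation
rules before the TRIGGER default.** Escape rules describe geometries where
degradation does not occur at all, so they must dominate efficiency
modifiers; a PTC in the last exon escapes regardless of how close it sits
to the start codon. Within the winning class all applicable rules are
listed, so a start-proximal PTC in a long exon reports both.

Start-proximal maps to INTERMEDIATE, not ESCAPE, because the evidence for
it is hedged ("may not cause degradation"); both the threshold and the
fate it maps to would be the natural knobs to revisit as quantitative NMD
data improve.

Measurement conventions the literature leaves open, fixed here once:

* The 50 nt distance runs from the **first nucleotide of the stop codon**
  to the 3' end of the penultimate exon, inclusive — the junction-adjacent
  nucleotide is distance 1, so distances 1..50 escape and 51 does not.
* A stop codon straddling an exon junction is assigned to the exon holding
  its first nucleotide, and the verdict's confidence note records this.
* Single-exon transcripts are classified ESCAPE (no exon-junction complex
  downstream of any stop); the published rule statistics restrict
  themselves to multi-exon transcripts, so this is an extrapolation and is
  labelled by its own rule name.
* Modifiers that are named but not quantified in the literature — last
  exon size, re-initiation of transcription, splice site rescue — are not
  scored; their names appear verbatim in the confidence note of non-TRIGGER
  verdicts so downstream users know what was not evaluated.

### Emission

TRIGGER emits `r.(0)` / `p.(0)` with VariO:0245 *missing RNA* and
VariO:0240 *missing protein*. ESCAPE emits the RNA-level edit and a
Ter/fs-Ter protein string with VariO:0015 *protein truncation*. A record
can never carry both 0240 and 0015. INTERMEDIATE keeps the truncation-form
HGVS — partial degradation implies some protein may exist, and the less
destructive claim is emitted — together with the caveat "partial NMD
predicted; residual expression possible"; its `varioRna` stays empty
because VariO has no term for a partially degraded transcript.

Parentheses everywhere by default: all outcomes here are computational
predictions with no RNA or protein evidence, so emitted strings are
`r.(0)`, `p.(Trp24*)` etc.; an `asserted` switch drops the parentheses for
records backed by experiment. Every PTC record additionally carries a fixed
caveat that the annotation is a prediction.

The predicted-loss-of-function tag (`stop_gained`, `frameshift`,
`essential_splice`) is assigned from the variant *type* only — never from
the NMD outcome — and always travels with a caveat that type is not
functional effect.

### Unsense screen

Substitutions that are synonymous by the codon table can still abolish the
protein by disrupting splicing (unsense variation, VariO:0514). No motif
models (ESE/ESS hexamers, miRNA seeds, splice-strength scores) are
published with usable parameters in this context, so the only computable
signal is junction proximity: synonymous substitutions within
`windowNt` = 3 exonic nucleotides of a splice junction are flagged as
*candidates* — never classified. Transcript ends are not junctions.
Everything else synonymous passes with a caveat that synonymy is a
codon-table statement only. Intronic ±1/±2 changes route through the
essential-splice plof tag (VCF path), not through this screen.

## Synthetic transcripts

`makeTranscript()` builds transcripts as an ATG, a seeded random fill of
sense codons (no internal stop), one terminal stop, and random-nucleotide
UTRs, on any exon layout. The two bundled fixtures pin down the features
their worked examples need and nothing else:

* `DMD_like` — 3,685 codons + stop (CDS 11,058 nt) over 79 exons, codon 24
  forced to TGG so `c.72G>A` creates TGA: a PTC 70 nt into the CDS, in exon
  1 (300 nt, under the long-exon threshold), hitting the start-proximal
  window.
* `BTK_like` — 659 codons + stop (CDS 1,980 nt) over 19 exons, codons
  198/199 forced to CTA/AAA so `c.592_595delinsCTAACTACATA` leaves codon
  198 silent (CTA→CTA, Leu) and shifts the frame from Lys199 with a stop at
  the third new-frame codon; the PTC lies mid-transcript in exon 8. In both
  fixtures the stop codon falls in the last exon, as in the real genes.

Exon sizes around the pinned features are round numbers chosen to land the
variant sites in the documented exons; the stop-to-poly(A) geometry, UTR
lengths, and all sequence outside the pinned codons are arbitrary. The
generator emulates exon structure and coding constraints only: no splice
site motifs, no codon-usage bias, no GC structure, no alternative
transcripts. Tests passing on these fixtures therefore validate the
coordinate arithmetic and rule logic — they say nothing about transcript
model quality, mapping ambiguity, or biological NMD efficiency on real
data.

The fixtures are committed as JSON and regenerated by
`regenerateFixtures()`; a test asserts byte-identity, so tampering with
either copy is visible.

## The sweep harness

`sweepBoundary()` recovers each rule's empirical boundary. For the
position-based rules it classifies a *hypothetical* PTC at every CDS
position of the template — the classifier needs only a position on the exon
scaffold, so every coordinate is reachable, which a single-nucleotide
nonsense sweep could not achieve (stops are reachable from only about a
third of codons, at codon granularity). `ptcSweep()` separately enumerates
real single-nucleotide nonsense variants for the oracle tests, so both
views exist: every-position boundary location and real-variant end-to-end
sweeps. For the long-exon rule the PTC-bearing exon is grown in 1-bp steps
across a ±10 bp window around the configured threshold.

Problem sizes: the templates are a 3-exon/699 nt-CDS, a 5-exon/498 nt-CDS
and a growable 5-exon transcript (21 lengths); the property suite checks
the codon scan against a brute-force full-translation oracle on 1,000
random edits over ten random transcripts, and the NMD classifier against a
one-expression re-implementation at every CDS position of a five-exon
transcript. These sizes locate every boundary exactly and keep the whole
suite fast.

## Known limitations

* NMD efficiency is modelled as three ordinal fates from published
  geometric rules; no probabilistic or tissue-specific score is attempted,
  and population-scale fractions of triggering/escaping PTCs are outside
  what desk-scale synthetic sweeps can reproduce.
* Translation re-initiation and alternative start sites are reported only
  as free-text caveats when the start-proximal rule fires (a downstream
  start can rescue expression of an N-terminally shorter protein), never
  computed.
* Selenoprotein UGA recoding and ribosomal readthrough are ignored.
* The HGVS subset is the coding-region mini-language the tool needs;
  intronic offsets and UTR positions are deliberately rejected with a
  typed "unsupported-region" error rather than approximated, and
  inversions, repeats and alleles in trans are out of scope.
* VCF indel mapping requires plus-strand transcripts and left-anchored
  alleles fully within one exon's CDS; everything else is reported as a
  per-record error rather than guessed.
* One transcript is annotated at a time; canonical-transcript selection
  across a call set is out of scope.
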