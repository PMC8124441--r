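---
title: "Detecting tRNA-Sec genes nested in selB open reading frames"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting tRNA-Sec genes nested in selB open reading frames}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selnest)
```

## The biological problem

Bacteria insert selenocysteine (Sec) at recoded stop codons using a
dedicated elongation factor, SelB, and a dedicated tRNA, tRNA-Sec (the
*selC* gene product). In several Alphaproteobacteria (and some
Gammaproteobacteria and Nitrospirae) the *selC* gene is not a free-standing
locus: the entire tRNA gene lies **inside the protein-coding region of
selB**, so that the SelB protein carries a C-terminal extension that is the
conceptual translation of the tRNA gene. Around this core arrangement a
family of locus geometries recurs:

* **complete forward nested** — the whole tRNA gene sits in frame inside
  the *selB* ORF; the *selB* stop codon typically overlaps the start codon
  of the next ORF (stop–start translational coupling);
* **adjacent** — a new stop codon has arisen just before the tRNA, ending
  the overlap while keeping the genes contiguous (on either strand);
* **spaced** — *selB* and *selC* are separated by a long spacer;
* **remnant** — only the 5′ half of the tRNA survives inside the ORF
  (e.g. after a transposon insertion), giving a shorter extension;
* **partial overlap** — the *selB* stop codon lies in the middle of the
  tRNA, at residues 46–48 in the Dyella/Luteibacter arrangement;
* **complete reverse** — the reverse complement of the tRNA gene is nested
  in the ORF, with a σ70-like *selC* promoter near the *selB* stop.

`selnest` turns that survey into a reusable, tested pipeline: locate ORFs,
localize tRNA-Sec homology inside ORF windows on both strands, classify
each locus into the archetypes above, extract tRNA gene features, and
compute the translated-extension signatures and their conservation
profile. Because the surveyed loci are published only as figures, the
pipeline is exercised on **synthetic genomes with planted loci** whose
ground truth is known exactly.

## Locus constants the pipeline reproduces

Three positional constants characterize the arrangement and are the
package's worked examples:

* nested tRNA-Sec genes are 96 nt when the CCA tail is gene-encoded and
  93 nt when it is not — both multiples of 3, preserving the host reading
  frame; a 95-nt variant (deletion of residue U66) breaks the
  multiple-of-3 rule;
* in the partial-overlap arrangement the stop codon occupies tRNA
  residues 46–48;
* forward extensions start with Gly (translating the tRNA's initial
  `GGA`) and end with Pro (translating the CCA tail or a remnant `CCN`);
  reverse extensions start with Trp (`TGG`, the complement of the CCA
  end) and end with Pro (`CCN`, the complement of tRNA positions −1..+2).

A frame-arithmetic point worth making explicit: for a reverse-embedded
tRNA the Trp codon sits at the 5′ end of the sense-strand region and the
terminal `CCN` codon extends **one base past** it, so both fall into one
reading frame only when the gene length is ≡ 2 (mod 3). A 95-nt
CCA-encoding tRNA satisfies this; 96 nt would not. The reverse template
therefore plants the 95-nt variant by default, and the package reports
`multiple_of_3 = FALSE` for such calls rather than forcing the flag.

## Pipeline parameters

| parameter | default | meaning |
|---|---|---|
| `min_orf_len` | 300 nt | ORF floor for genome scans (SelB-sized genes are far larger; unit work uses 30) |
| `start_codons` | ATG, GTG, TTG | bacterial initiators; the downstream ORF's start set is a choice, not a literature fact |
| match/mismatch | +2 / −2 | local-alignment scoring; gap open −5, extend −2 per position |
| `min_identity` | 0.75 | identity (matches / alignment columns, gaps included) floor for a reported hit |
| `min_cov_nt` | 30 nt | minimum reference positions covered |
| `flank` | 150 nt | window margin around each ORF |
| `complete_cov` | 0.95 | reference coverage for a COMPLETE call |
| remnant band | [0.30, 0.70) | coverage of a 5′-anchored remnant-grade hit |
| `adjacent_max` | 30 nt | stop-to-tRNA gap separating ADJACENT from SPACED |
| `partial_min_ext` | 12 nt | reference coverage required 3′ of the stop for a PARTIAL call |
| promoter | TTGACA / TATAAT, spacer 15–19, ≤ 4 mismatches | σ70 consensus scan |

The archetypes themselves are qualitative categories; these thresholds
are the package's operational cut points, chosen so the planted
geometries separate cleanly at point-mutation rates up to about 10%.

`partial_min_ext` deserves a note because it is a disambiguation rule the
category list alone does not force. A Smith–Waterman alignment of a
remnant locus will often accrete a few net-positive columns past the
remnant/stop junction, which makes the hit span graze the ORF stop — the
textual definition of a partial overlap. The biological distinction is
that a genuine partial overlap has substantial tRNA sequence continuing
past the stop (~50 reference positions in the residue-46 arrangement),
while a remnant junction has only alignment-tail noise. A PARTIAL call
therefore requires at least 12 reference positions covered 3′ of the
mapped stop, and the remnant rule tolerates the same bounded slack past
the coding span.

## Coordinates, frames and degenerate inputs

* Internally everything is 0-based half-open; GFF3 output is 1-based
  inclusive; `stop_in_trna` is a 1-based tRNA reference coordinate.
* ORF spans include the stop codon; "nested inside the ORF" is evaluated
  against the coding span excluding the stop, since in the canonical
  arrangement the stop follows the tRNA.
* Classification runs in an ORF-forward coordinate frame: scan windows
  are extracted in ORF orientation, so one strand-free decision procedure
  serves both genomic strands, and hit strand is recorded relative to the
  ORF.
* The stop codon is mapped into tRNA coordinates through the alignment's
  column map; a stop base falling in an alignment gap reports the nearest
  aligned reference position with a `gapped` flag, and a stop outside the
  aligned interval reports an absent position.
* The discriminator base is located through the alignment (the base
  matched to the reference position immediately 5′ of the encoded CCA, or
  the 3′ terminus for CCA-less references), so length variants do not
  shift it; an alignment that does not reach it yields "unknown" (`NA`).
* Translation uses the bacterial code (table 11; amino-acid assignments
  identical to the standard table). Ambiguity codes translate when every
  resolution agrees (`CCN` → Pro), else `X`. Internal stops in a mutated
  extension truncate the peptide and flag the signature — conceptual
  translation mirrors what a ribosome would do.
* Alignment tie-breaking is the deterministic choice of the underlying
  dynamic-programming implementation; runs are reproducible but the
  specific tie chosen among equal-scoring alignments is not a contract.

## What the simulator emulates — and what it does not

`generate_dataset()` is a pure function of its configuration: one
sequence per planted locus, each built as background – locus – background.
The reference tRNA is random sequence constrained to the positional
invariants (starts `GGA`, discriminator G, encoded `CCA`, length 96, and
a `CC` acceptor-side motif so CCA-less derivatives still end in a
Pro-encoding `CCN` triplet); the 93/95/A73 variants are single edits of
it. All constraints the analysis asserts are positional or
compositional, so random interiors are an adequate stand-in for the real
(figure-bound) gene sequences; the shipped reference set is synthetic and
labelled as such.

Two engineering details keep the benchmark exact rather than merely
likely:

* **Frame guards.** ORF filler is interspersed with an 8-codon guard
  block that places stop codons in every reading frame except the host
  ORF's own (both forward off-frames and all three reverse frames), and
  intergenic background is punctuated with a self-complementary 12-mer
  carrying stops in all six frames. No spurious ORF ≥ 300 nt can
  therefore arise, which is what makes precision exactly 1.0 at mutation
  rate 0 a fair assertion rather than a coin flip.
* **Junction arithmetic.** The coupled arrangement uses stop codon `TAA`
  (`TAATG` overlap motif). With `TGA`, the junction of a CCA-ending tRNA
  and the stop (`...CCA-TGA-TG...`) contains an earlier in-frame `ATG`,
  and the maximal-ORF convention would report the downstream start 3 nt
  early (overlap 2 instead of 1). Codons ending `..T,A` can never be
  start codons, so `TAA` makes the planted overlap-1 geometry the one the
  scanner recovers. The random tRNA interior is likewise rejection-sampled
  so no start codon opens the coupled downstream frame inside the gene.

Mutations are substitutions only (no indels), applied outside
functionally fixed positions (the `GGA` start, the encoded CCA, planted
stop codons), so length-based expectations stay exact. Background GC is
0.6 (rhizobial-like) by default, and the long-spacer template uses a
100-nt spacer so that, with the default 150-nt window flank, a SPACED
tRNA is still seen by about half its length.

What the simulator does **not** emulate: transposon or insertion-sequence
anatomy behind remnants (only the truncation geometry), SECIS elements
and Sec recoding, tRNA secondary structure (detection is homology-based,
not covariance-model-based), real intergenic composition, and indel
divergence. Passing the benchmark therefore demonstrates the geometry,
classification and signature logic — not detection power against deeply
degenerate remnants in real genomes, for which users can supply real
*selC* references and covariance-model screens remain the stronger tool.

## Benchmark sizes and behaviour

The shipped analysis (and the test suite) uses desk-scale sizes: one
locus per archetype per dataset (~7.6 kb of genome), 20 seeds per
condition, mutation rates {0, 0.05, 0.15}. At rate 0 every archetype is
recovered with sensitivity and precision 1.0; mean sensitivity is
non-increasing in the mutation rate. Background false positives at the
default identity/coverage thresholds are rare, weak (~30-nt, score ≈ 30
versus ≈ 190 for a true hit) and never locus-grade — they are neither
complete-coverage nor 5′-anchored-remnant-grade, so the positional rules
send them to NONE.

## Known limitations

* Homology search against a small reference set replaces curated BLAST
  plus manual inspection; diverged tRNA-Sec genes below ~75% identity to
  any supplied reference are invisible.
* Reverse-strand partial and remnant geometries are representable (the
  hit strand is recorded) but are not given dedicated archetype labels,
  mirroring the reported locus taxonomy.
* The promoter scan is a consensus mismatch count, not an energy or PWM
  model; it marks candidates, it does not predict transcription.
* `NONE` ORFs are suppressed from reports by default (`report_all` to
  include them), so genome-scale output lists positive loci only.
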