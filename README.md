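# selnest

Detection and classification of bacterial selenocysteine tRNA (tRNA-Sec,
*selC*) genes nested inside *selB* elongation-factor open reading frames.

## The problem

In diverse Alphaproteobacteria (and some Gammaproteobacteria and
Nitrospirae) the *selC* gene is not a free-standing locus: the entire
96-nt (or CCA-less 93-nt) tRNA-Sec gene lies **within the protein-coding
region of selB**, so the SelB protein carries a C-terminal extension that
is the conceptual translation of the tRNA gene — starting with Gly
(translating the tRNA's initial `GGA`) and ending with Pro (translating
the CCA tail or a remnant `CCN`). Around this core arrangement a family
of locus geometries recurs: complete forward nesting with stop–start
translational coupling to the next ORF, loss-of-overlap variants (a new
stop codon just before the tRNA, or a long spacer), 5′-half remnants,
partial overlaps in which the *selB* stop codon sits at tRNA residues
46–48, and reverse-complement nesting in which the extension runs
Trp…Pro and a σ70-like *selC* promoter lies near the *selB* stop.

`selnest` is for comparative genomicists who want to find and classify
such loci reproducibly: it locates ORFs, localizes tRNA-Sec homology in
ORF windows on both strands (Smith–Waterman, affine gaps), applies a
total first-match-wins decision procedure over the locus archetypes

```
COMPLETE_FORWARD | COMPLETE_REVERSE | PARTIAL_FORWARD |
REMNANT_FORWARD  | ADJACENT         | SPACED | NONE
```

extracts tRNA gene features (length, encoded CCA tail, discriminator
base, 5′ anchoring), maps the ORF stop codon into 1-based tRNA
coordinates through the alignment, computes extension signatures and a
tRNA-coordinate-anchored conservation profile, and scans for
`TTGACA … TATAAT` promoter box pairs. Because the surveyed loci are
published only as figures, the package ships a deterministic simulator
that plants every archetype with ground-truth labels; the pipeline is
validated by exact recovery on those synthetic genomes.

## Worked example

```r
library(selnest)

ds    <- generate_dataset(gen_config(seed = 1, mut_rate = 0))  # 7 archetypes
calls <- scan_genome(ds$seqs, ds$refs)
calls[, c("seq_id", "archetype", "gene_length", "has_cca", "discriminator",
          "stop_in_trna", "coupling_overlap", "ext_first", "ext_last")]
```

```
  seq_id              archetype        gene_length has_cca discriminator stop_in_trna coupling_overlap ext_first ext_last
1 adjacent_forward_01 ADJACENT                  96 TRUE    A                       NA               NA <NA>      <NA>
2 adjacent_reverse_01 ADJACENT                  96 TRUE    G                       NA               NA <NA>      <NA>
3 complete_forward_01 COMPLETE_FORWARD          96 TRUE    G                       NA                1 G         P
4 complete_reverse_01 COMPLETE_REVERSE          95 TRUE    G                       NA               NA W         P
5 partial_forward_01  PARTIAL_FORWARD           96 TRUE    G                       46               NA G         S
6 remnant_forward_01  REMNANT_FORWARD           48 FALSE   <NA>                    NA               NA G         G
7 spaced_01           SPACED                    50 FALSE   <NA>                    NA               NA <NA>      <NA>
```

Reading the table: the complete forward locus is a 96-nt CCA-encoding
tRNA gene whose host ORF stop overlaps the next ORF's start by 1 nt and
whose extension runs Gly…Pro; the reverse locus is the 95-nt variant
(Trp…Pro extension); the partial locus has its stop codon at tRNA
residue 46; the remnant is the 5′ half (48 nt, no CCA, discriminator not
covered); the adjacent-forward locus carries the non-canonical A73
discriminator. Evaluating against the planted truth:

```r
ev <- evaluate_calls(calls, ds$truth)
ev$sensitivity$sensitivity   # all 1.0
ev$precision                 # 1.0
```

The numbered scripts under `analysis/` run the same workflow as a
narrative: `01_simulate.R` builds clean and 10%-mutated study sets,
`02_scan.R` scans them and writes `calls.gff3` / `report.tsv` /
`conservation.tsv`, `03_evaluate.R` benchmarks recovery over 20 seeds at
mutation rates 0/0.05/0.15, and `04_extension_profile.R` builds the
pooled extension-conservation profile. Outputs land under `results/`.

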