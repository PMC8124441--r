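#!/usr/bin/env Rscript
# Step 1 -- build the synthetic study set.
#
# The survey this package reproduces rests on curated selB loci that are
# not machine-readable, so the study set is simulated: every one of the
# seven selB-selC locus archetypes is planted into guarded random
# background with ground-truth labels. Two collections are written:
#   results/data/clean/   one locus per archetype, no mutations
#   results/data/mut10/   the same templates at 10% point-mutation noise
# plus the synthetic tRNA-Sec reference set (96-nt complete, 93-nt
# CCA-less, 95-nt U66-deletion, A73 discriminator variants).

library(selnest)

dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

clean <- generate_dataset(gen_config(seed = 1, mut_rate = 0),
                          outdir = "results/data/clean")
mut10 <- generate_dataset(gen_config(seed = 1, mut_rate = 0.10),
                          outdir = "results/data/mut10")

cat("clean set:", nrow(clean$seqs), "sequences,",
    sum(nchar(clean$seqs$residues)), "nt total\n")
cat("reference variants:",
    paste(sprintf("%s (%d nt)", clean$refs$variant, clean$refs$length),
          collapse = ", "), "\n")
cat("planted archetypes:\n")
print(table(clean$truth$archetype, clean$truth$trna_strand))
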