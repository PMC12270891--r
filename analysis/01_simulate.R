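#!/usr/bin/env Rscript
# Step 1: simulate the four virus-like coding-sequence sets.
#
# The presets mirror the shape of the honeybee-virus polyprotein study:
# 43 ABPV-like, 57 CBPV-like, 8 KBV-like and 96 SBV-like sequences of
# ~2,800 codons, with third-position GC dials 0.23 / 0.54 / 0.31 / 0.31
# and CpG usage halved within codons. Output: one FASTA per set plus a
# key = value provenance config, under results/simulated/.

suppressPackageStartupMessages(library(cubkit))

seed <- 101L
out_dir <- "results/simulated"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

presets <- virus_presets(seed = seed)
for (v in names(presets)) {
  fasta <- file.path(out_dir, paste0(v, ".fasta"))
  recs <- generate_cds_set(presets[[v]], fasta = fasta)
  cat(sprintf("%s: %d sequences x %d codons -> %s\n", v, length(recs),
              presets[[v]]$length, fasta))
}
cat(sprintf("done (base seed %d)\n", seed))
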