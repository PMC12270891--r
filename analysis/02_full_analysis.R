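#!/usr/bin/env Rscript
# Step 2: run the complete codon-usage-bias analysis on the simulated sets.
#
# Reads the FASTA files written by 01_simulate.R and produces the full
# table surface under results/analysis/: composition (table1), RSCU with
# host columns (table2), CAI/RCDI per host (table3), index correlations
# (table4), ENC/PR2/neutrality/COA plot data and dinucleotide odds ratios.

suppressPackageStartupMessages(library(cubkit))

in_dir <- "results/simulated"
out_dir <- "results/analysis"
viruses <- c("ABPV", "CBPV", "KBV", "SBV")
sets <- stats::setNames(file.path(in_dir, paste0(viruses, ".fasta")), viruses)
if (!all(file.exists(sets))) stop("run analysis/01_simulate.R first")

res <- run_codon_usage_analysis(sets, out_dir = out_dir)

cat("== per-virus summary ==\n")
for (v in viruses) {
  sub <- res$per_seq[res$per_seq$virus == v, ]
  fit <- res$neutrality[[v]]
  cat(sprintf(
    "%-5s n=%3d  ENC=%5.2f  GC3s=%5.3f  CAI(A.mellifera)=%4.2f  slope=%6.3f (R2=%5.3f)\n",
    v, nrow(sub), mean(sub$enc), mean(sub$gc3s),
    mean(sub$cai_apis_mellifera), fit$slope, fit$r_squared))
}
rho <- res$dinuc_grand
cat(sprintf("\nCpG: grand-mean rho(CG) = %.3f (%s-represented)\n",
            rho$rho[rho$dinucleotide == "CG"],
            rho$representation[rho$dinucleotide == "CG"]))
cat(sprintf("COA: axis 1 carries %.1f%%, axis 2 %.1f%% of inertia\n",
            res$coa$inertia_pct[1], res$coa$inertia_pct[2]))
cat(sprintf("\ntables written to %s\n", out_dir))
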