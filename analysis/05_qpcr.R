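#!/usr/bin/env Rscript
# Stage 5: marker frequency analysis by qPCR (delta-delta-Ct).
#
# Simulates quadruplicate Ct tables for amplicons at an origin apex, a
# flank, and a distal locus (plus the chromosome-6-style calibrator at
# ratio 1) and quantifies S-phase DNA relative to G2 = 1.

suppressPackageStartupMessages(library(orcmap))
dir.create("results", showWarnings = FALSE)

cfg <- sim_config(seed = 20120726)
true_ratios <- c(ORI_APEX = 1.8, ORI_FLANK = 1.3, DISTAL = 1.0)
ct <- simulate_qpcr(true_ratios, cfg)
utils::write.table(ct, "results/qpcr_ct.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)

quant <- ddct_table(ct, "CAL")
utils::write.table(quant, "results/qpcr_quantities.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
for (k in seq_len(nrow(quant)))
  cat(sprintf("%-10s S/G2 = %.2f [%.2f, %.2f] (true %.2f)\n",
              quant$amplicon[k], quant$quantity[k], quant$lo[k],
              quant$hi[k], true_ratios[[quant$amplicon[k]]]))
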