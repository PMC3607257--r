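#!/usr/bin/env Rscript
# Stage 1: build the synthetic study genome.
#
# Three megabase-chromosome analogues (2, 1.5, 1 Mbp) with the canonical
# layout [VSG array | subtelomere | core | subtelomere | VSG array],
# alternating-strand directional gene clusters (DGCs) in the core, VSG
# cassettes in the arrays, early-firing origins at a subset of divergent
# strand switch regions, and one silent MVSG-like locus per chromosome.
# The ground truth drives every later stage's recovery check.

suppressPackageStartupMessages(library(orcmap))
dir.create("results", showWarnings = FALSE)

cfg <- sim_config(seed = 20120726)
genome <- generate_genome(cfg)

write_gff3_genes(genome$genes, "results/genes.gff3")
utils::write.table(genome$truth$region_classes,
                   "results/truth_region_classes.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
jsonlite::write_json(
  list(seed = cfg$seed,
       chromosomes = as.list(genome$chromosome_lengths),
       n_genes = nrow(genome$genes),
       n_dgcs = nrow(genome$truth$dgcs),
       n_ssrs = nrow(genome$truth$ssrs),
       n_sites = nrow(genome$truth$sites),
       n_origins = nrow(genome$truth$origins),
       replicated_fraction = genome$truth$replicated_fraction),
  "results/truth_summary.json", auto_unbox = TRUE, pretty = TRUE,
  digits = NA)

cat(sprintf("genome: %d genes on %d chromosomes (%.1f Mbp)\n",
            nrow(genome$genes), length(genome$chromosome_lengths),
            sum(genome$chromosome_lengths) / 1e6))
cat(sprintf("truth: %d DGCs, %d SSRs, %d binding sites, %d origins\n",
            nrow(genome$truth$dgcs), nrow(genome$truth$ssrs),
            nrow(genome$truth$sites), nrow(genome$truth$origins)))
cat(sprintf("expected replicated fraction by mid-S: %.1f%%\n",
            100 * genome$truth$replicated_fraction))
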