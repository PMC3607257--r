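#!/usr/bin/env Rscript
# Stage 3: call ORC1/CDC6 binding sites from tiling-probe signal.
#
# Simulates probe log2 ratios (61 bp spacing, ~4-fold enrichment over the
# true site footprints), runs the sliding-window detector over the
# descending cutoff grid with a 20-permutation randomization FDR, merges
# called sites closer than 10 kb into "unique" sites, and tabulates their
# association with the region classes, SSRs, and DGCs.

suppressPackageStartupMessages(library(orcmap))
dir.create("results", showWarnings = FALSE)

cfg <- sim_config(seed = 20120726)
genome <- generate_genome(cfg)
probes <- simulate_chip(genome, cfg)
cat(sprintf("probes: %d at %d bp spacing\n", nrow(probes),
            cfg$probe_spacing))

sites <- call_sites(probes, seed = cfg$seed + 11)
cat(sprintf("sites by FDR class: %s\n",
            paste(names(table(sites$fdr_class)),
                  table(sites$fdr_class), collapse = ", ")))
print(attr(sites, "fdr_table"))

merged <- merge_sites(sites)
cat(sprintf("%d sites -> %d unique (merge gap 10 kb); true sites: %d\n",
            nrow(sites), nrow(merged), nrow(genome$truth$sites)))

sites$name <- sites$fdr_class
sites$score <- sites$peak_score
write_bed(sites, "results/chip_sites.bed")
utils::write.table(merged, "results/chip_sites_merged.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

assoc <- associate_sites_with_regions(
  sites, genome$truth$region_classes, genome$truth$ssrs,
  genome$truth$dgcs)
utils::write.table(assoc$by_class, "results/chip_by_class.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(assoc$by_feature, "results/chip_by_feature.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
print(assoc$by_class)
print(assoc$by_feature)

# recovery against truth: fraction of true sites hit by a called site
hit <- proximity_and_overlap(genome$truth$sites, sites, within = 0)
cat(sprintf("true sites overlapped by a call: %d / %d\n",
            hit$n_overlap, nrow(genome$truth$sites)))
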