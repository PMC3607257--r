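#!/usr/bin/env Rscript
# Stage 4: map early replication origins by marker frequency analysis.
#
# Simulates S-phase and G2 read depth (negative binomial around the
# semi-analytic copy-number expectation), forms 2,500 bp S/G2 ratio
# tracks normalized to a per-chromosome baseline of 1, calls OBR peaks,
# classifies flank symmetry, estimates fork-rate asymmetry, the
# replicated fraction by region class, the origin-vs-length regression,
# and colocalization of peaks with the merged ChIP sites.

suppressPackageStartupMessages(library(orcmap))
dir.create("results", showWarnings = FALSE)

cfg <- sim_config(seed = 20120726)
genome <- generate_genome(cfg)
depth <- simulate_replication(genome, cfg)

ratio <- do.call(rbind, lapply(names(depth), function(ch)
  ratio_and_normalize(bin_depth(depth[[ch]]$S, chromosome = ch),
                      bin_depth(depth[[ch]]$G2, chromosome = ch))))
bg <- ratio[!is.na(ratio$ratio), c("chromosome", "start", "end", "ratio")]
names(bg)[4] <- "value"
write_bedgraph(bg, "results/mfa_ratio.bedGraph")

peaks <- do.call(rbind, lapply(split(ratio, ratio$chromosome),
                               call_obr_peaks))
rownames(peaks) <- NULL
utils::write.table(peaks, "results/obr_peaks.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat(sprintf("%d OBR peaks called (%d origins planted):\n",
            nrow(peaks), nrow(genome$truth$origins)))
print(peaks[, c("name", "center", "amplitude", "symmetry")])

asym <- vapply(seq_len(nrow(peaks)), function(k)
  fork_rate_asymmetry(peaks[k, ])$fold, numeric(1))
cat(sprintf("fork-rate asymmetry per peak: %s\n",
            paste(sprintf("%.2f", asym), collapse = ", ")))

rf <- replicated_fraction(ratio, genome$truth$region_classes)
cat(sprintf("replicated fraction: %.1f%% (truth %.1f%%), threshold %.3f\n",
            100 * rf$fraction, 100 * genome$truth$replicated_fraction,
            rf$threshold))
print(rf$by_class)

n_peaks <- vapply(names(cfg$chromosomes), function(ch)
  sum(peaks$chromosome == ch), numeric(1))
dens <- origin_density_and_extrapolation(n_peaks, cfg$chromosomes,
                                         analyzed_fraction = 0.5)
cat(sprintf("observed %d peaks -> ~%d predicted origins, 1 per %.0f kb; r = %.2f\n",
            sum(n_peaks), dens$predicted_origins, dens$density_bp / 1000,
            dens$correlation))

probes <- simulate_chip(genome, cfg)
sites <- merge_sites(call_sites(probes, seed = cfg$seed + 11))
colo <- colocalize_peaks_with_features(peaks, sites)
cat(sprintf("%d / %d peaks centre on a merged binding site\n",
            colo$n_matched, colo$n_total))

jsonlite::write_json(
  list(n_peaks = nrow(peaks),
       predicted_origins = dens$predicted_origins,
       density_kb = dens$density_bp / 1000,
       replicated_fraction = rf$fraction,
       colocalized = colo$n_matched),
  "results/mfa_summary.json", auto_unbox = TRUE, pretty = TRUE,
  digits = NA)
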