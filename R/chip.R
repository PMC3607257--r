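## ChIP-chip sliding-window peak detection with randomization FDR.
##
## Probe tracks are data.frames with columns probe_id, chromosome,
## position (probe midpoint, bp), log2_ratio.  The detector follows the
## tiling-array procedure: rescale the track to a minimum of zero, form a
## "hypothetical maximum" M = mean + 6*SD per chromosome, and report every
## 500 bp window holding >= 4 probes above cutoff_fraction * M.  False
## discovery rates per cutoff come from re-running the detector on tracks
## whose probe values are permuted within each chromosome.

#' Rescale probe signals to a minimum of zero
#'
#' Subtracts the per-chromosome minimum so the track minimum is exactly 0;
#' pairwise differences are preserved.
#'
#' @param track probe signal data.frame.
#' @return the track with shifted `log2_ratio`.
#' @export
rescale_min_zero <- function(track) {
  stopifnot(nrow(track) > 0)
  shift <- ave(track$log2_ratio, track$chromosome, FUN = min)
  track$log2_ratio <- track$log2_ratio - shift
  track
}

## Windowed hit evaluation for one chromosome: windows are anchored at
## every probe, spanning [position, position + window).  Returns candidate
## intervals (union of hit windows) as an IRanges.
.detect_chrom <- function(position, value, cutoff_fraction, window,
                          min_probes) {
  n <- length(position)
  if (n < min_probes) return(IRanges::IRanges())
  m <- mean(value) + 6 * stats::sd(value)
  if (is.na(m)) m <- mean(value)           # single probe: sd undefined
  thr <- cutoff_fraction * m
  above <- as.integer(value > thr)
  cum <- cumsum(above)
  ## last probe index with position < p_i + window
  j <- findInterval(position + window - 0.5, position)
  cnt <- cum[j] - c(0, cum)[seq_len(n)]
  hit <- which(cnt >= min_probes)
  if (length(hit) == 0) return(IRanges::IRanges())
  IRanges::reduce(IRanges::IRanges(start = position[hit],
                                   width = window))
}

#' Detect enriched windows on a probe track
#'
#' A window is a hit when at least `min_probes` probes within `window` bp
#' exceed `cutoff_fraction` of the hypothetical maximum (per-chromosome
#' mean + 6 SD of the rescaled signal); overlapping hit windows are
#' unioned into candidate intervals.
#'
#' @param track rescaled probe signal data.frame.
#' @param cutoff_fraction fraction of the hypothetical maximum (0.15-0.90).
#' @param window sliding window span in bp (default 500).
#' @param min_probes minimum above-cutoff probes per window (default 4).
#' @return data.frame(chromosome, start, end) of candidate intervals.
#' @export
detect_enriched_windows <- function(track, cutoff_fraction, window = 500,
                                    min_probes = 4) {
  stopifnot(cutoff_fraction > 0, cutoff_fraction <= 1)
  parts <- lapply(split(track, track$chromosome), function(tr) {
    tr <- tr[order(tr$position), , drop = FALSE]
    ir <- .detect_chrom(tr$position, tr$log2_ratio, cutoff_fraction,
                        window, min_probes)
    if (length(ir) == 0) return(NULL)
    data.frame(chromosome = tr$chromosome[1],
               start = IRanges::start(ir) , end = IRanges::end(ir) + 1,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  if (is.null(out))
    out <- data.frame(chromosome = character(0), start = numeric(0),
                      end = numeric(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Estimate per-cutoff false discovery rates by randomization
#'
#' Probe values are permuted within each chromosome (positions fixed) and
#' the detector re-run; FDR(cutoff) = mean candidate count over
#' randomizations / observed candidate count, capped at 1.
#'
#' @param track rescaled probe signal data.frame.
#' @param cutoffs numeric vector of cutoff fractions.
#' @param n_randomizations permutations (default 20).
#' @param seed integer seed; results are deterministic given it.
#' @inheritParams detect_enriched_windows
#' @return data.frame(cutoff, observed, null_mean, fdr); `fdr` is NA where
#'   the observed count is 0.
#' @export
estimate_fdr <- function(track, cutoffs, n_randomizations = 20, seed = 1,
                         window = 500, min_probes = 4) {
  obs <- vapply(cutoffs, function(cf)
    nrow(detect_enriched_windows(track, cf, window, min_probes)),
    numeric(1))
  null_counts <- matrix(0, n_randomizations, length(cutoffs))
  set.seed(seed)
  for (r in seq_len(n_randomizations)) {
    perm <- track
    perm$log2_ratio <- unsplit(lapply(split(track$log2_ratio,
                                            track$chromosome), sample),
                               track$chromosome)
    null_counts[r, ] <- vapply(cutoffs, function(cf)
      nrow(detect_enriched_windows(perm, cf, window, min_probes)),
      numeric(1))
  }
  null_mean <- colMeans(null_counts)
  fdr <- ifelse(obs > 0, pmin(null_mean / obs, 1), NA_real_)
  data.frame(cutoff = cutoffs, observed = obs, null_mean = null_mean,
             fdr = fdr)
}

#' Call binding sites with FDR confidence classes
#'
#' Runs the detector over a descending cutoff grid, estimates the FDR at
#' each cutoff by randomization, and reports candidate intervals from the
#' loosest cutoff whose FDR is within 0.2.  Each site takes the most
#' stringent class supported by any cutoff whose candidates overlap it:
#' `high` (FDR <= 0.05), `mid` (<= 0.1), `low` (<= 0.2).
#'
#' @param track raw probe signal data.frame (rescaled internally).
#' @param cutoff_grid descending cutoffs (default 0.90 .. 0.15).
#' @param seed integer seed for the randomization FDR.
#' @inheritParams detect_enriched_windows
#' @param n_randomizations permutations per cutoff (default 20).
#' @return data.frame(chromosome, start, end, peak_score, fdr_class); the
#'   FDR table is attached as attribute `fdr_table`.
#' @export
call_sites <- function(track,
                       cutoff_grid = c(0.90, 0.80, 0.70, 0.60, 0.50,
                                       0.40, 0.30, 0.20, 0.15),
                       seed = 1, window = 500, min_probes = 4,
                       n_randomizations = 20) {
  stopifnot(!is.unsorted(rev(cutoff_grid)))
  track <- rescale_min_zero(track)
  fdr_tab <- estimate_fdr(track, cutoff_grid, n_randomizations, seed,
                          window, min_probes)
  empty <- data.frame(chromosome = character(0), start = numeric(0),
                      end = numeric(0), peak_score = numeric(0),
                      fdr_class = character(0), stringsAsFactors = FALSE)
  class_of <- function(f) {
    if (is.na(f)) return(NA_character_)
    if (f <= 0.05) "high" else if (f <= 0.1) "mid"
    else if (f <= 0.2) "low" else NA_character_
  }
  cls <- vapply(fdr_tab$fdr, class_of, character(1))
  keep <- which(!is.na(cls))
  if (length(keep) == 0) { attr(empty, "fdr_table") <- fdr_tab; return(empty) }
  ## base intervals: loosest qualifying cutoff (largest candidate set)
  base_i <- keep[length(keep)]
  base <- detect_enriched_windows(track, cutoff_grid[base_i], window,
                                  min_probes)
  if (nrow(base) == 0) { attr(empty, "fdr_table") <- fdr_tab; return(empty) }
  gr_base <- GenomicRanges::GRanges(base$chromosome,
                                    IRanges::IRanges(base$start + 1, base$end))
  site_class <- rep(cls[base_i], nrow(base))
  rank <- c(high = 1, mid = 2, low = 3)
  for (i in keep[-length(keep)]) {
    cand <- detect_enriched_windows(track, cutoff_grid[i], window, min_probes)
    if (nrow(cand) == 0) next
    gr_c <- GenomicRanges::GRanges(cand$chromosome,
                                   IRanges::IRanges(cand$start + 1, cand$end))
    hit <- unique(S4Vectors::queryHits(
      GenomicRanges::findOverlaps(gr_base, gr_c)))
    upgrade <- hit[rank[cls[i]] < rank[site_class[hit]]]
    site_class[upgrade] <- cls[i]
  }
  score <- vapply(seq_len(nrow(base)), function(k) {
    sel <- track$chromosome == base$chromosome[k] &
      track$position >= base$start[k] & track$position < base$end[k]
    if (!any(sel)) return(NA_real_)
    max(track$log2_ratio[sel])
  }, numeric(1))
  out <- data.frame(chromosome = base$chromosome, start = base$start,
                    end = base$end, peak_score = score,
                    fdr_class = site_class, stringsAsFactors = FALSE)
  attr(out, "fdr_table") <- fdr_tab
  out
}

#' Merge sites closer than a gap threshold
#'
#' Transitive closure of the "edge gap <= merge_gap" relation; the merged
#' count is the "unique sites" statistic.
#'
#' @param sites data.frame(chromosome, start, end), sorted.
#' @param merge_gap maximum separating gap in bp (default 10,000).
#' @return merged data.frame(chromosome, start, end, n_members).
#' @export
merge_sites <- function(sites, merge_gap = 10000) {
  if (nrow(sites) == 0) return(cbind(sites, n_members = integer(0)))
  parts <- lapply(split(sites, sites$chromosome), function(s) {
    ir <- IRanges::IRanges(s$start + 1, s$end)
    red <- IRanges::reduce(ir, min.gapwidth = merge_gap + 1,
                           with.revmap = TRUE)
    data.frame(chromosome = s$chromosome[1],
               start = IRanges::start(red) - 1, end = IRanges::end(red),
               n_members = lengths(S4Vectors::mcols(red)$revmap),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out[order(out$chromosome, out$start), , drop = FALSE]
}

#' Merge histone-mark loci, then discard short ones
#'
#' Merge-then-filter: loci closer than `merge_gap` are grouped and merged
#' loci shorter than `min_size` discarded, yielding unique binding loci.
#'
#' @param loci data.frame(chromosome, start, end), sorted.
#' @param merge_gap merge distance in bp (default 10,000).
#' @param min_size minimum merged-locus span in bp (default 1,000).
#' @return merged, filtered data.frame.
#' @export
merge_h4k10ac <- function(loci, merge_gap = 10000, min_size = 1000) {
  m <- merge_sites(loci, merge_gap)
  m[m$end - m$start >= min_size, , drop = FALSE]
}

#' Mean inter-site spacing within a region category
#'
#' @param category_length total category length in bp.
#' @param n_sites merged ("unique") site count in the category.
#' @return spacing in bp.
#' @export
region_spacing <- function(category_length, n_sites) {
  stopifnot(n_sites > 0)
  category_length / n_sites
}

.midpoint_assign <- function(sites, intervals, label_col) {
  mid <- floor((sites$start + sites$end) / 2)
  lab <- rep(NA_character_, nrow(sites))
  for (k in seq_len(nrow(intervals))) {
    sel <- sites$chromosome == intervals$chromosome[k] &
      mid >= intervals$start[k] & mid < intervals$end[k]
    lab[sel] <- intervals[[label_col]][k]
  }
  lab
}

#' Associate binding sites with annotation categories
#'
#' Assigns each site to the region class, and within the core to the SSR
#' or DGC, containing its midpoint; reports per-category counts,
#' fractions, occupancy (fraction of category loci holding >= 1 site) and
#' mean spacing (category length / merged-site count).
#'
#' @param sites site table (chromosome, start, end).
#' @param region_track demarcation table from [demarcate_chromosome()]
#'   (rows for all chromosomes).
#' @param ssrs optional SSR table; @param dgcs optional DGC table.
#' @param merge_gap merge distance used for the spacing denominator.
#' @return list with `by_class`, and when SSR/DGC tables are given,
#'   `by_feature` (divergent/convergent/intra-DGC counts and occupancy).
#' @export
associate_sites_with_regions <- function(sites, region_track, ssrs = NULL,
                                         dgcs = NULL, merge_gap = 10000) {
  cls <- .midpoint_assign(sites, region_track, "class")
  classes <- c("core", "subtelomere", "vsg_array")
  by_class <- do.call(rbind, lapply(classes, function(cl) {
    n <- sum(cls == cl, na.rm = TRUE)
    len <- sum(region_track$end[region_track$class == cl] -
               region_track$start[region_track$class == cl])
    merged <- merge_sites(sites[which(cls == cl), , drop = FALSE], merge_gap)
    data.frame(class = cl, n_sites = n,
               fraction = n / max(nrow(sites), 1), length_bp = len,
               n_merged = nrow(merged),
               spacing_bp = if (nrow(merged) > 0) len / nrow(merged) else NA,
               stringsAsFactors = FALSE)
  }))
  out <- list(by_class = by_class)
  if (!is.null(ssrs) && !is.null(dgcs)) {
    feat <- rbind(
      data.frame(chromosome = ssrs$chromosome, start = ssrs$start,
                 end = ssrs$end,
                 feature = paste0(ssrs$ssr_type, rep("_ssr", nrow(ssrs))),
                 stringsAsFactors = FALSE),
      data.frame(chromosome = dgcs$chromosome, start = dgcs$start,
                 end = dgcs$end, feature = "intra_dgc",
                 stringsAsFactors = FALSE))
    core_sites <- sites[which(cls == "core"), , drop = FALSE]
    fl <- .midpoint_assign(core_sites, feat, "feature")
    types <- c("divergent_ssr", "convergent_ssr", "intra_dgc")
    by_feature <- do.call(rbind, lapply(types, function(tp) {
      iv <- feat[feat$feature == tp, , drop = FALSE]
      n <- sum(fl == tp, na.rm = TRUE)
      occupied <- 0L
      if (nrow(iv) > 0 && nrow(core_sites) > 0) {
        mid <- floor((core_sites$start + core_sites$end) / 2)
        occupied <- sum(vapply(seq_len(nrow(iv)), function(k)
          any(core_sites$chromosome == iv$chromosome[k] &
              mid >= iv$start[k] & mid < iv$end[k]), logical(1)))
      }
      data.frame(feature = tp, n_sites = n,
                 fraction_core = n / max(nrow(core_sites), 1),
                 n_loci = nrow(iv), n_occupied = occupied,
                 occupancy = if (nrow(iv) > 0) occupied / nrow(iv) else NA,
                 stringsAsFactors = FALSE)
    }))
    out$by_feature <- by_feature
  }
  out
}

#' Proximity and overlap between two interval sets
#'
#' Distance is 0 for overlapping intervals, otherwise the gap between
#' nearest edges.  Optionally reports, for each A-member inside a DGC,
#' whether it lies upstream (in the transcription direction) of its
#' nearest B-member.
#'
#' @param setA,setB data.frames (chromosome, start, end), sorted.
#' @param within proximity threshold in bp (default 15,000).
#' @param dgcs optional DGC table for the upstream/downstream call.
#' @return list(n_within, n_overlap, pairs) where `pairs` has the nearest-B
#'   distance per A member (and `upstream` when `dgcs` is given).
#' @export
proximity_and_overlap <- function(setA, setB, within = 15000, dgcs = NULL) {
  grA <- GenomicRanges::GRanges(setA$chromosome,
                                IRanges::IRanges(setA$start + 1, setA$end))
  grB <- GenomicRanges::GRanges(setB$chromosome,
                                IRanges::IRanges(setB$start + 1, setB$end))
  nearest <- GenomicRanges::distanceToNearest(grA, grB)
  d <- rep(NA_real_, nrow(setA))
  bidx <- rep(NA_integer_, nrow(setA))
  d[S4Vectors::queryHits(nearest)] <- S4Vectors::mcols(nearest)$distance
  bidx[S4Vectors::queryHits(nearest)] <- S4Vectors::subjectHits(nearest)
  pairs <- data.frame(a = seq_len(nrow(setA)), b = bidx, distance = d)
  if (!is.null(dgcs)) {
    midA <- (setA$start + setA$end) / 2
    midB <- (setB$start + setB$end) / 2
    strand <- .midpoint_assign(setA, dgcs, "strand")
    up <- rep(NA, nrow(setA))
    ok <- !is.na(bidx) & !is.na(strand)
    up[ok] <- ifelse(strand[ok] == "+",
                     midA[ok] < midB[bidx[ok]],
                     midA[ok] > midB[bidx[ok]])
    pairs$upstream <- up
  }
  list(n_within = sum(pairs$distance <= within, na.rm = TRUE),
       n_overlap = sum(pairs$distance == 0, na.rm = TRUE),
       pairs = pairs)
}
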