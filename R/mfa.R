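## Marker frequency analysis: S/G2 ratio tracks, origin (OBR) peak
## calling, fork-rate asymmetry, replicated fraction, origin density.

#' Bin a per-position depth track
#'
#' @param depth numeric vector of per-position read depth for one
#'   chromosome (position i covers base i-1 in 0-based coordinates).
#' @param bin_size bin width in bp (default 2,500); the final partial bin
#'   is averaged over its true length.
#' @param chromosome chromosome name attached to the output.
#' @return data.frame(chromosome, start, end, value) with the mean depth
#'   per bin.
#' @export
bin_depth <- function(depth, bin_size = 2500, chromosome = "chr") {
  stopifnot(bin_size >= 1)
  n <- length(depth)
  if (n == 0)
    return(data.frame(chromosome = character(0), start = numeric(0),
                      end = numeric(0), value = numeric(0)))
  idx <- (seq_len(n) - 1) %/% bin_size
  mean_by <- tapply(depth, idx, mean)
  starts <- as.numeric(names(mean_by)) * bin_size
  data.frame(chromosome = chromosome, start = starts,
             end = pmin(starts + bin_size, n),
             value = as.numeric(mean_by), stringsAsFactors = FALSE,
             row.names = NULL)
}

## Baseline: the unreplicated level (mode) of a raw S/G2 ratio vector,
## robust to a large replicated fraction in mid-S.  Seed the estimate from
## the lowest quartile of scorable bins, then take the median of the full
## symmetric cluster around it (one mode-seeking refinement; the seed
## alone sits a fraction of a noise SD below the mode because it is drawn
## from the lower tail).
.ratio_baseline <- function(r) {
  r <- r[is.finite(r)]
  low <- r[r <= stats::quantile(r, 0.25)]
  b0 <- stats::median(low)
  s0 <- stats::mad(low, center = b0)
  if (!is.finite(s0) || s0 == 0) return(b0)
  stats::median(r[abs(r - b0) <= 3 * s0])
}

#' S/G2 ratio track, normalized to a per-chromosome baseline of 1
#'
#' Raw ratio = S bin / G2 bin; bins with zero G2 depth are flagged and
#' excluded (NA).  The chromosome baseline (unreplicated level) is the
#' median of the lowest quartile of raw ratios and is divided out, so
#' unreplicated territory sits at 1.  Scale-invariant: multiplying either
#' depth track by a positive constant leaves the output unchanged.
#'
#' @param s_binned,g2_binned binned tracks from [bin_depth()] for one
#'   chromosome, on the same bin grid.
#' @param quality optional logical vector flagging low-mapping-quality
#'   bins (carried through as column `low_quality`).
#' @return data.frame(chromosome, start, end, ratio, low_quality).
#' @export
ratio_and_normalize <- function(s_binned, g2_binned, quality = NULL) {
  stopifnot(nrow(s_binned) == nrow(g2_binned),
            all(s_binned$start == g2_binned$start))
  if (all(g2_binned$value == 0)) stop("all-zero G2 chromosome")
  raw <- ifelse(g2_binned$value > 0, s_binned$value / g2_binned$value,
                NA_real_)
  base <- .ratio_baseline(raw)
  if (!is.finite(base) || base <= 0) stop("degenerate ratio baseline")
  out <- data.frame(chromosome = s_binned$chromosome,
                    start = s_binned$start, end = s_binned$end,
                    ratio = raw / base, stringsAsFactors = FALSE)
  out$low_quality <- if (is.null(quality)) FALSE else quality
  out
}

## Robust SD of sub-baseline bins: MAD of bins at or below 1, centred at 1.
.baseline_sd <- function(ratio) {
  sub <- ratio[is.finite(ratio) & ratio <= 1]
  s <- stats::mad(sub, center = 1)
  if (!is.finite(s) || s == 0) s <- stats::sd(ratio[is.finite(ratio)])
  if (!is.finite(s) || s == 0) s <- .Machine$double.eps
  s
}

#' Call origin (OBR) peaks on a normalized S/G2 ratio track
#'
#' The track is lightly smoothed (running median, 5 bins), and local
#' maxima with amplitude >= `min_amplitude` above baseline and width at
#' half-amplitude >= `min_width` bins become peaks.  Peak boundaries
#' extend from the apex to the first bin back within one robust SD of
#' baseline; flank slopes are least-squares fits of smoothed ratio against
#' position on each side.  A peak is `symmetric` when
#' |left slope| / |right slope| lies in [0.8, 1.25].  Peaks are named
#' "OBR:<chromosome>:<position in Mbp, 2 decimals>".  Low-quality bins are
#' excluded from calling.
#'
#' @param ratio normalized track from [ratio_and_normalize()].
#' @param min_amplitude minimum apex height above 1 (default 0.15).
#' @param min_width minimum width at half amplitude, in bins (default 10).
#' @param smooth_window running-median window in bins (default 5).
#' @return data.frame with center, amplitude, flank slopes (ratio units
#'   per bp), symmetry, and name, one row per peak.
#' @export
call_obr_peaks <- function(ratio, min_amplitude = 0.15, min_width = 10,
                           smooth_window = 5) {
  r <- ratio$ratio
  r[ratio$low_quality] <- NA
  ok <- is.finite(r)
  if (!any(ok)) return(.empty_peaks())
  sm <- r
  sm[ok] <- smooth_running_median(r[ok], smooth_window)
  rsd <- .baseline_sd(sm[ok])
  thr <- 1 + min_amplitude
  ret <- 1 + rsd                        # return-to-baseline level
  centers <- (ratio$start + ratio$end) / 2
  bin_bp <- stats::median(ratio$end - ratio$start)

  above <- !is.na(sm) & sm >= thr
  runs <- rle(above)
  run_end <- cumsum(runs$lengths)
  run_start <- c(1, head(run_end, -1) + 1)
  peaks <- list()
  for (k in which(runs$values)) {
    seg <- run_start[k]:run_end[k]
    apex <- seg[which.max(sm[seg])]
    amp <- sm[apex] - 1
    ## width at half amplitude around the apex
    half <- 1 + amp / 2
    lo <- apex; while (lo > 1 && !is.na(sm[lo - 1]) && sm[lo - 1] >= half)
      lo <- lo - 1
    hi <- apex; while (hi < length(sm) && !is.na(sm[hi + 1]) &&
                       sm[hi + 1] >= half) hi <- hi + 1
    if (hi - lo + 1 < min_width) next
    ## boundaries: walk out to return-to-baseline
    b_lo <- apex; while (b_lo > 1 && !is.na(sm[b_lo - 1]) &&
                         sm[b_lo - 1] > ret) b_lo <- b_lo - 1
    b_hi <- apex; while (b_hi < length(sm) && !is.na(sm[b_hi + 1]) &&
                         sm[b_hi + 1] > ret) b_hi <- b_hi + 1
    fit_line <- function(idx) {
      ## restrict to the linear mid-section of the flank: below the
      ## median-flattened top, above the curved tail near baseline
      idx <- idx[!is.na(sm[idx]) & sm[idx] >= 1 + 0.25 * amp &
                 sm[idx] <= 1 + 0.85 * amp]
      if (length(idx) < 3) return(c(NA_real_, NA_real_))
      stats::coef(stats::lm(sm[idx] ~ centers[idx]))
    }
    left_fit <- fit_line(b_lo:apex)
    right_fit <- fit_line(apex:b_hi)
    left_slope <- unname(left_fit[2]); right_slope <- unname(right_fit[2])
    ## apex refinement: the intersection of the flank lines is the kink
    ## of the underlying tent profile (exact for asymmetric flanks too)
    center <- centers[apex]; height <- sm[apex]
    if (is.finite(left_slope) && is.finite(right_slope) &&
        left_slope > 0 && right_slope < 0) {
      x_star <- (right_fit[1] - left_fit[1]) / (left_slope - right_slope)
      if (abs(x_star - centers[apex]) <= 4 * bin_bp) {
        center <- unname(x_star)
        height <- unname(left_fit[1] + left_slope * x_star)
      }
    }
    amp <- height - 1
    sym <- NA
    if (is.finite(left_slope) && is.finite(right_slope) &&
        right_slope != 0) {
      q <- abs(left_slope) / abs(right_slope)
      sym <- q >= 0.8 && q <= 1.25
    }
    peaks[[length(peaks) + 1]] <- data.frame(
      chromosome = ratio$chromosome[1], center = center,
      amplitude = amp, left_slope = left_slope,
      right_slope = right_slope,
      symmetry = ifelse(is.na(sym), NA_character_,
                        ifelse(sym, "symmetric", "asymmetric")),
      start = ratio$start[b_lo], end = ratio$end[b_hi],
      name = sprintf("OBR:%s:%.2f", ratio$chromosome[1], center / 1e6),
      stringsAsFactors = FALSE)
  }
  if (length(peaks) == 0) return(.empty_peaks())
  out <- do.call(rbind, peaks)
  rownames(out) <- NULL
  out
}

.empty_peaks <- function() {
  data.frame(chromosome = character(0), center = numeric(0),
             amplitude = numeric(0), left_slope = numeric(0),
             right_slope = numeric(0), symmetry = character(0),
             start = numeric(0), end = numeric(0), name = character(0),
             stringsAsFactors = FALSE)
}

#' Fork-rate asymmetry of an origin peak
#'
#' Under a constant per-cell fork speed and uniform sampling through S
#' phase, the magnitude of an MFA flank slope is inversely proportional to
#' the fork speed on that flank, so the fold difference in fork rate is
#' |steeper slope| / |shallower slope|, with the shallow (fast) flank
#' reported.
#'
#' @param peak one row of the [call_obr_peaks()] output.
#' @return list(fold, shallow_flank) with `shallow_flank` in
#'   `left`/`right`; fold is NA (flagged) for a zero slope.
#' @export
fork_rate_asymmetry <- function(peak) {
  l <- abs(peak$left_slope); r <- abs(peak$right_slope)
  if (!is.finite(l) || !is.finite(r) || l == 0 || r == 0)
    return(list(fold = NA_real_, shallow_flank = NA_character_))
  list(fold = max(l, r) / min(l, r),
       shallow_flank = if (l < r) "left" else "right")
}

#' Replicated fraction of the genome, overall and by region class
#'
#' A bin counts as replicated when its normalized ratio is at least
#' 1 + threshold; the default threshold is 3 robust SDs of the
#' sub-baseline bins.  Also reports the region-class composition of the
#' replicated territory.
#'
#' @param ratio normalized ratio track (one or more chromosomes,
#'   rbind-ed).
#' @param region_track optional demarcation table for the per-class
#'   breakdown.
#' @param threshold elevation above baseline; NULL for the robust default.
#' @return list(threshold, fraction, by_class, composition).
#' @export
replicated_fraction <- function(ratio, region_track = NULL,
                                threshold = NULL) {
  ok <- is.finite(ratio$ratio) & !ratio$low_quality
  if (is.null(threshold)) threshold <- 3 * .baseline_sd(ratio$ratio[ok])
  repl <- ok & ratio$ratio >= 1 + threshold
  out <- list(threshold = threshold, fraction = sum(repl) / sum(ok))
  if (!is.null(region_track)) {
    mids <- data.frame(chromosome = ratio$chromosome,
                       start = ratio$start, end = ratio$end)
    cls <- .midpoint_assign(mids, region_track, "class")
    by_class <- tapply(repl[ok], cls[ok], mean)
    comp <- table(cls[repl]) / max(sum(repl), 1)
    out$by_class <- by_class
    out$composition <- comp
  }
  out
}

#' Origin density and genome-wide extrapolation
#'
#' Fits origin count against chromosome length through the origin, scales
#' the observed peak count by the reciprocal of the analyzed S-phase
#' fraction (peaks are enriched for origins firing early in S), and
#' reports the implied genome-wide origin density.
#'
#' @param n_peaks integer vector of peak counts per chromosome.
#' @param lengths chromosome lengths in bp (same order).
#' @param analyzed_fraction fraction of S phase covered by the sorted S
#'   sample (default 0.5).
#' @param round_to predicted count is rounded to this multiple
#'   (default 10).
#' @return list(predicted_origins, density_bp, slope_per_bp, correlation);
#'   with a single chromosome only the density is returned.
#' @export
origin_density_and_extrapolation <- function(n_peaks, lengths,
                                             analyzed_fraction = 0.5,
                                             round_to = 10) {
  total <- sum(n_peaks)
  predicted <- round(total / analyzed_fraction / round_to) * round_to
  density <- sum(lengths) / predicted
  if (length(n_peaks) < 2)
    return(list(predicted_origins = predicted, density_bp = density,
                slope_per_bp = NA_real_, correlation = NA_real_))
  fit <- stats::lm(n_peaks ~ 0 + lengths)
  list(predicted_origins = predicted, density_bp = density,
       slope_per_bp = unname(stats::coef(fit)[1]),
       correlation = stats::cor(lengths, n_peaks))
}

#' Colocalize MFA peaks with feature intervals
#'
#' A peak matches when its apex bin (within `tolerance` bins) intersects a
#' feature.  When `ranked_features` is supplied (e.g., centromere
#' positions), also reports whether the amplitude-ranked top peaks match
#' them.
#'
#' @param peaks [call_obr_peaks()] output.
#' @param features data.frame(chromosome, start, end).
#' @param tolerance bins of slack around the apex (default 2).
#' @param bin_size bin width in bp (default 2,500).
#' @param ranked_features optional feature set tested against the
#'   highest-amplitude peaks (one per chromosome in `ranked_features`).
#' @return list(n_matched, n_total, matched logical vector,
#'   top_ranked_matched).
#' @export
colocalize_peaks_with_features <- function(peaks, features, tolerance = 2,
                                           bin_size = 2500,
                                           ranked_features = NULL) {
  slack <- tolerance * bin_size
  match_one <- function(chrom, center, feat) {
    any(feat$chromosome == chrom &
        feat$start < center + bin_size / 2 + slack &
        feat$end > center - bin_size / 2 - slack)
  }
  matched <- vapply(seq_len(nrow(peaks)), function(k)
    match_one(peaks$chromosome[k], peaks$center[k], features), logical(1))
  out <- list(n_matched = sum(matched), n_total = nrow(peaks),
              matched = matched)
  if (!is.null(ranked_features)) {
    top <- do.call(rbind, lapply(split(peaks, peaks$chromosome),
      function(p) p[which.max(p$amplitude), , drop = FALSE]))
    keep <- top$chromosome %in% ranked_features$chromosome
    out$top_ranked_matched <- vapply(which(keep), function(k)
      match_one(top$chromosome[k], top$center[k], ranked_features),
      logical(1))
  }
  out
}
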