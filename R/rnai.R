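## Post-knockdown transcriptome analysis: quantile-normalized depth,
## 250 bp log2 ratio and presence tracks, running-median smoothing,
## per-gene fold changes, boundary enrichment.

#' Quantile-normalize two per-position depth tracks
#'
#' Each rank is assigned the mean of the two tracks' rank-ordered values
#' (ties share their tied block's mean), so the output tracks have
#' identical sorted value distributions.
#'
#' @param a,b equal-length numeric depth vectors.
#' @return list(a, b) of normalized vectors.
#' @export
quantile_normalize <- function(a, b) {
  stopifnot(length(a) == length(b))
  m <- limma::normalizeQuantiles(cbind(a, b), ties = TRUE)
  list(a = m[, 1], b = m[, 2])
}

#' Running median with shrinking edge windows
#'
#' Each value is replaced by the median of the `window`-wide window
#' centred on it; near the edges the window shrinks to the available
#' positions.
#'
#' @param x numeric vector.
#' @param window odd window width in bins (default 7).
#' @return smoothed numeric vector.
#' @export
smooth_running_median <- function(x, window = 7) {
  stopifnot(window %% 2 == 1)
  n <- length(x)
  if (n == 0) return(x)
  h <- (window - 1) / 2
  clipped <- function(i) stats::median(x[max(1, i - h):min(n, i + h)])
  if (n <= window) return(vapply(seq_len(n), clipped, numeric(1)))
  out <- as.numeric(stats::runmed(x, window, endrule = "keep"))
  for (i in c(seq_len(h), seq(n - h + 1, n))) out[i] <- clipped(i)
  out
}

#' Binned log2 induced/uninduced expression ratio track
#'
#' Per-position log2 ratios are computed where both samples are nonzero
#' (zero positions belong to the presence track) and summarized as the
#' per-bin median.
#'
#' @param induced,uninduced normalized per-position depth vectors for one
#'   chromosome.
#' @param bin bin width in bp (default 250).
#' @param chromosome chromosome name.
#' @return data.frame(chromosome, start, end, log2_ratio); bins with no
#'   scorable position are NA.
#' @export
ratio_track_250 <- function(induced, uninduced, bin = 250,
                            chromosome = "chr") {
  stopifnot(length(induced) == length(uninduced))
  n <- length(induced)
  lr <- ifelse(induced > 0 & uninduced > 0, log2(induced / uninduced),
               NA_real_)
  idx <- (seq_len(n) - 1) %/% bin
  med <- tapply(lr, idx, function(v)
    if (all(is.na(v))) NA_real_ else stats::median(v, na.rm = TRUE))
  starts <- as.numeric(names(med)) * bin
  data.frame(chromosome = chromosome, start = starts,
             end = pmin(starts + bin, n), log2_ratio = as.numeric(med),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Presence track: bins expressed in only one sample
#'
#' Zero positions are substituted with `zero_sub` before forming log2
#' ratios; a bin whose median log2 ratio exceeds
#' log2(read_floor / zero_sub) / 2 is flagged `induced_only` (signal over
#' pseudo-zero), and symmetrically for `uninduced_only`.  Positions zero
#' in both samples give ratio 0 and are never flagged.
#'
#' @inheritParams ratio_track_250
#' @param zero_sub pseudo-count replacing zero positions (default 1e-5).
#' @param read_floor smallest depth treated as real signal (default 1).
#' @return data.frame(chromosome, start, end, direction) restricted to
#'   flagged bins, direction in `induced_only`/`uninduced_only`.
#' @export
presence_track <- function(induced, uninduced, bin = 250,
                           zero_sub = 0.00001, read_floor = 1,
                           chromosome = "chr") {
  stopifnot(length(induced) == length(uninduced))
  i2 <- ifelse(induced == 0, zero_sub, induced)
  u2 <- ifelse(uninduced == 0, zero_sub, uninduced)
  lr <- log2(i2 / u2)
  idx <- (seq_len(length(lr)) - 1) %/% bin
  med <- tapply(lr, idx, stats::median)
  starts <- as.numeric(names(med)) * bin
  bound <- log2(read_floor / zero_sub) / 2
  dir <- ifelse(med > bound, "induced_only",
                ifelse(med < -bound, "uninduced_only", NA_character_))
  keep <- which(!is.na(dir))
  data.frame(chromosome = rep(chromosome, length(keep)),
             start = starts[keep],
             end = pmin(starts[keep] + bin, length(lr)),
             direction = dir[keep], stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Scale two depth tracks to a common library size
#'
#' Per-gene quantification uses depth scaled by total mapped signal (the
#' counts-per-million convention), which preserves within-gene fold
#' changes; quantile normalization is reserved for the position-level
#' ratio and presence tracks, where comparable distributions matter.
#'
#' @param a,b per-position depth vectors.
#' @return list(a, b) scaled so each track's mean equals the grand mean.
#' @export
normalize_library_size <- function(a, b) {
  grand <- mean(c(mean(a), mean(b)))
  list(a = a * grand / mean(a), b = b * grand / mean(b))
}

#' Per-gene fold changes after knockdown
#'
#' Gene abundance is the mean normalized depth over the gene body per
#' condition (normalize by library size, see
#' [normalize_library_size()]); fold = induced / uninduced with a
#' `zero_sub` guard on the denominator; genes with fold > `threshold` are
#' flagged significant.
#'
#' @param induced,uninduced normalized per-position depth vectors for one
#'   chromosome.
#' @param genes gene record table for that chromosome (0-based half-open
#'   coordinates).
#' @param threshold fold-change call threshold (default 1.4).
#' @param zero_sub denominator guard (default 1e-5).
#' @return data.frame(gene_id, mean_induced, mean_uninduced, fold,
#'   significant).
#' @export
gene_fold_changes <- function(induced, uninduced, genes, threshold = 1.4,
                              zero_sub = 0.00001) {
  if (any(genes$end <= genes$start)) stop("zero-length gene")
  out <- do.call(rbind, lapply(seq_len(nrow(genes)), function(k) {
    span <- (genes$start[k] + 1):genes$end[k]
    mi <- mean(induced[span]); mu <- mean(uninduced[span])
    fold <- mi / max(mu, zero_sub)
    data.frame(gene_id = genes$gene_id[k], mean_induced = mi,
               mean_uninduced = mu, fold = fold,
               significant = fold > threshold, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Boundary enrichment of a signal track with a permutation p-value
#'
#' Statistic: mean signal in bins lying within `distance` bp of any
#' transcription-unit boundary minus the mean signal elsewhere.  The null
#' is built by cyclic shifts of the bin values within the chromosome.
#' When boundary types are provided the statistic is also broken down by
#' type.
#'
#' @param track data.frame(start, end, value) of binned signal for one
#'   chromosome (use the log2 ratio or presence indicator).
#' @param boundaries data.frame(position, type) of DGC boundaries; type
#'   e.g. `divergent_ssr`, `convergent_ssr`, `intra_dgc`.
#' @param distance window around each boundary in bp (default 10,000).
#' @param n_perm cyclic-shift permutations (default 1,000).
#' @param seed integer seed.
#' @return list(statistic, p_value, by_type, null_mean, null_sd).
#' @export
boundary_enrichment <- function(track, boundaries, distance = 10000,
                                n_perm = 1000, seed = 1) {
  if (nrow(boundaries) == 0) stop("no boundaries")
  mid <- (track$start + track$end) / 2
  v <- track$value
  near <- rep(FALSE, length(mid))
  for (p in boundaries$position)
    near <- near | abs(mid - p) <= distance
  stat_of <- function(x) {
    ok <- is.finite(x)
    mean(x[near & ok]) - mean(x[!near & ok])
  }
  stat <- stat_of(v)
  set.seed(seed)
  n <- length(v)
  ## shifts smaller than the boundary window leave the near-boundary mask
  ## largely intact and are not exchangeable null draws; keep shifts at
  ## least two window widths away from 0 (mod n)
  bin_bp <- stats::median(track$end - track$start)
  m <- min(floor(n / 4), ceiling(2 * distance / bin_bp))
  null <- vapply(seq_len(n_perm), function(r) {
    k <- sample(seq(m, n - m), 1)
    stat_of(v[((seq_len(n) - 1 + k) %% n) + 1])
  }, numeric(1))
  p <- (1 + sum(null >= stat)) / (n_perm + 1)
  by_type <- NULL
  if (!is.null(boundaries$type)) {
    okv <- is.finite(v)
    by_type <- vapply(split(boundaries$position, boundaries$type),
                      function(pos) {
                        nb <- rep(FALSE, length(mid))
                        for (q in pos) nb <- nb | abs(mid - q) <= distance
                        mean(v[nb & okv]) - mean(v[!near & okv])
                      }, numeric(1))
  }
  list(statistic = stat, p_value = p, by_type = by_type,
       null_mean = mean(null), null_sd = stats::sd(null))
}
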