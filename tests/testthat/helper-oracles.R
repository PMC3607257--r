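# Independent brute-force oracles and small fixture builders.

# Naive running median: median over the clipped centred window, per
# position, by direct evaluation.
naive_running_median <- function(x, k) {
  h <- (k - 1) / 2
  n <- length(x)
  vapply(seq_len(n), function(i)
    stats::median(x[max(1, i - h):min(n, i + h)]), numeric(1))
}

# Naive interval merging: repeated pairwise joins until closure of the
# "gap <= merge_gap" relation.
naive_merge <- function(start, end, merge_gap) {
  repeat {
    n <- length(start)
    joined <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i >= j) next
        gap <- max(start[i], start[j]) - min(end[i], end[j])
        if (gap <= merge_gap) {
          start[i] <- min(start[i], start[j]); end[i] <- max(end[i], end[j])
          start <- start[-j]; end <- end[-j]
          joined <- TRUE
          break
        }
      }
      if (joined) break
    }
    if (!joined) break
  }
  o <- order(start)
  data.frame(start = start[o], end = end[o])
}

# Per-cell Monte Carlo replication expectation: each cell draws one
# sampling time (uniform over the S window) and one firing time per
# origin (uniform over the firing window, thinned by efficiency); a
# position is replicated when some origin's fork reaches it in time.
mc_replication_probability <- function(positions, origins, config,
                                       n_cells = 20000, seed = 1) {
  set.seed(seed)
  p <- numeric(length(positions))
  for (cell in seq_len(n_cells)) {
    u <- stats::runif(1, config$s_window[1], config$s_window[2])
    tf <- stats::runif(nrow(origins), 0, config$firing_window)
    fires <- stats::runif(nrow(origins)) < origins$efficiency
    repl <- rep(FALSE, length(positions))
    for (k in seq_len(nrow(origins))) {
      if (!fires[k]) next
      d <- positions - origins$position[k]
      tt <- tf[k] + pmax(d, 0) / origins$speed_right[k] +
        pmax(-d, 0) / origins$speed_left[k]
      repl <- repl | tt <= u
    }
    p <- p + repl
  }
  p / n_cells
}

# Toy chromosome with the canonical arm structure:
# [VSG array | subtelomere run | ordinary core | subtelomere run | array]
toy_arm_genes <- function() {
  gene_records(
    gene_id = paste0("t", 1:11),
    chromosome = "t",
    start = c(0, 2000, 5000, 7000, 10000, 12000, 14000, 17000, 19000,
              22000, 24000),
    end = c(1000, 3000, 6000, 8000, 11000, 13000, 15000, 18000, 20000,
            23000, 25000),
    strand = "+",
    category = c("VSG", "VSG", "ESAG", "RHS", "ordinary", "ordinary",
                 "ordinary", "RHS", "ESAG", "VSG", "VSG"))
}

# A "genome" stub carrying only what the track simulators need, for
# planting custom sites/origins.
stub_genome <- function(lengths, sites = NULL, origins = NULL) {
  list(chromosome_lengths = lengths,
       truth = list(sites = sites, origins = origins))
}
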