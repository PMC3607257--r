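## Synthetic genomes with known ground truth.
##
## The generator emulates the organization of the T. brucei megabase
## chromosomes at desk scale: each chromosome is laid out as
## [VSG array | subtelomere | core | subtelomere | VSG array], the core is
## tiled with alternating-strand directional gene clusters separated by
## strand switch regions, and the arrays with VSG cassettes
## (70 bp repeats, 5' flank, ORF, 3' flank).  ChIP enrichment concentrates
## at transcription-unit boundaries, S/G2 depth ratios are shaped by
## early-firing origins with direction-dependent fork speeds, and
## knockdown transcriptomes gain signal at cluster boundaries and at
## silent metacyclic-VSG-like loci.  Every stage is deterministic given
## (seed, config).

#' Simulation configuration
#'
#' Defaults mirror the study conditions where these are stated (61 bp
#' probe spacing, ~4-fold ChIP enrichment, 2,500 bp MFA bins, S sample
#' enriched for the first half of S phase, 2-fold boundary elevation over
#' 5 kb, 8-fold metacyclic-VSG derepression, ~30x depth) and otherwise
#' hold field-realistic values at a scale small enough for routine reruns.
#'
#' @param seed integer master seed; each stage derives its own stream.
#' @param chromosomes named numeric vector of chromosome lengths (bp).
#' @param ... override any default listed below.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       chromosomes = c("1" = 2e6, "2" = 1.5e6, "3" = 1e6),
                       ...) {
  cfg <- list(
    seed = seed,
    chromosomes = chromosomes,
    ## genome layout
    array_length = 150000, subtel_length = 50000,
    gene_length = 1400, intergenic = 1300,
    genes_per_dgc = 50, ssr_gap = 5000,
    hypothetical_rate = 0.10,
    cassette_length = 6000,
    cassette_fractions = c(repeat_70bp = 0.05, flank_5p = 0.40,
                           vsg_orf = 0.50, flank_3p = 0.05),
    pseudogene_rate = 0.3,
    at_content = c(core = 0.55, subtelomere = 0.60, vsg_array = 0.65),
    ## ChIP
    probe_spacing = 61, probe_noise_sd = 0.30,
    chip_fold = 4, site_halfwidth = 500, array_site_rate = 0.5,
    intra_dgc_site_rate = 0.25,
    ## replication
    origin_spacing = 4.5e5, fork_speed = 1.4e5, speed_multiplier = 2,
    origin_efficiency = 1, firing_window = 0.2, s_window = c(0, 0.5),
    depth_mean = 30, depth_dispersion = 20, u_grid = 41, p_step = 50,
    ## RNAi
    expr_mean = 20, boundary_fold = 2, boundary_extent = 5000,
    readthrough_level = 0.1,
    mvsg_fold = 8, mvsg_base_depth = 5, rnai_dispersion = 20,
    ## qPCR
    qpcr_base_ct = 22, qpcr_noise_sd = 0.1, qpcr_replicates = 4)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config keys: ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  if (cfg$array_length * 2 + cfg$subtel_length * 2 >= min(cfg$chromosomes))
    stop("arrays larger than chromosome")
  structure(cfg, class = "sim_config")
}

## class track from designed per-gene classes via the midpoint joining
## rule (gaps inside a class inherit it; boundaries at inter-gene
## midpoints; chromosome ends extend the outermost class).
.truth_track <- function(chrom, cls, gstart, gend, L) {
  runs <- rle(cls)
  nr <- length(runs$lengths)
  e <- cumsum(runs$lengths); s <- c(1, head(e, -1) + 1)
  data.frame(chromosome = chrom,
             start = c(0, floor((gend[e[-nr]] + gstart[s[-1]]) / 2)),
             end = c(floor((gend[e[-nr]] + gstart[s[-1]]) / 2), L),
             class = runs$values, stringsAsFactors = FALSE)
}

#' Generate a synthetic genome, annotation, and ground truth
#'
#' @param config a [sim_config()].
#' @param emit_sequence also build chromosome sequences with
#'   class-specific AT content (slower; default FALSE).
#' @return list with `genes` (gene record table), `repeats` (70 bp repeat
#'   feature table), `chromosome_lengths`, optional `sequence`
#'   ([Biostrings::DNAStringSet]), and `truth`: region class track, DGCs,
#'   SSRs, binding sites, origins (with per-flank fork speeds),
#'   MVSG-like loci, and the expected replicated fraction.
#' @export
generate_genome <- function(config, emit_sequence = FALSE) {
  set.seed(config$seed)
  genes <- list(); repeats <- list(); tracks <- list()
  sites <- list(); mvsg <- list()
  gid <- 0
  for (chrom in names(config$chromosomes)) {
    L <- config$chromosomes[[chrom]]
    aL <- config$array_length; sL <- config$subtel_length
    core0 <- aL + sL; core1 <- L - aL - sL
    g <- list()

    add_gene <- function(start, end, strand, category, id = NULL,
                         design = NULL) {
      gid <<- gid + 1
      g[[length(g) + 1]] <<- data.frame(
        gene_id = if (is.null(id)) sprintf("g%05d", gid) else id,
        chromosome = chrom, start = start, end = end, strand = strand,
        category = category,
        design = if (is.null(design)) gene_class(category) else design,
        stringsAsFactors = FALSE)
    }

    ## ---- arrays: tiled cassettes ---------------------------------------
    lay_array <- function(a0, a1) {
      fr <- config$cassette_fractions
      cl <- config$cassette_length
      pos <- a0
      while (pos + cl <= a1) {
        r1 <- pos + round(fr[["repeat_70bp"]] * cl)
        o0 <- r1 + round(fr[["flank_5p"]] * cl)
        o1 <- o0 + round(fr[["vsg_orf"]] * cl)
        repeats[[length(repeats) + 1]] <<- data.frame(
          chromosome = chrom, start = pos, end = r1,
          type = "repeat_70bp", stringsAsFactors = FALSE)
        status <- if (stats::runif(1) < config$pseudogene_rate)
          "pseudogene" else "functional"
        add_gene(o0, o1, "+", "VSG", design = "vsg_array")
        ## occasional ESAG3 decoy between cassettes (also array content)
        if (stats::runif(1) < 0.1 && pos + cl + 300 <= a1)
          add_gene(o1 + 50, min(o1 + 250, a1), "+", "ESAG3",
                   design = "vsg_array")
        if (stats::runif(1) < config$array_site_rate)
          sites[[length(sites) + 1]] <<- data.frame(
            chromosome = chrom, start = r1,
            end = r1 + 2 * config$site_halfwidth, kind = "array_flank5",
            stringsAsFactors = FALSE)
        pos <- pos + cl
      }
    }
    lay_array(0, aL)
    lay_array(L - aL, L)

    ## ---- subtelomeres ---------------------------------------------------
    lay_subtel <- function(s0, s1, left) {
      cats <- c("ESAG", "RHS", "VSG_related")
      pos <- s0 + 500
      first <- TRUE
      while (pos + config$gene_length <= s1 - 500) {
        id <- NULL
        if (first && left) {  # one silent MVSG-like locus per chromosome
          id <- paste0("MVSG_", chrom)
          add_gene(pos, pos + config$gene_length, "+", "VSG_related",
                   id = id)
          mvsg[[length(mvsg) + 1]] <<- data.frame(
            chromosome = chrom, gene_id = id, start = pos,
            end = pos + config$gene_length, fold = config$mvsg_fold,
            stringsAsFactors = FALSE)
        } else {
          add_gene(pos, pos + config$gene_length,
                   sample(c("+", "-"), 1), sample(cats, 1))
        }
        first <- FALSE
        pos <- pos + config$gene_length + config$intergenic
      }
    }
    lay_subtel(aL, core0, left = TRUE)
    lay_subtel(core1, L - aL, left = FALSE)

    ## ---- core: alternating-strand DGCs separated by SSRs ----------------
    pos <- core0 + config$ssr_gap / 2
    strand <- "-"
    dgc_bounds <- list()
    while (TRUE) {
      n_genes <- max(3, stats::rpois(1, config$genes_per_dgc))
      need <- n_genes * (config$gene_length + config$intergenic)
      if (pos + need > core1 - config$ssr_gap / 2) {
        n_genes <- floor((core1 - config$ssr_gap / 2 - pos) /
                         (config$gene_length + config$intergenic))
        if (n_genes < 3) break
      }
      d0 <- pos
      for (i in seq_len(n_genes)) {
        cat_i <- if (stats::runif(1) < config$hypothetical_rate)
          "hypothetical" else "ordinary"
        add_gene(pos, pos + config$gene_length, strand, cat_i,
                 design = "core")
        pos <- pos + config$gene_length + config$intergenic
      }
      dgc_bounds[[length(dgc_bounds) + 1]] <- data.frame(
        chromosome = chrom, start = d0,
        end = pos - config$intergenic, strand = strand,
        stringsAsFactors = FALSE)
      pos <- pos - config$intergenic + config$ssr_gap
      strand <- if (strand == "+") "-" else "+"
      if (pos >= core1 - config$ssr_gap) break
    }

    gc <- do.call(rbind, g)
    gc <- gc[order(gc$start), , drop = FALSE]
    ## class-neutral categories (hypothetical, ESAG3) carry no boundary
    voting <- !(gc$category %in% c("hypothetical", "ESAG3"))
    tracks[[chrom]] <- .truth_track(chrom, gc$design[voting],
                                    gc$start[voting], gc$end[voting], L)
    genes[[chrom]] <- gc
  }

  genes <- do.call(rbind, genes)
  rownames(genes) <- NULL
  design <- genes$design
  genes$design <- NULL

  truth_dgcs <- build_dgcs(genes[design == "core", , drop = FALSE])
  truth_ssrs <- classify_ssrs(truth_dgcs)

  ## binding sites: every SSR midpoint, plus array 5' flanks drawn above
  ssr_sites <- data.frame(
    chromosome = truth_ssrs$chromosome,
    start = floor((truth_ssrs$start + truth_ssrs$end) / 2) -
      config$site_halfwidth,
    end = floor((truth_ssrs$start + truth_ssrs$end) / 2) +
      config$site_halfwidth,
    kind = paste0(truth_ssrs$ssr_type, rep("_ssr", nrow(truth_ssrs))),
    stringsAsFactors = FALSE)
  ## intra-DGC sites: internal transcription start/stop points carry
  ## initiator binding in a fraction of clusters
  dgc_sites <- NULL
  if (nrow(truth_dgcs) > 0) {
    pick <- stats::runif(nrow(truth_dgcs)) < config$intra_dgc_site_rate
    if (any(pick)) {
      d <- truth_dgcs[pick, , drop = FALSE]
      at <- floor(d$start + (d$end - d$start) *
                    stats::runif(nrow(d), 0.25, 0.75))
      dgc_sites <- data.frame(chromosome = d$chromosome,
                              start = at - config$site_halfwidth,
                              end = at + config$site_halfwidth,
                              kind = rep("intra_dgc", nrow(d)),
                              stringsAsFactors = FALSE)
    }
  }
  truth_sites <- rbind(ssr_sites, dgc_sites, do.call(rbind, sites))
  truth_sites <- truth_sites[order(truth_sites$chromosome,
                                   truth_sites$start), , drop = FALSE]
  rownames(truth_sites) <- NULL

  ## origins: at divergent SSR midpoints, spaced >= origin_spacing, with
  ## per-flank speeds set by the transcription direction of the flanking
  ## DGCs (both flanks of a divergent SSR are co-directional, so these
  ## origins are symmetric)
  origins <- list()
  for (chrom in names(config$chromosomes)) {
    div <- truth_ssrs[truth_ssrs$chromosome == chrom &
                      truth_ssrs$ssr_type == "divergent", , drop = FALSE]
    last <- -Inf
    for (k in seq_len(nrow(div))) {
      p <- floor((div$start[k] + div$end[k]) / 2)
      if (p - last < config$origin_spacing) next
      last <- p
      origins[[length(origins) + 1]] <- data.frame(
        chromosome = chrom, position = p,
        speed_left = config$fork_speed * config$speed_multiplier,
        speed_right = config$fork_speed * config$speed_multiplier,
        efficiency = config$origin_efficiency,
        stringsAsFactors = FALSE)
    }
  }
  truth_origins <- do.call(rbind, origins)
  if (is.null(truth_origins))
    truth_origins <- data.frame(chromosome = character(0),
                                position = numeric(0),
                                speed_left = numeric(0),
                                speed_right = numeric(0),
                                efficiency = numeric(0))
  rownames(truth_origins) <- NULL

  region_track <- do.call(rbind, tracks)
  rownames(region_track) <- NULL

  out <- list(genes = genes,
              repeats = do.call(rbind, repeats),
              chromosome_lengths = config$chromosomes,
              truth = list(region_classes = region_track,
                           dgcs = truth_dgcs, ssrs = truth_ssrs,
                           sites = truth_sites, origins = truth_origins,
                           mvsg = do.call(rbind, mvsg)))
  out$truth$replicated_fraction <- .truth_replicated_fraction(out, config)

  if (emit_sequence) {
    set.seed(config$seed + 7)
    seqs <- lapply(names(config$chromosomes), function(chrom) {
      L <- config$chromosomes[[chrom]]
      tr <- region_track[region_track$chromosome == chrom, , drop = FALSE]
      base <- character(L)
      for (k in seq_len(nrow(tr))) {
        at <- config$at_content[[tr$class[k]]]
        n <- tr$end[k] - tr$start[k]
        if (n <= 0) next
        base[(tr$start[k] + 1):tr$end[k]] <-
          sample(c("A", "T", "C", "G"), n, replace = TRUE,
                 prob = c(at / 2, at / 2, (1 - at) / 2, (1 - at) / 2))
      }
      paste(base, collapse = "")
    })
    out$sequence <- Biostrings::DNAStringSet(unlist(seqs))
    names(out$sequence) <- names(config$chromosomes)
  }
  out
}

## Expected replicated fraction: positions reachable by a fork from some
## origin within the sampled S window (earliest firing).
.truth_replicated_fraction <- function(genome, config) {
  if (is.null(genome$truth$origins) || nrow(genome$truth$origins) == 0)
    return(0)
  u_max <- config$s_window[2]
  covered <- 0
  for (chrom in names(genome$chromosome_lengths)) {
    L <- genome$chromosome_lengths[[chrom]]
    o <- genome$truth$origins[genome$truth$origins$chromosome == chrom, ,
                              drop = FALSE]
    if (nrow(o) == 0) next
    iv <- IRanges::reduce(IRanges::IRanges(
      start = pmax(1, o$position - o$speed_left * u_max),
      end = pmin(L, o$position + o$speed_right * u_max)))
    covered <- covered + sum(IRanges::width(iv))
  }
  covered / sum(genome$chromosome_lengths)
}

#' Simulate a tiling-array ChIP probe table
#'
#' Probes every `probe_spacing` bp; log2 ratio = Gaussian baseline noise
#' plus a plateau of log2(`chip_fold`) over each true site footprint.
#'
#' @param genome output of [generate_genome()].
#' @param config the [sim_config()] used.
#' @return probe signal data.frame(probe_id, chromosome, position,
#'   log2_ratio).
#' @export
simulate_chip <- function(genome, config) {
  set.seed(config$seed + 1)
  parts <- lapply(names(genome$chromosome_lengths), function(chrom) {
    L <- genome$chromosome_lengths[[chrom]]
    pos <- seq(1, L - 1, by = config$probe_spacing)
    val <- stats::rnorm(length(pos), 0, config$probe_noise_sd)
    s <- genome$truth$sites
    if (is.null(s)) s <- data.frame(chromosome = character(0))
    s <- s[s$chromosome == chrom, , drop = FALSE]
    for (k in seq_len(nrow(s))) {
      sel <- pos >= s$start[k] & pos < s$end[k]
      val[sel] <- val[sel] + log2(config$chip_fold)
    }
    data.frame(probe_id = paste0(chrom, "_", seq_along(pos)),
               chromosome = chrom, position = pos, log2_ratio = val,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

## Semi-analytic per-position replication probability for one chromosome:
## p(x) = E_u[ 1 - prod_i (1 - e_i * clamp((u - d_i(x)/v_i) / w_f, 0, 1)) ]
## with firing times uniform on [0, w_f] and sampling time u uniform over
## the S window.
.replication_probability <- function(x, origins, config) {
  u_grid <- seq(config$s_window[1], config$s_window[2],
                length.out = config$u_grid)
  w <- config$firing_window
  ## fork arrival time per origin (independent of the sampling time)
  tt <- lapply(seq_len(nrow(origins)), function(k) {
    d <- x - origins$position[k]
    pmax(d, 0) / origins$speed_right[k] +
      pmax(-d, 0) / origins$speed_left[k]
  })
  p <- numeric(length(x))
  for (u in u_grid) {
    not_rep <- rep(1, length(x))
    for (k in seq_len(nrow(origins))) {
      pr <- origins$efficiency[k] * pmin(pmax((u - tt[[k]]) / w, 0), 1)
      not_rep <- not_rep * (1 - pr)
    }
    p <- p + (1 - not_rep)
  }
  p / length(u_grid)
}

#' Simulate S-phase and G2 read-depth tracks
#'
#' Per-position expected copy number is 1 + P(replicated by the sampled
#' time), computed semi-analytically by integrating origin firing
#' (uniform over the firing window) and the sampling time (uniform over
#' the S window) against fork arrival times; read depth is negative
#' binomial with mean proportional to copy number.  G2 has uniform copy
#' number.
#'
#' @param genome output of [generate_genome()] (its `truth$origins` may be
#'   replaced to plant custom origins).
#' @param config the [sim_config()] used.
#' @return list per chromosome of list(S, G2) per-position depth vectors,
#'   plus attribute `p` holding the per-position replication probability.
#' @export
simulate_replication <- function(genome, config) {
  set.seed(config$seed + 2)
  out <- lapply(names(genome$chromosome_lengths), function(chrom) {
    L <- genome$chromosome_lengths[[chrom]]
    o <- genome$truth$origins
    if (is.null(o)) o <- data.frame(chromosome = character(0))
    o <- o[o$chromosome == chrom, , drop = FALSE]
    if (nrow(o) == 0) {
      p <- numeric(L)
    } else if (config$p_step > 1) {
      ## p is piecewise linear in position to excellent approximation:
      ## evaluate on a coarse grid and interpolate
      grid <- unique(c(seq(1, L, by = config$p_step), L))
      pg <- .replication_probability(grid, o, config)
      p <- stats::approx(grid, pg, xout = seq_len(L))$y
    } else {
      p <- .replication_probability(seq_len(L), o, config)
    }
    mu_s <- config$depth_mean * (1 + p) / mean(1 + p)
    s <- stats::rnbinom(L, size = config$depth_dispersion, mu = mu_s)
    g2 <- stats::rnbinom(L, size = config$depth_dispersion,
                         mu = config$depth_mean)
    structure(list(S = s, G2 = g2), p = p)
  })
  names(out) <- names(genome$chromosome_lengths)
  out
}

#' Simulate induced/uninduced knockdown transcriptomes
#'
#' Uninduced: uniform expression over DGC spans, a low baseline at the
#' silent MVSG-like loci, zero elsewhere.  Induced: boundary elevation by
#' `boundary_fold` within `boundary_extent` bp inside each DGC end, new
#' signal over the same extent outside the DGC (readthrough past
#' starts/stops), and MVSG-like loci derepressed by `mvsg_fold`.
#' Negative-binomial noise per position.
#'
#' @inheritParams simulate_replication
#' @return list per chromosome of list(induced, uninduced) depth vectors.
#' @export
simulate_rnai <- function(genome, config) {
  set.seed(config$seed + 3)
  out <- lapply(names(genome$chromosome_lengths), function(chrom) {
    L <- genome$chromosome_lengths[[chrom]]
    mu_u <- numeric(L); mu_i <- numeric(L)
    d <- genome$truth$dgcs
    d <- d[d$chromosome == chrom, , drop = FALSE]
    for (k in seq_len(nrow(d))) {
      span <- (d$start[k] + 1):d$end[k]
      mu_u[span] <- config$expr_mean
      mu_i[span] <- config$expr_mean
      ext <- config$boundary_extent
      for (b in c(d$start[k], d$end[k])) {
        inside <- intersect((b - ext + 1):(b + ext), span)
        mu_i[inside] <- config$expr_mean * config$boundary_fold
        outside <- setdiff(max(1, b - ext + 1):min(L, b + ext), span)
        mu_i[outside] <- pmax(mu_i[outside],
                              config$expr_mean * config$readthrough_level)
      }
    }
    m <- genome$truth$mvsg
    m <- m[m$chromosome == chrom, , drop = FALSE]
    for (k in seq_len(nrow(m))) {
      span <- (m$start[k] + 1):m$end[k]
      mu_u[span] <- config$mvsg_base_depth
      mu_i[span] <- config$mvsg_base_depth * m$fold[k]
    }
    draw <- function(mu) {
      v <- numeric(L)
      nz <- mu > 0
      v[nz] <- stats::rnbinom(sum(nz), size = config$rnai_dispersion,
                              mu = mu[nz])
      v
    }
    list(induced = draw(mu_i), uninduced = draw(mu_u))
  })
  names(out) <- names(genome$chromosome_lengths)
  out
}

#' Simulate a replicate Ct table from true S:G2 quantity ratios
#'
#' Ct = base - log2(quantity) + Gaussian replicate noise; the calibrator
#' amplicon `CAL` sits at ratio 1 in both samples.
#'
#' @param true_ratios named numeric vector of true S:G2 ratios per
#'   amplicon (all > 0).
#' @param config the [sim_config()] used.
#' @return data.frame(amplicon, sample, ct).
#' @export
simulate_qpcr <- function(true_ratios, config) {
  stopifnot(all(true_ratios > 0))
  set.seed(config$seed + 4)
  ratios <- c(true_ratios, CAL = 1)
  rows <- list()
  for (a in names(ratios)) {
    for (smp in c("S", "G2")) {
      q <- if (smp == "S") ratios[[a]] else 1
      ct <- config$qpcr_base_ct - log2(q) +
        stats::rnorm(config$qpcr_replicates, 0, config$qpcr_noise_sd)
      rows[[length(rows) + 1]] <- data.frame(
        amplicon = a, sample = smp, ct = ct, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
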