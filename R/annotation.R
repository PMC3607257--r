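## Chromosome demarcation and transcription-unit annotation.
##
## Coordinates are 0-based, half-open throughout the package; GFF3 IO
## converts to/from 1-based inclusive (see io.R).

GENE_CATEGORIES <- c("ordinary", "hypothetical", "VSG", "VSG_related",
                     "ESAG", "ESAG3", "RHS", "pseudogene")

## Categories that trigger a subtelomere-proximal call.  ESAG3 is excluded
## because it also occurs inside VSG arrays.
SUBTEL_CATEGORIES <- c("RHS", "VSG_related", "ESAG")

#' Construct and validate a gene record table
#'
#' @param gene_id character vector of gene identifiers.
#' @param chromosome character vector of chromosome names.
#' @param start,end 0-based half-open coordinates (start < end).
#' @param strand "+" (forward) or "-" (reverse).
#' @param category one of `ordinary`, `hypothetical`, `VSG`, `VSG_related`,
#'   `ESAG`, `ESAG3`, `RHS`, `pseudogene`.
#' @return data.frame with one row per gene, sorted by chromosome and start.
#' @export
gene_records <- function(gene_id, chromosome, start, end, strand, category) {
  if (length(gene_id) == 0)
    return(data.frame(gene_id = character(0), chromosome = character(0),
                      start = numeric(0), end = numeric(0),
                      strand = character(0), category = character(0),
                      stringsAsFactors = FALSE))
  df <- data.frame(gene_id = as.character(gene_id),
                   chromosome = as.character(chromosome),
                   start = as.numeric(start), end = as.numeric(end),
                   strand = as.character(strand),
                   category = as.character(category),
                   stringsAsFactors = FALSE)   # length-1 args recycle
  stopifnot(all(df$start < df$end),
            all(df$strand %in% c("+", "-")),
            all(df$category %in% GENE_CATEGORIES))
  df <- df[order(df$chromosome, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

## Gene-level class used by the demarcation scan.  Hypothetical genes and
## ESAG3 (which occurs both in subtelomeres and inside VSG arrays) are
## neutral: they carry no class vote.
gene_class <- function(category) {
  ifelse(category == "VSG", "vsg_array",
         ifelse(category %in% SUBTEL_CATEGORIES, "subtelomere",
                ifelse(category %in% c("hypothetical", "ESAG3"),
                       NA_character_, "core")))
}

#' Demarcate a chromosome into core, subtelomere, and VSG-array regions
#'
#' Scans the gene list inward from each chromosome end.  On each arm the
#' sequence up to and including the outermost run of VSG genes becomes a
#' `vsg_array` region; runs of RHS/VSG-related/ESAG genes (ESAG3 excluded,
#' since it also populates arrays) adjacent to an array become
#' `subtelomere`; the span covering all remaining non-hypothetical genes is
#' `core`.  Short internal runs of subtelomeric-category genes inside the
#' core (relics of chromosome fusions) are labelled `subtelomere` when at
#' least `min_island` consecutive qualifying genes occur.  Hypothetical
#' genes are ignored for all class decisions.  Boundaries between classes
#' fall at the midpoint of the inter-gene gap; inter-gene gaps within a
#' class inherit that class, so the track covers `[0, chromosome_length)`
#' exactly.
#'
#' @param genes gene record table for one chromosome, sorted by start.
#' @param chromosome_length chromosome length in bp.
#' @param min_island minimum consecutive subtelomeric-category genes for an
#'   internal subtelomere island (default 2).
#' @param min_array_genes minimum VSG genes in a terminal run to found a
#'   `vsg_array` (default 1); isolated internal VSGs below this count are
#'   treated as island content instead.
#' @return data.frame(chromosome, start, end, class) covering the
#'   chromosome; attribute `degenerate` is TRUE for an empty gene list.
#' @export
demarcate_chromosome <- function(genes, chromosome_length,
                                 min_island = 2, min_array_genes = 1) {
  if (nrow(genes) == 0) {
    out <- data.frame(chromosome = NA_character_, start = 0, end = 0,
                      class = "core", stringsAsFactors = FALSE)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  if (is.unsorted(genes$start)) stop("genes must be sorted by start")
  if (length(unique(genes$chromosome)) != 1L)
    stop("demarcate_chromosome() expects a single chromosome")
  if (any(genes$end > chromosome_length))
    stop("gene coordinates exceed chromosome length")
  chrom <- genes$chromosome[1]

  cls0 <- gene_class(genes$category)
  g <- genes[!is.na(cls0), , drop = FALSE]
  if (nrow(g) == 0) stop("at least one non-hypothetical gene is required")
  cls <- cls0[!is.na(cls0)]
  n <- nrow(g)

  ## --- terminal arrays, one arm at a time -------------------------------
  ## Arm prefix = genes before the first core-class gene; the array covers
  ## everything up to and including the outermost run's last VSG.
  first_core <- match("core", cls)
  last_core <- n + 1 - match("core", rev(cls))
  if (is.na(first_core)) { first_core <- n + 1; last_core <- 0 }

  arm_assign <- function(idx) {
    ## idx: indices of one arm prefix, ordered outermost-first.
    ## Returns class per index ("vsg_array" or "subtelomere").
    out <- rep("subtelomere", length(idx))
    vsg <- which(cls[idx] == "vsg_array")
    if (length(vsg) >= min_array_genes && length(vsg) > 0) {
      out[seq_len(max(vsg))] <- "vsg_array"
    }
    out
  }

  assigned <- cls
  if (first_core > 1) {
    left <- seq_len(first_core - 1)
    assigned[left] <- arm_assign(left)
  }
  if (last_core < n) {
    right <- seq(n, last_core + 1)      # outermost-first
    assigned[right] <- arm_assign(right)
  }

  ## --- internal islands --------------------------------------------------
  if (first_core <= last_core) {
    mid <- seq(first_core, last_core)
    island_like <- cls[mid] != "core"
    r <- rle(island_like)
    pos <- cumsum(c(1, r$lengths))
    for (k in seq_along(r$lengths)) {
      if (r$values[k] && r$lengths[k] >= min_island) {
        run <- mid[seq(pos[k], length.out = r$lengths[k])]
        assigned[run] <- "subtelomere"
      } else if (r$values[k]) {
        run <- mid[seq(pos[k], length.out = r$lengths[k])]
        assigned[run] <- "core"         # lone stragglers absorbed by core
      }
    }
  }

  ## --- join gaps: boundaries at midpoints between class changes ----------
  runs <- rle(assigned)
  nr <- length(runs$lengths)
  run_end_idx <- cumsum(runs$lengths)
  run_start_idx <- c(1, head(run_end_idx, -1) + 1)
  starts <- numeric(nr); ends <- numeric(nr)
  for (k in seq_len(nr)) {
    starts[k] <- if (k == 1) 0 else
      floor((g$end[run_end_idx[k - 1]] + g$start[run_start_idx[k]]) / 2)
    ends[k] <- if (k == nr) chromosome_length else
      floor((g$end[run_end_idx[k]] + g$start[run_start_idx[k + 1]]) / 2)
  }
  out <- data.frame(chromosome = chrom, start = starts, end = ends,
                    class = runs$values, stringsAsFactors = FALSE)
  ## merge any adjacent same-class rows (possible after island absorption)
  keep <- c(TRUE, out$class[-1] != out$class[-nrow(out)])
  grp <- cumsum(keep)
  out <- data.frame(chromosome = chrom,
                    start = tapply(out$start, grp, min),
                    end = tapply(out$end, grp, max),
                    class = out$class[keep],
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "degenerate") <- FALSE
  out
}

#' Partition genes into directional gene clusters (DGCs)
#'
#' A DGC is a maximal run of consecutive same-strand genes; hypothetical
#' genes are retained as members.
#'
#' @param genes gene record table (may span chromosomes), sorted.
#' @return data.frame(chromosome, start, end, strand, n_genes, gene_ids)
#'   with `gene_ids` a comma-separated member list in genomic order.
#' @export
build_dgcs <- function(genes) {
  empty <- data.frame(chromosome = character(0), start = numeric(0),
                      end = numeric(0), strand = character(0),
                      n_genes = integer(0), gene_ids = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(genes) == 0) return(empty)
  parts <- lapply(split(genes, genes$chromosome), function(g) {
    g <- g[order(g$start), , drop = FALSE]
    r <- rle(g$strand)
    idx_end <- cumsum(r$lengths)
    idx_start <- c(1, head(idx_end, -1) + 1)
    data.frame(chromosome = g$chromosome[1],
               start = g$start[idx_start],
               end = g$end[idx_end],
               strand = r$values,
               n_genes = r$lengths,
               gene_ids = vapply(seq_along(r$values), function(k)
                 paste(g$gene_id[idx_start[k]:idx_end[k]], collapse = ","),
                 character(1)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out[order(out$chromosome, out$start), , drop = FALSE]
}

#' Classify strand switch regions (SSRs) between adjacent DGCs
#'
#' Each adjacent pair of opposite-strand DGCs yields one SSR spanning the
#' inter-cluster gap: reverse-then-forward is `divergent` (bidirectional
#' transcription initiation), forward-then-reverse is `convergent`
#' (termination).  Same-strand adjacencies yield no SSR.
#'
#' @param dgcs DGC table from [build_dgcs()].
#' @return data.frame(chromosome, start, end, ssr_type).
#' @export
classify_ssrs <- function(dgcs) {
  empty <- data.frame(chromosome = character(0), start = numeric(0),
                      end = numeric(0), ssr_type = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(dgcs) < 2) return(empty)
  parts <- lapply(split(dgcs, dgcs$chromosome), function(d) {
    d <- d[order(d$start), , drop = FALSE]
    if (nrow(d) < 2) return(empty)
    if (any(d$start[-1] < d$end[-nrow(d)])) stop("overlapping DGCs")
    i <- which(d$strand[-nrow(d)] != d$strand[-1])
    if (length(i) == 0) return(empty)
    data.frame(chromosome = d$chromosome[1],
               start = d$end[i], end = d$start[i + 1],
               ssr_type = ifelse(d$strand[i] == "-", "divergent",
                                 "convergent"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out[order(out$chromosome, out$start), , drop = FALSE]
}

#' Parse VSG cassettes within a subtelomeric array
#'
#' Each 70 bp repeat feature anchors one cassette; the next VSG ORF
#' downstream of the repeat (before the next repeat) is assigned to it.
#' The 5' flank spans repeat end to ORF start, and the 3' flank spans ORF
#' end to the next repeat (or the array boundary).
#'
#' @param array_region list or one-row data.frame with `start`, `end` of a
#'   `vsg_array` interval.
#' @param features data.frame(start, end, type, ...) with `type` in
#'   `repeat_70bp` or `vsg_orf`; VSG gene records can be converted by
#'   setting type = "vsg_orf".  Optional column `orf_status`.
#' @return data.frame, one row per cassette, with component intervals
#'   (`repeat_start/end`, `flank5_start/end`, `orf_start/end`,
#'   `flank3_start/end`), `orf_status`, and `flagged` for repeats with no
#'   downstream ORF.
#' @export
parse_vsg_cassettes <- function(array_region, features) {
  a0 <- as.numeric(array_region$start); a1 <- as.numeric(array_region$end)
  f <- features[order(features$start), , drop = FALSE]
  reps <- f[f$type == "repeat_70bp", , drop = FALSE]
  orfs <- f[f$type == "vsg_orf", , drop = FALSE]
  if (nrow(reps) == 0) return(NULL)
  if (is.null(orfs$orf_status))
    orfs$orf_status <- rep("functional", nrow(orfs))
  out <- vector("list", nrow(reps))
  for (k in seq_len(nrow(reps))) {
    r0 <- reps$start[k]; r1 <- reps$end[k]
    next_rep <- if (k < nrow(reps)) reps$start[k + 1] else a1
    cand <- orfs[orfs$start >= r1 & orfs$start < next_rep, , drop = FALSE]
    if (nrow(cand) == 0) {
      out[[k]] <- data.frame(repeat_start = r0, repeat_end = r1,
                             flank5_start = NA, flank5_end = NA,
                             orf_start = NA, orf_end = NA,
                             flank3_start = NA, flank3_end = NA,
                             orf_status = NA_character_, flagged = TRUE)
    } else {
      o <- cand[1, ]
      out[[k]] <- data.frame(repeat_start = r0, repeat_end = r1,
                             flank5_start = r1, flank5_end = o$start,
                             orf_start = o$start, orf_end = o$end,
                             flank3_start = o$end, flank3_end = next_rep,
                             orf_status = o$orf_status, flagged = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cassette component length shares
#'
#' @param cassettes table from [parse_vsg_cassettes()].
#' @return named numeric vector of length fractions for `repeat_70bp`,
#'   `flank_5p`, `vsg_orf`, `flank_3p` (summing to 1 over parsed content).
#' @export
cassette_component_shares <- function(cassettes) {
  ok <- cassettes[!cassettes$flagged, , drop = FALSE]
  lens <- c(repeat_70bp = sum(ok$repeat_end - ok$repeat_start),
            flank_5p = sum(ok$flank5_end - ok$flank5_start),
            vsg_orf = sum(ok$orf_end - ok$orf_start),
            flank_3p = sum(ok$flank3_end - ok$flank3_start))
  lens / sum(lens)
}

#' AT content by region label (bound vs unbound)
#'
#' Computes 100 * (A+T)/(A+C+G+T) over the bases contained in each labelled
#' interval group, optionally split into site-bound and unbound partitions.
#'
#' @param sequence a [Biostrings::DNAStringSet] named by chromosome.
#' @param regions data.frame(chromosome, start, end, label) in 0-based
#'   half-open coordinates; optional logical column `bound`.
#' @return data.frame(label, bound, percent_at, bases).
#' @export
at_content_by_class <- function(sequence, regions) {
  stopifnot(all(regions$chromosome %in% names(sequence)))
  lens <- Biostrings::width(sequence)[match(regions$chromosome,
                                            names(sequence))]
  if (any(regions$start < 0) || any(regions$end > lens))
    stop("interval outside sequence")
  if (is.null(regions$bound)) regions$bound <- NA
  key <- paste(regions$label, regions$bound)
  parts <- lapply(split(regions, key), function(rg) {
    at <- 0; tot <- 0
    for (k in seq_len(nrow(rg))) {
      if (rg$end[k] <= rg$start[k]) next
      sub <- Biostrings::subseq(sequence[[rg$chromosome[k]]],
                                rg$start[k] + 1, rg$end[k])
      fr <- Biostrings::letterFrequency(sub, c("A", "C", "G", "T"))
      at <- at + fr[["A"]] + fr[["T"]]
      tot <- tot + sum(fr)
    }
    data.frame(label = rg$label[1], bound = rg$bound[1],
               percent_at = 100 * at / tot, bases = tot,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}
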