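## Readers/writers for the standard formats the pipeline consumes and
## emits, plus the end-to-end driver.  Internal coordinates are 0-based
## half-open; GFF3 files are 1-based inclusive and BED/bedGraph files are
## 0-based half-open, so GFF3 IO shifts starts by one and BED IO does
## not.

#' Read a gene annotation GFF3
#'
#' Expects `gene` features with a `category` attribute (one of the gene
#' record categories); 1-based inclusive coordinates are converted to
#' 0-based half-open.
#'
#' @param path GFF3 file.
#' @return gene record table as from [gene_records()].
#' @export
read_gff3_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  gene_records(gene_id = gr$ID,
               chromosome = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr) - 1,
               end = GenomicRanges::end(gr),
               strand = as.character(GenomicRanges::strand(gr)),
               category = gr$category)
}

#' Write gene records as GFF3
#'
#' @param genes gene record table.
#' @param path output file.
#' @export
write_gff3_genes <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    genes$chromosome,
    IRanges::IRanges(genes$start + 1, genes$end),
    strand = genes$strand)
  gr$type <- "gene"
  gr$ID <- genes$gene_id
  gr$category <- genes$category
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read/write interval tables as BED
#'
#' BED is 0-based half-open, matching the internal convention; the name
#' column carries the class/label when present.
#'
#' @param path BED file.
#' @return data.frame(chromosome, start, end[, name, score]).
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  out <- data.frame(chromosome = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1,
                    end = GenomicRanges::end(gr),
                    stringsAsFactors = FALSE)
  ## only surface the columns the file actually carries
  first <- grep("^(track|browser|#)", readLines(path, n = 50),
                invert = TRUE, value = TRUE)[1]
  nfield <- length(strsplit(first, "\t")[[1]])
  if (nfield >= 4 && !is.null(gr$name)) out$name <- gr$name
  if (nfield >= 5 && !is.null(gr$score)) out$score <- gr$score
  out
}

#' @rdname read_bed
#' @param intervals data.frame(chromosome, start, end) with optional
#'   `name` and `score` columns.
#' @export
write_bed <- function(intervals, path) {
  gr <- GenomicRanges::GRanges(
    intervals$chromosome,
    IRanges::IRanges(intervals$start + 1, intervals$end))
  if (!is.null(intervals$name)) gr$name <- intervals$name
  if (!is.null(intervals$score)) gr$score <- intervals$score
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read/write binned signal tracks as bedGraph
#'
#' @param path bedGraph file; track and comment lines are tolerated.
#' @return data.frame(chromosome, start, end, value).
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  data.frame(chromosome = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             value = gr$score, stringsAsFactors = FALSE)
}

#' @rdname read_bedgraph
#' @param track data.frame(chromosome, start, end, value).
#' @export
write_bedgraph <- function(track, path) {
  gr <- GenomicRanges::GRanges(
    track$chromosome, IRanges::IRanges(track$start + 1, track$end),
    score = track$value)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read a FASTA file of chromosome sequences
#'
#' @param path FASTA file.
#' @return [Biostrings::DNAStringSet] named by chromosome.
#' @export
read_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' Read a Ct replicate table
#'
#' @param path TSV with columns amplicon, sample, ct.
#' @return data.frame as required by [ddct_quantity()].
#' @export
read_ct_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("amplicon", "sample", "ct")
  if (!all(need %in% names(df)))
    stop("Ct table must have columns: ", paste(need, collapse = ", "))
  df
}

#' Run the full synthetic pipeline
#'
#' Generates a genome, then runs annotation, ChIP site calling, MFA
#' origin mapping, qPCR quantification at the origin apexes, and the
#' knockdown analysis, writing tables and a JSON run manifest recording
#' seeds and parameters.  Identical config gives identical outputs.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @param stages character vector of stages to run, a subset of
#'   `annotate`, `chip`, `mfa`, `qpcr`, `rnai`.
#' @return invisible list of stage results (also written to `out_dir`).
#' @export
run_pipeline <- function(config, out_dir,
                         stages = c("annotate", "chip", "mfa", "qpcr",
                                    "rnai")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  genome <- generate_genome(config)
  res <- list(genome = genome)
  manifest <- list(package_version = as.character(
                     utils::packageVersion("orcmap")),
                   seed = config$seed, stages = list())

  if ("annotate" %in% stages) {
    tracks <- do.call(rbind, lapply(names(config$chromosomes), function(ch) {
      demarcate_chromosome(
        genome$genes[genome$genes$chromosome == ch, , drop = FALSE],
        config$chromosomes[[ch]])
    }))
    dgcs <- build_dgcs(genome$genes[
      .midpoint_assign(genome$genes, tracks, "class") == "core", ,
      drop = FALSE])
    ssrs <- classify_ssrs(dgcs)
    utils::write.table(tracks, file.path(out_dir, "region_classes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(ssrs, file.path(out_dir, "ssrs.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    res$annotation <- list(region_classes = tracks, dgcs = dgcs,
                           ssrs = ssrs)
    manifest$stages$annotate <- list(done = TRUE)
  }

  if ("chip" %in% stages) {
    probes <- simulate_chip(genome, config)
    sites <- call_sites(probes, seed = config$seed + 11)
    merged <- merge_sites(sites)
    utils::write.table(sites, file.path(out_dir, "sites.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    res$chip <- list(sites = sites, merged = merged)
    manifest$stages$chip <- list(done = TRUE, seed = config$seed + 11,
                                 n_sites = nrow(sites))
  }

  if ("mfa" %in% stages) {
    depth <- simulate_replication(genome, config)
    peaks <- do.call(rbind, lapply(names(depth), function(ch) {
      s <- bin_depth(depth[[ch]]$S, chromosome = ch)
      g2 <- bin_depth(depth[[ch]]$G2, chromosome = ch)
      call_obr_peaks(ratio_and_normalize(s, g2))
    }))
    utils::write.table(peaks, file.path(out_dir, "obr_peaks.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res$mfa <- list(peaks = peaks, depth = depth)
    if (!is.null(res$chip)) {
      res$mfa$colocalization <- colocalize_peaks_with_features(
        peaks, res$chip$merged)
    } else {
      res$mfa$colocalization <- "sites unavailable (chip stage disabled)"
    }
    manifest$stages$mfa <- list(done = TRUE, seed = config$seed + 2,
                                n_peaks = nrow(peaks))
  }

  if ("qpcr" %in% stages) {
    ratios <- c(ORI = 1.8, MID = 1.3, DIST = 1.0)
    ct <- simulate_qpcr(ratios, config)
    quant <- ddct_table(ct, "CAL")
    utils::write.table(quant, file.path(out_dir, "qpcr_quantities.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res$qpcr <- quant
    manifest$stages$qpcr <- list(done = TRUE, seed = config$seed + 4)
  }

  if ("rnai" %in% stages) {
    expr <- simulate_rnai(genome, config)
    folds <- do.call(rbind, lapply(names(expr), function(ch) {
      ls <- normalize_library_size(expr[[ch]]$induced,
                                   expr[[ch]]$uninduced)
      gene_fold_changes(ls$a, ls$b,
                        genome$genes[genome$genes$chromosome == ch, ,
                                     drop = FALSE])
    }))
    utils::write.table(folds, file.path(out_dir, "gene_fold_changes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res$rnai <- list(fold_changes = folds)
    manifest$stages$rnai <- list(done = TRUE, seed = config$seed + 3,
      n_significant = sum(folds$significant))
  }

  manifest$parameters <- unclass(config)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(res)
}
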