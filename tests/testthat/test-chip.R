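make_track <- function(values, spacing = 61, chromosome = "1") {
  data.frame(probe_id = paste0("p", seq_along(values)),
             chromosome = chromosome,
             position = seq(1, by = spacing, length.out = length(values)),
             log2_ratio = values, stringsAsFactors = FALSE)
}

test_that("rescale_min_zero shifts each chromosome to a zero minimum", {
  tr <- make_track(c(1, 2, 3))
  expect_equal(rescale_min_zero(tr)$log2_ratio, c(0, 1, 2))
  expect_equal(rescale_min_zero(make_track(c(5, 5, 5)))$log2_ratio,
               c(0, 0, 0))
  set.seed(2)
  tr2 <- make_track(rnorm(100))
  out <- rescale_min_zero(tr2)$log2_ratio
  expect_equal(min(out), 0)
  expect_equal(diff(out), diff(tr2$log2_ratio))
})

test_that("a flat positive track makes every covered window a hit", {
  tr <- make_track(rep(2, 100))
  cand <- detect_enriched_windows(tr, 0.9)
  expect_equal(nrow(cand), 1)
  expect_lte(cand$start, tr$position[1])
  expect_gte(cand$end, tr$position[97])
})

test_that("a planted enriched region is detected as one candidate", {
  set.seed(31)
  n <- 2000
  vals <- rnorm(n, 0, 0.1)
  plant <- 1000:1009                       # 10 probes, ~550 bp
  vals[plant] <- 4.0
  tr <- rescale_min_zero(make_track(vals))
  cand <- detect_enriched_windows(tr, 0.9)
  expect_equal(nrow(cand), 1)
  expect_lte(cand$start, tr$position[1000])
  expect_gte(cand$end, tr$position[1009])
  # monotone in cutoff: higher-cutoff candidates nest in lower-cutoff ones
  lo <- detect_enriched_windows(tr, 0.15)
  for (k in seq_len(nrow(cand)))
    expect_true(any(lo$start <= cand$start[k] & lo$end >= cand$end[k]))
  # fewer probes than min_probes: empty result
  expect_equal(nrow(detect_enriched_windows(make_track(c(4, 4, 4)), 0.5)),
               0)
})

test_that("randomization FDR is near 1 on exchangeable noise", {
  set.seed(8)
  tr <- rescale_min_zero(make_track(rnorm(3000, 0, 0.3)))
  fdr <- estimate_fdr(tr, c(0.5, 0.3, 0.15), n_randomizations = 10,
                      seed = 4)
  obs <- fdr$fdr[fdr$observed > 0]
  expect_true(all(is.na(fdr$fdr) | fdr$fdr > 0.5))
  expect_true(length(obs) == 0 || all(obs > 0.5))
})

test_that("planted sites are called in the high-FDR class", {
  cfg <- sim_config(seed = 21, chromosomes = c("1" = 6e5))
  pos <- seq(50000, 550000, length.out = 12)
  truth <- data.frame(chromosome = "1", start = pos - 500, end = pos + 500)
  probes <- simulate_chip(stub_genome(c("1" = 6e5), sites = truth), cfg)
  sites <- call_sites(probes, seed = 5)
  merged <- merge_sites(sites[sites$fdr_class == "high", ])
  hit <- vapply(seq_len(nrow(truth)), function(k)
    any(merged$chromosome == truth$chromosome[k] &
        merged$start < truth$end[k] & merged$end > truth$start[k]),
    logical(1))
  expect_gte(sum(hit), 11)
  # shift invariance of the calls
  shifted <- probes
  shifted$log2_ratio <- shifted$log2_ratio + 3.7
  sites2 <- call_sites(shifted, seed = 5)
  expect_equal(sites2[, c("chromosome", "start", "end", "fdr_class")],
               sites[, c("chromosome", "start", "end", "fdr_class")])
})

test_that("merge_sites groups by gap with transitive closure", {
  s <- data.frame(chromosome = "1", start = c(0, 5000, 20000),
                  end = c(1000, 6000, 21000))
  m <- merge_sites(s, 10000)
  expect_equal(nrow(m), 2)
  expect_equal(m$start, c(0, 20000))
  expect_equal(m$end, c(6000, 21000))
  expect_equal(m$n_members, c(2L, 1L))
  # single site and zero gap are identities
  expect_equal(nrow(merge_sites(s[1, ], 10000)), 1)
  expect_equal(merge_sites(s, 0)[, c("start", "end")],
               s[, c("start", "end")])
  # idempotent; monotone in the gap
  expect_equal(nrow(merge_sites(m, 10000)), nrow(m))
  expect_lte(nrow(merge_sites(s, 20000)), nrow(m))
})

test_that("merge_sites matches the naive closure on random inputs", {
  set.seed(14)
  for (rep in 1:60) {
    n <- sample(1:12, 1)
    start <- sort(sample(0:300, n)) * 100
    end <- start + sample(50:900, n, replace = TRUE)
    gap <- sample(c(0, 500, 5000, 10000), 1)
    s <- data.frame(chromosome = "1", start = start, end = end)
    got <- merge_sites(s, gap)
    want <- naive_merge(start, end, gap)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
  }
})

test_that("histone loci are merged before the size filter", {
  loci <- data.frame(chromosome = "1", start = c(0, 2600),
                     end = c(600, 3200))
  m <- merge_h4k10ac(loci)
  expect_equal(nrow(m), 1)                 # 3.2 kb merged span retained
  expect_equal(m$end - m$start, 3200)
  expect_equal(nrow(merge_h4k10ac(loci[1, ])), 0)   # 600 bp discarded
  big <- data.frame(chromosome = "1", start = 0, end = 1500)
  expect_equal(nrow(merge_h4k10ac(big)), 1)
})

test_that("spacing statistics reproduce printed-table arithmetic", {
  expect_equal(region_spacing(22.3e6, 170) / 1000, 131.18, tolerance = 0.01)
  expect_equal(region_spacing(1.3e6, 107) / 1000, 12.15, tolerance = 0.01)
})

test_that("site/region association counts form a partition", {
  track <- data.frame(chromosome = "1",
                      start = c(0, 100000, 900000),
                      end = c(100000, 900000, 1000000),
                      class = c("vsg_array", "core", "vsg_array"))
  dgcs <- data.frame(chromosome = "1", start = c(110000, 500000),
                     end = c(400000, 850000), strand = c("-", "+"))
  ssrs <- data.frame(chromosome = "1", start = 400000, end = 500000,
                     ssr_type = "divergent")
  sites <- data.frame(chromosome = "1",
                      start = c(50000, 150000, 420000, 600000, 920000),
                      end = c(51000, 151000, 421000, 601000, 921000))
  a <- associate_sites_with_regions(sites, track, ssrs, dgcs)
  expect_equal(sum(a$by_class$n_sites), nrow(sites))
  expect_equal(a$by_class$n_sites[a$by_class$class == "core"], 3)
  bf <- a$by_feature
  expect_equal(bf$n_sites[bf$feature == "divergent_ssr"], 1)
  expect_equal(bf$n_occupied[bf$feature == "divergent_ssr"], 1)
  expect_equal(bf$n_sites[bf$feature == "intra_dgc"], 2)
  expect_equal(bf$occupancy[bf$feature == "intra_dgc"], 1)
})

test_that("proximity_and_overlap measures edge gaps and overlap", {
  a <- data.frame(chromosome = "1", start = 0, end = 1000)
  b <- data.frame(chromosome = "1", start = 12000, end = 13000)
  r <- proximity_and_overlap(a, b, within = 15000)
  expect_equal(r$n_within, 1)
  expect_equal(r$n_overlap, 0)
  expect_equal(r$pairs$distance, 11000)
  ident <- proximity_and_overlap(a, a)
  expect_equal(ident$n_overlap, 1)
  expect_equal(ident$pairs$distance, 0)
})

test_that("upstream orientation is resolved against DGC strand", {
  dgcs <- data.frame(chromosome = "1", start = c(0, 60000),
                     end = c(50000, 120000), strand = c("+", "-"))
  a <- data.frame(chromosome = "1", start = c(10000, 90000),
                  end = c(11000, 91000))
  b <- data.frame(chromosome = "1", start = c(15000, 80000),
                  end = c(16000, 81000))
  r <- proximity_and_overlap(a, b, dgcs = dgcs)
  # forward DGC: site before mark is upstream; reverse DGC: site after
  expect_true(r$pairs$upstream[1])
  expect_true(r$pairs$upstream[2])
})
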