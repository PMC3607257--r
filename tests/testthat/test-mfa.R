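test_that("bin_depth averages per bin, partial final bin included", {
  b <- bin_depth(rep(10, 5000), 2500)
  expect_equal(b$value, c(10, 10))
  b2 <- bin_depth(c(rep(0, 2500), rep(10, 2500)), 2500)
  expect_equal(b2$value, c(0, 10))
  # linear ramp: bin means are the midpoint values
  n <- 10000
  b3 <- bin_depth(seq_len(n), 2500)
  expect_equal(b3$value, c(1250.5, 3750.5, 6250.5, 8750.5))
  # partial final bin averaged over its true length
  b4 <- bin_depth(rep(4, 3000), 2500)
  expect_equal(b4$end, c(2500, 3000))
  expect_equal(b4$value, c(4, 4))
  expect_equal(nrow(bin_depth(numeric(0))), 0)
})

test_that("S = G2 gives a ratio track of exactly 1", {
  s <- bin_depth(rep(20, 50000))
  r <- ratio_and_normalize(s, s)
  expect_equal(r$ratio, rep(1, nrow(r)))
})

test_that("ratio normalization is scale-invariant and handles plateaus", {
  set.seed(4)
  depth <- rep(30, 100000)
  s <- bin_depth(depth); g2 <- bin_depth(depth)
  s$value[11:20] <- 60                      # fully replicated region
  r <- ratio_and_normalize(s, g2)
  expect_equal(r$ratio[11:20], rep(2, 10))
  expect_equal(r$ratio[1:10], rep(1, 10))
  # multiplying either track by a constant changes nothing
  s2 <- s; s2$value <- s2$value * 7.3
  expect_equal(ratio_and_normalize(s2, g2)$ratio, r$ratio)
  g22 <- g2; g22$value <- g22$value * 0.21
  expect_equal(ratio_and_normalize(s, g22)$ratio, r$ratio)
})

test_that("zero-G2 bins are excluded and all-zero G2 rejected", {
  s <- bin_depth(rep(10, 25000)); g2 <- s
  g2$value[3] <- 0
  r <- ratio_and_normalize(s, g2)
  expect_true(is.na(r$ratio[3]))
  g2$value[] <- 0
  expect_error(ratio_and_normalize(s, g2), "all-zero")
})

test_that("flat tracks yield no OBR peaks", {
  s <- bin_depth(rep(25, 250000))
  r <- ratio_and_normalize(s, s)
  expect_equal(nrow(call_obr_peaks(r)), 0)
})

test_that("a planted origin yields a named peak at its position", {
  cfg <- sim_config(seed = 13, chromosomes = c("11" = 1.1e6))
  org <- data.frame(chromosome = "11", position = 550000,
                    speed_left = 2.8e5, speed_right = 2.8e5,
                    efficiency = 1)
  depth <- simulate_replication(stub_genome(c("11" = 1.1e6),
                                            origins = org), cfg)
  r <- ratio_and_normalize(bin_depth(depth[["11"]]$S, chromosome = "11"),
                           bin_depth(depth[["11"]]$G2, chromosome = "11"))
  pk <- call_obr_peaks(r)
  expect_equal(nrow(pk), 1)
  expect_lt(abs(pk$center - 550000), 2500)
  expect_equal(pk$name, "OBR:11:0.55")
  expect_equal(pk$symmetry, "symmetric")
})

test_that("two equal-speed origins give two symmetric peaks within a bin", {
  cfg <- sim_config(seed = 17, chromosomes = c("1" = 1e6))
  org <- data.frame(chromosome = "1", position = c(300000, 700000),
                    speed_left = 1.4e5, speed_right = 1.4e5,
                    efficiency = 1)
  depth <- simulate_replication(stub_genome(c("1" = 1e6),
                                            origins = org), cfg)
  r <- ratio_and_normalize(bin_depth(depth[["1"]]$S, chromosome = "1"),
                           bin_depth(depth[["1"]]$G2, chromosome = "1"))
  pk <- call_obr_peaks(r)
  expect_equal(nrow(pk), 2)
  offs <- vapply(org$position, function(p) min(abs(pk$center - p)),
                 numeric(1))
  expect_true(all(offs <= 2500))
})

test_that("fork_rate_asymmetry is symmetric under mirroring", {
  pk <- data.frame(left_slope = 2e-6, right_slope = -4e-6)
  fa <- fork_rate_asymmetry(pk)
  expect_equal(fa$fold, 2)
  expect_equal(fa$shallow_flank, "left")
  mirrored <- data.frame(left_slope = 4e-6, right_slope = -2e-6)
  fm <- fork_rate_asymmetry(mirrored)
  expect_equal(fm$fold, fa$fold)
  expect_equal(fm$shallow_flank, "right")
  expect_equal(fork_rate_asymmetry(
    data.frame(left_slope = 3e-6, right_slope = -3e-6))$fold, 1)
  expect_true(is.na(fork_rate_asymmetry(
    data.frame(left_slope = 0, right_slope = -3e-6))$fold))
})

test_that("replicated_fraction scores elevated bins against baseline", {
  r <- data.frame(chromosome = "1",
                  start = seq(0, by = 2500, length.out = 100),
                  end = seq(2500, by = 2500, length.out = 100),
                  ratio = rep(c(1.8, 1.0), each = 50),
                  low_quality = FALSE)
  expect_equal(replicated_fraction(r, threshold = 0.2)$fraction, 0.5)
  flat <- r; flat$ratio <- 1
  expect_equal(replicated_fraction(flat, threshold = 0.2)$fraction, 0)
  # monotone non-increasing in threshold
  set.seed(5)
  r$ratio <- 1 + abs(rnorm(100, 0, 0.3))
  fr <- vapply(c(0.1, 0.3, 0.6),
               function(th) replicated_fraction(r, threshold = th)$fraction,
               numeric(1))
  expect_true(all(diff(fr) <= 0))
})

test_that("per-class replicated composition follows the annotation", {
  track <- data.frame(chromosome = "1", start = c(0, 125000),
                      end = c(125000, 250000),
                      class = c("core", "subtelomere"))
  r <- data.frame(chromosome = "1",
                  start = seq(0, by = 2500, length.out = 100),
                  end = seq(2500, by = 2500, length.out = 100),
                  ratio = c(rep(1.8, 40), rep(1, 60)),
                  low_quality = FALSE)
  out <- replicated_fraction(r, track, threshold = 0.2)
  expect_equal(unname(out$by_class["core"]), 0.8)
  expect_equal(unname(out$by_class["subtelomere"]), 0)
  expect_equal(unname(out$composition[["core"]]), 1)
})

test_that("origin density scales observed peaks by the analyzed fraction", {
  # printed arithmetic: 25.7 Mbp per 100 origins is ~260 kb per origin
  d <- origin_density_and_extrapolation(c(50, 30, 20),
                                        c(12e6, 8.5e6, 5.2e6),
                                        analyzed_fraction = 1)
  expect_equal(d$predicted_origins, 100)
  expect_equal(d$density_bp / 1000, 257, tolerance = 0.001)
  # regression through the origin recovers a fixed per-Mbp rate
  lens <- c(2e6, 4e6, 6e6, 8e6)
  rate <- 2.5e-6                           # origins per bp
  set.seed(6)
  counts <- round(lens * rate + rnorm(4, 0, 0.3))
  fit <- origin_density_and_extrapolation(counts, lens,
                                          analyzed_fraction = 0.5)
  expect_lt(abs(fit$slope_per_bp - rate) / rate, 0.1)
  expect_gt(fit$correlation, 0.95)
  single <- origin_density_and_extrapolation(5, 2e6)
  expect_true(is.na(single$slope_per_bp))
})

test_that("peak/feature colocalization respects the bin tolerance", {
  pk <- data.frame(chromosome = "1", center = c(100000, 500000),
                   amplitude = c(0.5, 0.9))
  feats <- data.frame(chromosome = "1", start = c(99000, 499000),
                      end = c(101000, 501000))
  r <- colocalize_peaks_with_features(pk, feats)
  expect_equal(r$n_matched, 2)
  shifted <- feats
  shifted$start <- shifted$start + 25000
  shifted$end <- shifted$end + 25000
  expect_equal(colocalize_peaks_with_features(pk, shifted)$n_matched, 0)
  top <- colocalize_peaks_with_features(pk, feats,
                                        ranked_features = feats[2, ])
  expect_true(all(top$top_ranked_matched))
})
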