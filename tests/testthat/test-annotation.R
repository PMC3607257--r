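test_that("gene_records validates and sorts", {
  g <- gene_records("a", "1", 10, 20, "+", "ordinary")
  expect_equal(nrow(g), 1)
  expect_error(gene_records("a", "1", 20, 10, "+", "ordinary"))
  expect_error(gene_records("a", "1", 10, 20, "+", "nonsense"))
  g2 <- gene_records(c("b", "a"), "1", c(50, 10), c(60, 20), "+",
                     "ordinary")
  expect_equal(g2$gene_id, c("a", "b"))
})

test_that("all-ordinary chromosome demarcates to a single core interval", {
  g <- gene_records(paste0("g", 1:3), "1", c(100, 500, 900),
                    c(300, 700, 1100), "+", "ordinary")
  tr <- demarcate_chromosome(g, 2000)
  expect_equal(nrow(tr), 1)
  expect_equal(tr$class, "core")
  expect_equal(tr$start, 0)
  expect_equal(tr$end, 2000)
})

test_that("arm scan yields array | subtelomere | core on each arm", {
  tr <- demarcate_chromosome(toy_arm_genes(), 26000)
  expect_equal(tr$class, c("vsg_array", "subtelomere", "core",
                           "subtelomere", "vsg_array"))
  # boundaries at midpoints of the inter-gene gaps at class changes
  expect_equal(tr$start, c(0, 4000, 9000, 16000, 21000))
  expect_equal(tr$end, c(4000, 9000, 16000, 21000, 26000))
  # joint cover of [0, L)
  expect_equal(sum(tr$end - tr$start), 26000)
})

test_that("internal runs of subtelomeric genes become subtelomere islands", {
  g <- gene_records(
    paste0("g", 1:8), "1",
    start = seq(0, 1400, by = 200), end = seq(100, 1500, by = 200),
    strand = "+",
    category = c("ordinary", "ordinary", "RHS", "RHS", "RHS",
                 "ordinary", "ordinary", "ordinary"))
  tr <- demarcate_chromosome(g, 1600)
  expect_equal(tr$class, c("core", "subtelomere", "core"))
  # a lone RHS is absorbed into the core (below the island minimum)
  g$category[4:5] <- "ordinary"
  tr2 <- demarcate_chromosome(g, 1600)
  expect_equal(tr2$class, "core")
})

test_that("demarcation rejects unsorted input and flags empty input", {
  g <- toy_arm_genes()
  expect_error(demarcate_chromosome(g[c(2, 1), ], 26000), "sorted")
  d <- demarcate_chromosome(g[0, ], 26000)
  expect_true(attr(d, "degenerate"))
  expect_equal(d$end - d$start, 0)
})

test_that("hypothetical and ESAG3 genes carry no class vote", {
  g <- toy_arm_genes()
  extra <- gene_records(c("h1", "e3"), "t", c(15500, 16200),
                        c(15800, 16600), "+", c("hypothetical", "ESAG3"))
  g2 <- rbind(g, extra)
  g2 <- g2[order(g2$start), ]
  tr <- demarcate_chromosome(g2, 26000)
  expect_equal(tr$class, c("vsg_array", "subtelomere", "core",
                           "subtelomere", "vsg_array"))
  expect_equal(tr$start, c(0, 4000, 9000, 16000, 21000))
})

test_that("build_dgcs partitions genes into maximal same-strand runs", {
  mk <- function(strands) {
    n <- length(strands)
    gene_records(paste0("g", seq_len(n)), "1",
                 start = seq(0, by = 1000, length.out = n),
                 end = seq(500, by = 1000, length.out = n),
                 strand = strands, category = "ordinary")
  }
  one <- build_dgcs(mk(c("+", "+", "+")))
  expect_equal(nrow(one), 1)
  expect_equal(one$strand, "+")
  expect_equal(one$n_genes, 3L)

  five <- build_dgcs(mk(c("-", "-", "+", "+", "-")))
  expect_equal(nrow(five), 3)
  expect_equal(five$strand, c("-", "+", "-"))
  expect_equal(five$n_genes, c(2L, 2L, 1L))

  empty <- gene_records(character(0), character(0), numeric(0),
                        numeric(0), character(0), character(0))
  expect_equal(nrow(build_dgcs(empty)), 0)

  # membership: concatenating member lists reproduces gene order
  g <- mk(c("-", "-", "+", "-", "-", "+", "+"))
  d <- build_dgcs(g)
  expect_equal(unlist(strsplit(d$gene_ids, ",")), g$gene_id)
})

test_that("classify_ssrs types gaps by flanking strands", {
  mk_dgcs <- function(strands) {
    n <- length(strands)
    data.frame(chromosome = "1",
               start = seq(0, by = 10000, length.out = n),
               end = seq(6000, by = 10000, length.out = n),
               strand = strands, stringsAsFactors = FALSE)
  }
  expect_equal(classify_ssrs(mk_dgcs(c("-", "+")))$ssr_type, "divergent")
  expect_equal(classify_ssrs(mk_dgcs(c("+", "-")))$ssr_type, "convergent")
  # (+ + | - - | + +) as three clusters: convergent then divergent
  s <- classify_ssrs(mk_dgcs(c("+", "-", "+")))
  expect_equal(s$ssr_type, c("convergent", "divergent"))
  expect_equal(s$start, c(6000, 16000))
  expect_equal(s$end, c(10000, 20000))
  expect_equal(nrow(classify_ssrs(mk_dgcs(c("+", "+")))), 0)
  bad <- mk_dgcs(c("+", "-")); bad$start[2] <- 3000
  expect_error(classify_ssrs(bad), "overlap")
})

test_that("SSR counts are invariant under coordinate mirroring", {
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(4:9, 1)
    strands <- sample(c("+", "-"), n, replace = TRUE)
    d <- data.frame(chromosome = "1",
                    start = seq(0, by = 10000, length.out = n),
                    end = seq(6000, by = 10000, length.out = n),
                    strand = strands, stringsAsFactors = FALSE)
    s <- classify_ssrs(d)
    L <- max(d$end) + 1000
    m <- data.frame(chromosome = "1", start = L - d$end, end = L - d$start,
                    strand = ifelse(d$strand == "+", "-", "+"),
                    stringsAsFactors = FALSE)
    m <- m[order(m$start), ]
    sm <- classify_ssrs(m)
    expect_equal(nrow(sm), nrow(s))
    for (tp in c("divergent", "convergent"))
      expect_equal(sum(sm$ssr_type == tp), sum(s$ssr_type == tp))
  }
})

test_that("parse_vsg_cassettes anchors cassettes at 70 bp repeats", {
  arr <- list(start = 0, end = 10000)
  feats <- data.frame(start = c(0, 1000), end = c(300, 2500),
                      type = c("repeat_70bp", "vsg_orf"),
                      stringsAsFactors = FALSE)
  cas <- parse_vsg_cassettes(arr, feats)
  expect_equal(nrow(cas), 1)
  expect_equal(cas$flank5_start, 300)
  expect_equal(cas$flank5_end, 1000)
  expect_equal(cas$flank3_start, 2500)
  expect_equal(cas$flank3_end, 10000)   # runs to the array boundary

  feats2 <- data.frame(start = c(0, 1000, 5000, 6000),
                       end = c(300, 2500, 5300, 7500),
                       type = rep(c("repeat_70bp", "vsg_orf"), 2),
                       stringsAsFactors = FALSE)
  cas2 <- parse_vsg_cassettes(arr, feats2)
  expect_equal(nrow(cas2), 2)
  expect_equal(cas2$flank3_end[1], 5000)  # abuts the next repeat
  # components within a cassette are ordered and disjoint
  expect_true(all(cas2$repeat_end <= cas2$flank5_start))
  expect_true(all(cas2$flank5_end <= cas2$orf_start))
  expect_true(all(cas2$orf_end <= cas2$flank3_start))

  # repeat with no downstream ORF is emitted flagged
  feats3 <- data.frame(start = 0, end = 300, type = "repeat_70bp",
                       stringsAsFactors = FALSE)
  expect_true(parse_vsg_cassettes(arr, feats3)$flagged)
})

test_that("synthetic arrays recover designed cassette component shares", {
  cfg <- sim_config(seed = 5, chromosomes = c("1" = 6e5))
  g <- generate_genome(cfg)
  reps <- g$repeats[g$repeats$chromosome == "1", ]
  vsg <- g$genes[g$genes$category == "VSG" & g$genes$chromosome == "1", ]
  orfs <- data.frame(start = vsg$start, end = vsg$end, type = "vsg_orf")
  feats <- rbind(reps[, c("start", "end", "type")], orfs)
  arr <- g$truth$region_classes[g$truth$region_classes$class == "vsg_array" &
                                g$truth$region_classes$chromosome == "1", ]
  cas <- parse_vsg_cassettes(list(start = arr$start[1], end = arr$end[1]),
                             feats[feats$start < arr$end[1], ])
  sh <- cassette_component_shares(cas)
  expect_lt(abs(sh[["flank_5p"]] - 0.40), 0.02)
  expect_lt(abs(sh[["vsg_orf"]] - 0.50), 0.02)
})

test_that("at_content_by_class computes percent AT over labelled intervals", {
  seqs <- Biostrings::DNAStringSet(c(chrA = paste(rep("AT", 500),
                                                  collapse = ""),
                                     chrB = paste(rep("ACGT", 250),
                                                  collapse = "")))
  reg <- data.frame(chromosome = c("chrA", "chrB"), start = 0,
                    end = 1000, label = c("x", "y"))
  tab <- at_content_by_class(seqs, reg)
  expect_equal(tab$percent_at[tab$label == "x"], 100)
  expect_equal(tab$percent_at[tab$label == "y"], 50)
  reg$end <- 2000
  expect_error(at_content_by_class(seqs, reg), "outside")
})

test_that("generated sequences carry class-specific AT content", {
  cfg <- sim_config(seed = 9, chromosomes = c("1" = 6e5))
  g <- generate_genome(cfg, emit_sequence = TRUE)
  tr <- g$truth$region_classes
  tr$label <- tr$class
  tab <- at_content_by_class(g$sequence, tr)
  for (cl in c("core", "subtelomere", "vsg_array")) {
    want <- 100 * cfg$at_content[[cl]]
    got <- tab$percent_at[tab$label == cl]
    expect_lt(abs(got - want), 1)
  }
})

test_that("demarcation covers generated chromosomes exactly once", {
  cfg <- sim_config(seed = 3, chromosomes = c("1" = 5e5, "2" = 4.5e5))
  g <- generate_genome(cfg)
  for (ch in names(cfg$chromosomes)) {
    tr <- demarcate_chromosome(
      g$genes[g$genes$chromosome == ch, ], cfg$chromosomes[[ch]])
    expect_equal(tr$start[1], 0)
    expect_equal(tr$end[nrow(tr)], unname(cfg$chromosomes[[ch]]))
    expect_true(all(tr$start[-1] == tr$end[-nrow(tr)]))
    expect_true(all(tr$class[-1] != tr$class[-nrow(tr)]))
  }
})
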