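test_that("loci are partitioned into anchored fixed-width windows", {
  d1 <- tiny_design(30, spacing = 100)          # locus [0, 3000)
  r1 <- partition_regions(d1, width = 1000)
  expect_equal(nrow(r1), 3)
  expect_equal(r1$start, c(0L, 1000L, 2000L))
  expect_equal(r1$n_probes, rep(10L, 3))        # 100-bp spacing, 1000-bp regions
  expect_true(all(r1$testable))

  d2 <- tiny_design(25, spacing = 100)          # locus [0, 2500)
  r2 <- partition_regions(d2, width = 1000)
  expect_equal(nrow(r2), 3)
  expect_equal(r2$start[3], 2000L)
  expect_equal(r2$end[3], 2500L)                # truncated final window
  expect_equal(r2$n_probes[3], 5L)

  expect_error(partition_regions(d1, width = 0), "positive")
})

test_that("regions with too few probes are untestable", {
  d <- tiny_design(12, spacing = 500)           # locus [0, 6000), 2 probes/kb
  r <- partition_regions(d, width = 1000, min_probes = 3)
  expect_false(any(r$testable))
  r2 <- partition_regions(d, width = 1000, min_probes = 2)
  expect_true(all(r2$testable))
})

test_that("rank-sum enrichment reproduces the exact worked case", {
  set.seed(1)
  bg <- runif(7)                                 # all below the region scores
  res <- region_rank_sum(c(3.1, 3.4, 2.9), bg)
  expect_equal(res$p_up, 1 / choose(10, 3))      # 1/120
  expect_equal(res$p, 2 / 120)
  expect_equal(res$direction, "up")

  # all scores tied -> no enrichment either way
  tied <- region_rank_sum(rep(2, 3), rep(2, 7))
  expect_equal(tied$p, 1)

  # negating scores flips direction, combined p unchanged
  neg <- region_rank_sum(-c(3.1, 3.4, 2.9), -bg)
  expect_equal(neg$p, res$p)
  expect_equal(neg$direction, "down")
})

test_that("exact rank-sum equals brute-force enumeration up to 12 probes", {
  set.seed(77)
  for (n in 4:12) {
    for (k in 1:(n - 1)) {
      scores <- rnorm(n)
      if (n %% 2 == 0) scores[sample(n, 2)] <- scores[1]  # force ties
      res <- region_rank_sum(scores[1:k], scores[(k + 1):n])
      ref <- brute_rank_sum(scores[1:k], scores[(k + 1):n])
      expect_equal(res$p_up, ref$p_up, tolerance = 1e-12)
      expect_equal(res$p_down, ref$p_down, tolerance = 1e-12)
    }
  }
})

test_that("exact rank-sum matches wilcox.test on untied inputs", {
  set.seed(8)
  for (i in 1:10) {
    x <- rnorm(6); y <- rnorm(9)
    res <- region_rank_sum(x, y)
    ref_up <- wilcox.test(x, y, alternative = "greater",
                          exact = TRUE)$p.value
    ref_down <- wilcox.test(x, y, alternative = "less",
                            exact = TRUE)$p.value
    expect_equal(res$p_up, ref_up, tolerance = 1e-12)
    expect_equal(res$p_down, ref_down, tolerance = 1e-12)
  }
})

test_that("the normal approximation is close to exact near the boundary", {
  set.seed(9)
  x <- rnorm(10, 1); y <- rnorm(15)
  exact <- region_rank_sum(x, y, exact_max = 25)
  approx <- region_rank_sum(x, y, exact_max = 10)
  expect_equal(approx$p, exact$p, tolerance = 0.05)
  expect_equal(approx$direction, exact$direction)
})

test_that("BH adjustment matches the hand case and a brute-force reference", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(21)
  for (i in 1:25) {
    p <- runif(sample(1:50, 1))
    if (i %% 3 == 0 && length(p) > 1) p[2] <- p[1]   # ties
    expect_equal(bh_fdr(p), brute_bh(p), tolerance = 1e-12)
  }
})

test_that("BH output is monotone on sorted input", {
  set.seed(4)
  p <- sort(runif(40))
  q <- bh_fdr(p)
  expect_true(all(diff(q) >= -1e-12))
})

test_that("region calls obey the dual probe/region thresholds", {
  # one locus, 30 probes, 3 regions; region 1 strongly shifted up
  design <- tiny_design(30)
  stats <- data.frame(probe_id = design$probe_id,
                      t_mod = c(rep(5, 10), rnorm(20, 0, 0.5)),
                      lfc = c(rep(0.8, 10), rnorm(20, 0, 0.05)),
                      p_t = c(rep(1e-4, 10), runif(20, 0.2, 1)),
                      stringsAsFactors = FALSE)
  regions <- partition_regions(design, 1000)
  calls <- call_regions(stats, regions, calling_thresholds())
  expect_true(calls$called[1])
  expect_equal(calls$direction[1], "higher_in_A")
  expect_gte(calls$n_sig_probes[1], 1)

  # an FDR ceiling below the achieved q removes the call
  strict <- calling_thresholds(region_fdr_max = calls$q_region[1] / 2)
  expect_false(call_regions(stats, regions, strict)$called[1])

  # without a probe passing the lfc floor the region is not called
  weak <- stats
  weak$lfc[1:10] <- 0.10
  expect_false(call_regions(weak, regions, calling_thresholds())$called[1])

  # an opposite-sign probe cannot carry the call
  flipped <- stats
  flipped$lfc[1:10] <- -0.8
  expect_false(call_regions(flipped, regions,
                            calling_thresholds())$called[1])
})

test_that("raising the FDR ceiling never removes a called region", {
  set.seed(33)
  design <- tiny_design(60)
  stats <- data.frame(probe_id = design$probe_id,
                      t_mod = rnorm(60) + rep(c(2, 0, 0, -2, 0, 0), each = 10),
                      lfc = rnorm(60, 0, 0.4),
                      p_t = runif(60), stringsAsFactors = FALSE)
  regions <- partition_regions(design, 1000)
  lo <- call_regions(stats, regions, calling_thresholds(region_fdr_max = 0.1))
  hi <- call_regions(stats, regions, calling_thresholds(region_fdr_max = 0.2))
  expect_true(all(!lo$called | hi$called))
})

test_that("calls are invariant to locus relabeling and probe order", {
  set.seed(41)
  design <- tiny_design(30)
  stats <- data.frame(probe_id = design$probe_id,
                      t_mod = rnorm(30), lfc = rnorm(30, 0, 0.3),
                      p_t = runif(30), stringsAsFactors = FALSE)
  base <- call_regions(stats, partition_regions(design, 1000),
                       calling_thresholds())

  relabeled <- design
  relabeled$locus_id <- "renamed"
  re <- call_regions(stats, partition_regions(relabeled, 1000),
                     calling_thresholds())
  expect_equal(re$p_region, base$p_region)
  expect_equal(re$called, base$called)

  perm <- sample(30)
  shuffled <- call_regions(stats[perm, ],
                           partition_regions(design[perm, ], 1000),
                           calling_thresholds())
  expect_equal(shuffled$p_region, base$p_region)
  expect_equal(shuffled$called, base$called)
})

test_that("the contrast pipeline recovers a planted DMR with its direction", {
  planted <- planted_dmr("locusA", 4000, 5000, 1.0, "dmr1")
  spec <- tiny_spec(seed = 99, planted = planted)
  sim <- simulate_cohort(spec)
  m <- normalize_arrays(sim$intensities, sim$truth$design, sim$samples,
                        "T_cell")
  calls <- run_contrast_pipeline(m, sim$truth$design)
  hit <- calls[calls$start < sim$truth$planted$end &
                 calls$end > sim$truth$planted$start, ]
  expect_true(any(hit$called))
  expect_true(all(hit$direction[hit$called] == "higher_in_A"))
})

test_that("the correlation pipeline recovers a phenotype-linked region", {
  planted <- planted_dmr("locusA", 4000, 5000, 1.0, "dmr1")
  links <- phenotype_link("dmr1", slope = 1, intercept = 10,
                          noise_sd = 0.05, analyte = "IL1A")
  spec <- tiny_spec(seed = 123, planted = planted, links = links)
  sim <- simulate_cohort(spec)
  ph <- simulate_phenotype(sim$truth)
  m <- normalize_arrays(sim$intensities, sim$truth$design, sim$samples,
                        "T_cell")
  calls <- run_correlation_pipeline(m, sim$truth$design, ph, "IL1A")
  hit <- calls[calls$start < sim$truth$planted$end &
                 calls$end > sim$truth$planted$start, ]
  expect_true(any(hit$called))
  expect_true(all(hit$direction[hit$called] == "positive"))
})
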