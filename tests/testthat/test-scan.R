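test_that("extreme-SNP flags: strict boundaries, degenerate spreads, tail rate", {
  expect_false(flag_extreme(c(2.0, rep(0, 200)), "ihs")[1])  # strict >
  expect_true(flag_extreme(c(2.0001, rep(0, 200)), "ihs")[1])
  # constant XP scores: nothing exceeds the percentile
  expect_false(any(flag_extreme(rep(1.3, 500), "xpehh")))
  expect_error(flag_extreme(rnorm(50), "xpehh"), "at least 100")
  set.seed(7)
  z <- rnorm(1e5)
  rate <- mean(flag_extreme(z, "ihs"))
  expect_lt(abs(rate - 0.0455), 0.004)
  # XP percentile flags ~1% by construction
  expect_lt(abs(mean(flag_extreme(z, "xpehh")) - 0.01), 0.003)
})

test_that("window outliers: construction, tie handling, min_snps filter", {
  grid <- make_windows(c(s = 1e6), 1e3, 1e3)  # 1000 windows
  set.seed(1)
  snps <- data.frame(scaffold_id = "s",
                     position = rep(1:1000, each = 10) * 1000 - 500 +
                       rep(seq(10, 910, length.out = 10), 1000),
                     scored = TRUE, flagged = FALSE)
  snps$position <- as.integer((rep(0:999, each = 10)) * 1000 +
                                rep(seq(50, 950, 100), 1000))
  # one window fully flagged among 999 empty ones
  snps$flagged[snps$position > 4000 & snps$position <= 5000] <- TRUE
  out <- window_outliers(snps, grid, min_snps = 10)
  expect_equal(sum(out$candidate), 1)
  expect_equal(out$start[out$candidate], 4000)

  # all windows identical positive proportion: ties at the threshold
  # include all; identical zero proportion flags none
  snps$flagged <- TRUE
  out2 <- window_outliers(snps, grid, min_snps = 10)
  expect_true(all(out2$candidate))
  snps$flagged <- FALSE
  out2b <- window_outliers(snps, grid, min_snps = 10)
  expect_false(any(out2b$candidate))

  # windows below min_snps are excluded before ranking
  snps2 <- snps[snps$position <= 5000, ]
  out3 <- window_outliers(snps2, grid, min_snps = 10)
  expect_equal(nrow(out3), 5)
  expect_error(window_outliers(snps, grid[0, ]), "empty")
})

test_that("combining candidates applies the iHS uniqueness rule only", {
  cand <- data.frame(
    scaffold_id = "s",
    start = c(0, 0, 5e4, 1e5, 1e5),
    end = c(5e4, 5e4, 1e5, 1.5e5, 1.5e5),
    pop = c("IN", "NO", "IN", "IN", "IN"),
    statistic = c("ihs", "ihs", "ihs", "ihs", "xpehh"),
    prop = c(0.5, 0.4, 0.3, 0.6, 0.2))
  out <- combine_and_filter(cand)
  # window 0-50k: iHS-candidate in two pops -> dropped in both
  expect_false(any(out$start == 0))
  # window 50-100k: iHS in one pop only -> kept
  expect_true(any(out$start == 5e4 & out$pop == "IN"))
  # window 100-150k: iHS + XP-EHH both retained
  w3 <- out[out$start == 1e5, ]
  expect_equal(w3$stats, "ihs,xpehh")
  expect_equal(w3$n_stats, 2)

  # disjoint candidate sets across pops: output size = sum of inputs
  cand2 <- data.frame(scaffold_id = "s", start = c(0, 5e4),
                      end = c(5e4, 1e5), pop = c("IN", "NO"),
                      statistic = "xpehh", prop = 0.1)
  expect_equal(nrow(combine_and_filter(cand2)), 2)
})

test_that("PBS threshold is the type-1 empirical quantile of neutral values", {
  expect_equal(calibrate_pbs_threshold(rep(0, 2e4), "IN")$threshold, 0)
  set.seed(11)
  vals <- rnorm(1e4)  # any 1e4+ values
  vals <- c(vals, rnorm(2e4))
  th <- calibrate_pbs_threshold(vals, "IN", fpr = 0.01)
  expect_equal(th$threshold, sort(vals)[ceiling(0.99 * length(vals))])
  expect_lte(mean(vals > th$threshold), 0.01)
  expect_error(calibrate_pbs_threshold(rnorm(100), "IN"), "at least")

  # a frozen 1000-value case: threshold = 990th order statistic
  set.seed(2)
  v2 <- runif(1000)
  th2 <- calibrate_pbs_threshold(v2, "IN", fpr = 0.01, min_snps = 1000)
  expect_equal(th2$threshold, sort(v2)[990])
})

test_that("PBS overlap marks windows containing significant SNPs", {
  regions <- combine_and_filter(data.frame(
    scaffold_id = "s", start = c(0, 5e4), end = c(5e4, 1e5),
    pop = "IN", statistic = "xpehh", prop = 0.2))
  pbs_snps <- data.frame(scaffold_id = "s",
                         position = c(1e4, 2e4, 7e4),
                         pbs_IN = c(0.2, 0.5, 0.1))
  out <- pbs_overlap(regions, pbs_snps, c(IN = 0.4))
  expect_equal(out$pbs_overlap, c(TRUE, FALSE))
  expect_equal(out$pbs_max, c(0.5, 0.1))
  # threshold zero: any window with a positive-PBS SNP overlaps
  out2 <- pbs_overlap(regions, pbs_snps, c(IN = 0))
  expect_true(all(out2$pbs_overlap))
  expect_error(pbs_overlap(regions, pbs_snps, c(NO = 1)),
               "missing PBS threshold")
})

test_that("the scan is invariant to sample-order permutation", {
  m <- demography_imc_scaled(scale = 100, L = 2e5)
  r <- wf_simulate(m, n_per_pop = 10, seed = 60)
  p <- r$panels[[1]]
  grid <- make_windows(c(scaffold_1 = 2e5), 5e4)
  s1 <- sweep_scan(p, c("IN", "NO", "SO"), grid, min_snps = 5)
  set.seed(4)
  perm <- sample(length(p$sample_ids))
  rows <- as.vector(rbind(2 * perm - 1, 2 * perm))
  p2 <- haplotype_panel(p$scaffold_id, p$positions, p$hap_matrix[rows, ],
                        p$sample_ids[perm], p$pop_labels[perm],
                        polarized = TRUE)
  s2 <- sweep_scan(p2, c("IN", "NO", "SO"), grid, min_snps = 5)
  expect_equal(s1$regions$start, s2$regions$start)
  expect_equal(s1$regions$pop, s2$regions$pop)
  expect_equal(s1$regions$stats, s2$regions$stats)
})
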