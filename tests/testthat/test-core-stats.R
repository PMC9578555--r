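test_that("Hudson Fst matches the closed-form examples", {
  # equal frequencies and sizes: numerator is the small negative -2p(1-p)/(n-1)
  h <- hudson_fst(10, 50, 10, 50)
  expect_equal(h$numerator, -2 * 0.2 * 0.8 / 49)
  expect_lt(h$fst, 0)
  # fixed difference: ratio exactly 1
  h2 <- hudson_fst(0, 20, 20, 20)
  expect_equal(h2$fst, 1)
  h3 <- hudson_fst(0, 8, 8, 8)
  expect_equal(h3$fst, 1)
  # worked case: n1 = n2 = 50 alleles, derived 10 vs 40
  h4 <- hudson_fst(10, 50, 40, 50)
  expect_equal(h4$numerator, 0.3534694, tolerance = 1e-6)
  expect_equal(h4$denominator, 0.68)
  expect_equal(h4$fst, 0.5198, tolerance = 1e-4)
})

test_that("Hudson components agree with pair-enumeration oracle to 1e-12", {
  for (seed in 1:5) {
    hm <- rand_hap(20, 15, seed = seed, p = runif(1, 0.2, 0.7))
    c1 <- hm[1:12, ]; c2 <- hm[13:20, ]
    h <- hudson_fst(colSums(c1), rep(12, 15), colSums(c2), rep(8, 15))
    for (s in 1:15) {
      o <- bf_hudson_site(c1[, s], c2[, s])
      expect_equal(h$numerator[s], unname(o["num"]), tolerance = 1e-12)
      expect_equal(h$denominator[s], unname(o["den"]), tolerance = 1e-12)
    }
  }
})

test_that("PBS reproduces hand-derived values and its algebraic identities", {
  expect_equal(pbs(0, 0, 0)$pbs_a, 0)
  # the genome-wide pairwise divergence configuration: two branches at 0.02,
  # the offshore pair at 0.007
  p <- pbs(0.02, 0.02, 0.007)
  expect_equal(p$pbs_a, 0.016690399849, tolerance = 1e-6)
  set.seed(42)
  f <- matrix(runif(300, 0, 0.9), ncol = 3)
  pr <- pbs(f[, 1], f[, 2], f[, 3])
  expect_equal(pr$pbs_a + pr$pbs_b + pr$pbs_c,
               (pr$T_ab + pr$T_ac + pr$T_bc) / 2, tolerance = 1e-12)
  # focal branch invariant under relabeling of the two non-focal pops
  pr2 <- pbs(f[, 2], f[, 1], f[, 3])
  expect_equal(pr$pbs_a, pr2$pbs_a, tolerance = 1e-12)
  # Fst at 1 flags an infinite branch, never silently
  expect_true(is.infinite(pbs(1, 0.1, 0.1)$pbs_a))
  # negative Fst clamped to zero before the log
  expect_equal(pbs(-0.05, 0, 0)$pbs_a, 0)
})

test_that("window diversity: zero variation, Tajima oracle, pi pair oracle", {
  hm <- matrix(0L, nrow = 8, ncol = 5)
  hm[, 3] <- c(1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L)  # monomorphic derived? no:
  hm[, 3] <- 0L                                  # keep all identical
  p <- make_panel(hm, pos = c(10L, 20L, 30L, 40L, 50L),
                  pops = rep(c("A", "B"), each = 2))
  g <- make_windows(c(scf1 = 100), 100)
  wd <- window_diversity(p, grid = g)
  expect_equal(wd$stats$pi, c(0, 0))
  expect_equal(wd$dxy$dxy, 0)

  # n = 4 haplotypes, 3 singletons: theta_W = 3/a1, a1 = 11/6, D ~ -0.754
  expect_equal(tajima_d(3, 4, 3 * 2 * 0.25 * 0.75 * 4 / 3),
               -0.754451077653, tolerance = 1e-9)

  # windowed pi equals the brute-force mean pairwise difference
  hm2 <- rand_hap(12, 30, seed = 4)
  p2 <- make_panel(hm2, pos = seq_len(30) * 10L,
                   pops = rep("A", 6))
  g2 <- make_windows(c(scf1 = 300), 300)
  wd2 <- window_diversity(p2, grid = g2)
  expect_equal(wd2$stats$pi * 300, bf_pi_sum(hm2), tolerance = 1e-10)
})

test_that("windows failing the callable filter are flagged", {
  hm <- rand_hap(8, 10, seed = 2)
  p <- make_panel(hm, pos = as.integer(seq(5, 95, by = 10)))
  g <- make_windows(c(scf1 = 100), 50, 50)
  cal <- data.frame(start = 0, end = 60)  # second window only 20% callable
  wd <- window_diversity(p, grid = g, callable = cal)
  expect_equal(wd$stats$excluded, c(FALSE, TRUE))
  expect_equal(wd$stats$callable_fraction, c(1, 0.2))
})

test_that("LD decay: perfect linkage, independence level, r2 bounds", {
  hm <- rand_hap(40, 2, seed = 6)
  hm[, 2] <- hm[, 1]  # identical columns
  p <- make_panel(hm, pos = c(100L, 200L), pops = rep("A", 20))
  ld <- ld_decay(p, "A", bin_width = 1000)
  expect_equal(ld$mean_r2, 1)

  # independent sites: mean r2 near the 1/n sampling bias level
  set.seed(8)
  hm2 <- matrix(rbinom(100 * 200, 1, 0.5), nrow = 100)
  p2 <- make_panel(hm2, pos = as.integer(seq_len(200) * 7L),
                   pops = rep("A", 50))
  ld2 <- ld_decay(p2, "A", bin_width = 1e4)
  m <- stats::weighted.mean(ld2$mean_r2, ld2$n_pairs)
  expect_lt(abs(m - 1 / 50), 0.015)
})

test_that("inbreeding F: fully homozygous, HWE mean zero, selfed positive", {
  # fully homozygous sample at p = 0.5 sites
  set.seed(3)
  n_s <- 30
  hm <- matrix(rbinom(2 * 20 * n_s, 1, 0.5), nrow = 40)
  hm[1, ] <- hm[2, ]  # sample 1 homozygous everywhere
  p <- make_panel(hm, pops = rep("A", 20))
  f <- inbreeding_f(p, "A")
  expect_equal(f$O_hom[1], f$N_sites[1])
  expect_equal(f$F[1], 1)
  # large HWE panel: mean F near 0
  set.seed(13)
  hm2 <- matrix(rbinom(2 * 60 * 400, 1, 0.4), nrow = 120)
  p2 <- make_panel(hm2, pops = rep("A", 60))
  f2 <- inbreeding_f(p2, "A")
  expect_lt(abs(mean(f2$F)), 0.03)
})

test_that("HBD finds a planted run of homozygosity and nothing in het samples", {
  set.seed(21)
  n_samp <- 12; n_site <- 400
  pos <- as.integer(seq(500, by = 500, length.out = n_site))
  hm <- matrix(rbinom(2 * n_samp * n_site, 1, 0.5), nrow = 2 * n_samp)
  # plant a 100-kb homozygous run in sample 1 (sites 100..299)
  run <- 100:299
  hm[1, run] <- hm[2, run]
  p <- make_panel(hm, pos = pos, pops = rep("A", n_samp))
  res <- hbd_segments(p, "A", len_min = 5e4)
  s1 <- res$segments[res$segments$sample_id == "s01", ]
  expect_equal(nrow(s1), 1)
  planted <- c(pos[100], pos[299])
  overlap <- min(s1$end, planted[2]) - max(s1$start, planted[1] - 1)
  expect_gt(overlap / (planted[2] - planted[1] + 1), 0.8)

  # a fully heterozygous sample yields no segments
  hm2 <- hm
  hm2[3, ] <- 0L; hm2[4, ] <- 1L
  p2 <- make_panel(hm2, pos = pos, pops = rep("A", n_samp))
  res2 <- hbd_segments(p2, "A", len_min = 5e4)
  expect_false("s02" %in% res2$segments$sample_id)
})

test_that("near-privately fixed SNPs follow the strict-absence rule", {
  hm <- matrix(0L, nrow = 12, ncol = 4)
  hm[1:6, 1] <- c(1L, 1L, 1L, 1L, 1L, 1L)   # fixed in focal, absent others
  hm[1:6, 2] <- c(1L, 1L, 1L, 1L, 1L, 0L)   # 5/6 ~ 0.83 < 0.9
  hm[1:6, 3] <- 1L; hm[7, 3] <- 1L          # present in another pop
  hm[1:6, 4] <- c(1L, 1L, 1L, 1L, 1L, 1L)   # another private fixed
  p <- make_panel(hm, pops = c("IN", "IN", "IN", "NO", "NO", "SO"))
  r <- near_fixed_private(p, "IN", freq_min = 0.9)
  expect_equal(r$sites$position, c(100L, 400L))
  p_unpol <- make_panel(hm, pops = c("IN", "IN", "IN", "NO", "NO", "SO"),
                        polarized = FALSE)
  expect_error(near_fixed_private(p_unpol, "IN"), "polarized")
})
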