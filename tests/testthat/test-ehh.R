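test_that("EHH curve: single class, split classes, monotone decay", {
  # all carriers identical over the region -> EHH = 1 everywhere
  hm <- matrix(0L, nrow = 6, ncol = 9)
  hm[, 5] <- c(1L, 1L, 1L, 1L, 0L, 0L)
  p <- make_panel(hm, pops = rep("A", 3))
  cv <- ehh_curve(p, core_index = 5, core_allele = 1)
  expect_true(all(cv$ehh == 1))

  # 5 carriers splitting into classes {2, 3}: EHH = (1 + 3) / 10 = 0.4
  hm2 <- matrix(0L, nrow = 10, ncol = 3)
  hm2[, 2] <- c(rep(1L, 5), rep(0L, 5))
  hm2[1:2, 3] <- 1L  # carriers split 2 vs 3 at the next marker
  p2 <- make_panel(hm2, pops = rep("A", 5))
  cv2 <- ehh_curve(p2, core_index = 2, core_allele = 1,
                   direction = "right")
  expect_equal(cv2$ehh[cv2$position == 300], 0.4)

  # EHH never increases with distance, on random panels; matches oracle
  for (seed in 1:4) {
    hm3 <- rand_hap(12, 20, seed = 30 + seed, p = 0.4)
    hm3[, 10] <- rep(c(1L, 0L), 6)
    p3 <- make_panel(hm3, pops = rep("A", 6))
    cv3 <- ehh_curve(p3, core_index = 10, core_allele = 1)
    right <- cv3$ehh[cv3$position >= 1000]
    left <- rev(cv3$ehh[cv3$position <= 1000])
    expect_true(all(diff(right) <= 1e-12))
    expect_true(all(diff(left) <= 1e-12))
    carriers <- which(hm3[, 10] == 1)
    for (m in c(5, 12, 18))
      expect_equal(cv3$ehh[cv3$position == m * 100],
                   bf_ehh(hm3, carriers, 10, m), tolerance = 1e-12)
  }
  expect_error(ehh_curve(p2, core_index = 1, core_allele = 1),
               "fewer than 2 carriers")
})

test_that("EHH is invariant to haplotype row order", {
  hm <- rand_hap(10, 15, seed = 5, p = 0.5)
  hm[, 8] <- rep(c(1L, 0L), 5)
  p <- make_panel(hm, pops = rep("A", 5))
  cv1 <- ehh_curve(p, 8, 1)
  set.seed(1)
  # permute samples (pairs of rows) to keep the panel structure valid
  perm <- sample(5)
  rows <- as.vector(rbind(2 * perm - 1, 2 * perm))
  p2 <- make_panel(hm[rows, ], pops = rep("A", 5))
  cv2 <- ehh_curve(p2, 8, 1)
  expect_equal(cv1$ehh, cv2$ehh, tolerance = 1e-12)
})

test_that("iHH equals the brute-force trapezoid oracle on small panels", {
  for (seed in 1:6) {
    n_hap <- 10; n_site <- 25
    hm <- rand_hap(n_hap, n_site, seed = 40 + seed, p = 0.45)
    core <- 13
    hm[, core] <- rep(c(1L, 0L), 5)
    pos <- sort(sample(1:5000, n_site))
    p <- make_panel(hm, pos = as.integer(pos), pops = rep("A", 5))
    sc <- within_pop_scan(p, "A", maf_min = 0.05, ehh_cutoff = 0.05,
                          max_extend = 1e6)
    der <- which(hm[, core] == 1); anc <- which(hm[, core] == 0)
    od <- bf_ihh(hm, pos, der, core)
    oa <- bf_ihh(hm, pos, anc, core)
    expect_equal(sc$ihh_d[core], od$ihh, tolerance = 1e-10)
    expect_equal(sc$ihh_a[core], oa$ihh, tolerance = 1e-10)
    expect_equal(sc$status[core] == "ok",
                 od$complete && oa$complete && od$ihh > 0 && oa$ihh > 0)
    # nSL machinery against the per-pair identity-run oracle
    expect_equal(sc$sl_d[core], bf_sl(hm, der, core), tolerance = 1e-10)
    expect_equal(sc$sl_a[core], bf_sl(hm, anc, core), tolerance = 1e-10)
  }
})

test_that("raw iHS is zero under mirror symmetry and positive when derived haplotypes are long", {
  # derived and ancestral carrier sets with identical haplotype structure
  block <- rand_hap(4, 21, seed = 9, p = 0.5)
  hm <- rbind(block, block)
  hm[, 11] <- c(rep(1L, 4), rep(0L, 4))
  p <- make_panel(hm, pos = as.integer(seq_len(21) * 50L),
                  pops = rep("A", 4))
  sc <- within_pop_scan(p, "A", max_extend = 1e6)
  if (sc$status[11] == "ok") expect_equal(sc$ihs_raw[11], 0, tolerance = 1e-12)
  expect_equal(sc$nsl_raw[11], 0, tolerance = 1e-12)

  # identical derived carriers, maximally diverse ancestral carriers:
  # iHH_A < iHH_D so raw iHS = log(iHH_A / iHH_D) < 0 under our convention;
  # the magnitude, not the sign, marks the sweep
  hm2 <- matrix(0L, nrow = 12, ncol = 31)
  set.seed(77)
  hm2[7:12, ] <- matrix(rbinom(6 * 31, 1, 0.5), nrow = 6)
  hm2[, 16] <- c(rep(1L, 6), rep(0L, 6))
  p2 <- make_panel(hm2, pos = as.integer(seq_len(31) * 40L),
                   pops = rep("A", 6))
  sc2 <- within_pop_scan(p2, "A", max_extend = 1e6)
  expect_lt(sc2$nsl_raw[16], 0)
  expect_gt(sc2$sl_d[16], sc2$sl_a[16])
})

test_that("XP-EHH: identity gives zero, swapping pops negates, oracle match", {
  hm <- rand_hap(16, 25, seed = 12, p = 0.4)
  pos <- as.integer(sort(sample(1:4000, 25)))
  # two copies of the same haplotypes labelled as different populations
  p <- make_panel(rbind(hm, hm), pos = pos,
                  pops = rep(c("A", "B"), each = 8))
  x <- cross_pop_scan(p, "A", "B", max_extend = 1e6)
  ok <- x$status == "ok"
  expect_true(any(ok))
  expect_equal(x$xpehh_raw[ok], rep(0, sum(ok)), tolerance = 1e-12)

  hm2 <- rand_hap(20, 25, seed = 13, p = 0.4)
  p2 <- make_panel(hm2, pos = pos, pops = rep(c("A", "B"), each = 5))
  xab <- cross_pop_scan(p2, "A", "B", max_extend = 1e6)
  xba <- cross_pop_scan(p2, "B", "A", max_extend = 1e6)
  ok2 <- xab$status == "ok" & xba$status == "ok"
  expect_equal(xab$xpehh_raw[ok2], -xba$xpehh_raw[ok2], tolerance = 1e-12)
  expect_equal(xab$xpnsl_raw[!is.na(xab$xpnsl_raw)],
               -xba$xpnsl_raw[!is.na(xba$xpnsl_raw)], tolerance = 1e-12)

  # all-haplotype iHH against the brute-force oracle (core homozygosity
  # start, no allele partition)
  rowsA <- 1:10
  core <- 12
  o <- bf_ihh(hm2, pos, rowsA, core, by_core = TRUE)
  expect_equal(xab$ihh_a[core], o$ihh, tolerance = 1e-10)
  expect_equal(xab$sl_a[core], bf_sl(hm2, rowsA, core), tolerance = 1e-10)
})

test_that("bin normalization: unit moments per bin, z-score reduction, tail rate", {
  set.seed(99)
  raw <- rnorm(6000)
  freq <- runif(6000)
  std <- normalize_bins(raw, freq, n_bins = 50)
  bin <- pmin(pmax(ceiling(freq * 50), 1), 50)
  for (b in unique(bin)) {
    v <- std[bin == b]
    v <- v[!is.na(v)]
    if (length(v) >= 20) {
      expect_lt(abs(mean(v)), 0.05)
      expect_true(sd(v) > 0.9 && sd(v) < 1.1)
    }
  }
  # single bin equals the global z-score
  z <- normalize_bins(raw, freq, n_bins = 1)
  expect_equal(z, (raw - mean(raw)) / sd(raw), tolerance = 1e-10)
  # degenerate spread
  expect_warning(normalize_bins(rep(1, 200), runif(200), n_bins = 1),
                 "zero score spread")
})
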