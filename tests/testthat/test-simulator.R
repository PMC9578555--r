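test_that("no mutation means no segregating sites; runs are seed-deterministic", {
  m <- demography_constant(N = 30, mu = 0, rec = 1e-6, L = 1e4)
  r <- wf_simulate(m, n_per_pop = 10, seed = 3)
  expect_equal(ncol(r$panels[[1]]$hap_matrix), 0)

  m2 <- demography_constant(N = 40, L = 2e4)
  a <- wf_simulate(m2, n_per_pop = 10, seed = 9)
  b <- wf_simulate(m2, n_per_pop = 10, seed = 9)
  expect_identical(a$panels[[1]]$hap_matrix, b$panels[[1]]$hap_matrix)
  expect_identical(a$panels[[1]]$positions, b$panels[[1]]$positions)
  c2 <- wf_simulate(m2, n_per_pop = 10, seed = 10)
  expect_false(identical(a$panels[[1]]$hap_matrix, c2$panels[[1]]$hap_matrix))
})

test_that("sample size larger than the deme errors", {
  m <- demography_constant(N = 10, L = 1e4)
  expect_error(wf_simulate(m, n_per_pop = 11, seed = 1), "exceeds")
})

test_that("selection with s = 0 reduces exactly to the neutral path", {
  m <- demography_imc_scaled(scale = 300, L = 5e4)
  sel0 <- selection_spec("IN", s = 0, origin_time = 3,
                         focal_position = 2.5e4,
                         require_establishment = FALSE)
  a <- wf_simulate(m, n_per_pop = 8, seed = 5)
  b <- wf_simulate(m, n_per_pop = 8, selection = sel0, seed = 5)
  expect_identical(a$panels[[1]]$hap_matrix, b$panels[[1]]$hap_matrix)
})

test_that("deep split without migration gives high Fst, per the coalescent expectation", {
  # two demes of size N split t = 4N generations ago: expected
  # Fst ~ t / (t + 2N) = 2/3, so replicate means should clear 0.5
  N <- 40
  m <- demography_split(N = N, T_split = 4 * N, m = 0, L = 4e4)
  fst <- vapply(1:20, function(i) {
    p <- wf_simulate(m, n_per_pop = 10, seed = 100 + i)$panels[[1]]
    ac <- pop_allele_counts(p, c("POP1", "POP2"))
    hudson_fst(ac$derived[, 1], ac$called[, 1],
               ac$derived[, 2], ac$called[, 2])$fst_overall
  }, numeric(1))
  expect_gt(mean(fst), 0.5)
  expect_lt(abs(mean(fst) - 2 / 3), 0.15)
})

test_that("strong migration keeps two demes undifferentiated", {
  N <- 30
  m <- demography_split(N = N, T_split = 4 * N, m = 0.5, L = 4e4)
  fst <- vapply(1:8, function(i) {
    p <- wf_simulate(m, n_per_pop = 10, seed = 200 + i)$panels[[1]]
    ac <- pop_allele_counts(p, c("POP1", "POP2"))
    hudson_fst(ac$derived[, 1], ac$called[, 1],
               ac$derived[, 2], ac$called[, 2])$fst_overall
  }, numeric(1))
  expect_lt(abs(mean(fst)), 0.05)
})

test_that("constant-Ne counterfactual divides the ancestral size equally", {
  m <- demography_imc(N_anc = 1200)
  cm <- constant_n_variant(m)
  sch <- hapsweep:::build_schedule(cm, burn_mult = 8)
  last <- sch$sizes[, ncol(sch$sizes)]
  expect_equal(unname(last[c("IN", "NO", "SO")]), rep(400L, 3))
  # two demes in the middle epoch
  mid_gen <- sch$T_end - m$T_div2 + 2
  expect_equal(unname(sch$sizes[c("ANC", "IN"), mid_gen + 1]),
               rep(600L, 2))
  # idempotence
  expect_identical(constant_n_variant(cm), cm)
})

test_that("folded SFS counts are conserved and match a tiny hand case", {
  hm <- matrix(c(1, 0, 0, 0,   # singleton (count 1)
                 0, 1, 0, 0,   # singleton
                 1, 1, 0, 0),  # doubleton
               nrow = 4, byrow = FALSE)
  p <- make_panel(hm, pops = c("P1", "P1"))
  sfs <- joint_sfs(p, "P1", folded = TRUE)
  expect_equal(unname(sfs[["1"]]), 2)  # two sites at minor count 1
  expect_equal(unname(sfs[["2"]]), 1)  # one site at minor count 2
  expect_equal(sum(sfs), 3)
  expect_error(joint_sfs(p, "NOPE"), "zero samples")

  m <- demography_constant(N = 30, L = 2e4)
  r <- wf_simulate(m, n_per_pop = 6, seed = 77)
  sfs2 <- joint_sfs(r$panels[[1]], "POP1", folded = TRUE)
  expect_equal(sum(sfs2), ncol(r$panels[[1]]$hap_matrix))
})

test_that("established sweeps reach high focal frequency and are recorded", {
  m <- demography_imc_scaled(scale = 100, L = 1e5)
  sel <- selection_spec("IN", s = 0.6, origin_time = m$T_div2 - 1,
                        focal_position = 5e4, mode = "standing",
                        min_freq = 0.8)
  r <- wf_simulate(m, n_per_pop = 10, selection = sel, seed = 31)
  expect_false(is.null(r$sweep_truth))
  expect_gte(r$sweep_truth$freq_IN, 0.8)
  expect_true(r$sweep_truth$position >= 1 &&
                r$sweep_truth$position <= 1e5)
})
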