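test_that("gene-level Fisher enrichment matches hypergeometric enumeration", {
  go <- list(g1 = c("T"), g2 = c("T"), g3 = c("T"), g4 = c("T"),
             g5 = character(0), g6 = "U", g7 = "U", g8 = character(0),
             g9 = character(0), g10 = character(0))
  bg <- paste0("g", 1:10)
  # target = 2 genes both with T, background 10 with 4 carrying T:
  # p = C(4,2)/C(10,2) = 6/45
  r <- gene_enrichment(c("g1", "g2"), bg, go)
  expect_equal(r$p[r$term == "T"], 6 / 45, tolerance = 1e-12)
  # empty target: p = 1 for every term
  r0 <- gene_enrichment(character(0), bg, go)
  expect_true(all(r0$p == 1))
  # a term annotating every background gene cannot be enriched
  go2 <- lapply(bg, function(g) "ALL")
  names(go2) <- bg
  r2 <- gene_enrichment(c("g1", "g2"), bg, go2)
  expect_equal(r2$p, 1)
  expect_error(gene_enrichment("g1", character(0), go), "empty background")
})

test_that("Fisher p equals exhaustive tail sums on all small tables", {
  set.seed(5)
  for (i in 1:200) {
    N <- sample(5:200, 1)
    K <- sample(0:N, 1)
    n <- sample(0:N, 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(hapsweep:::fisher_upper(k, K, N, n),
                 bf_hyper_tail(k, K, N, n), tolerance = 1e-12)
  }
})

test_that("adding a with-term unit to the target never increases p", {
  for (K in c(5, 20)) {
    p_prev <- 1.01
    for (k in 0:K) {
      p <- hapsweep:::fisher_upper(k, K, 100, 30)
      expect_lte(p, p_prev + 1e-15)
      p_prev <- p
    }
  }
})

test_that("region-level enrichment follows the 1-bp overlap rule", {
  grid <- make_windows(c(chr = 1e6), 5e4, 5e4)  # 20 regions
  genes <- GenomicRanges::GRanges("chr",
                                  IRanges::IRanges(c(10, 49990, 210000),
                                                   c(500, 50500, 210500)))
  names(genes) <- c("gA", "gB", "gC")
  go <- list(gA = "T1", gB = "T1", gC = "T2")
  sweeps <- data.frame(scaffold_id = "chr", start = c(0, 200000),
                       end = c(5e4, 250000))
  r <- region_enrichment(sweeps, grid, genes, go)
  # gB spans the boundary at 50000 and annotates both flanking regions
  # regions with T1: [0,50k) via gA+gB, [50k,100k) via gB -> K = 2
  t1 <- r[r$term == "T1", ]
  expect_equal(t1$n_background_with_term, 2)
  expect_equal(t1$n_target_with_term, 1)
  expect_equal(t1$p, bf_hyper_tail(1, 2, 20, 2), tolerance = 1e-12)
  t2 <- r[r$term == "T2", ]
  expect_equal(t2$p, bf_hyper_tail(1, 1, 20, 2), tolerance = 1e-12)

  # sweep regions without annotated genes: p = 1 everywhere
  sweeps2 <- data.frame(scaffold_id = "chr", start = 900000, end = 950000)
  r2 <- region_enrichment(sweeps2, grid, genes, go)
  expect_true(all(r2$p == 1))
  # genes on unknown scaffolds are ignored with a warning
  genes2 <- suppressWarnings(
    c(genes, GenomicRanges::GRanges("chrX", IRanges::IRanges(1, 10))))
  names(genes2)[4] <- "gX"
  expect_warning(region_enrichment(sweeps, grid, genes2, go), "ignored")
})

test_that("a worked region-level tail: 5 of 20 sweeps vs 50 of 1000 regions", {
  p <- hapsweep:::fisher_upper(5, 50, 1000, 20)
  expect_equal(p, bf_hyper_tail(5, 50, 1000, 20), tolerance = 1e-12)
})

test_that("permutation null keeps the sub-0.005 fraction at nominal level", {
  set.seed(31)
  grid <- make_windows(c(chr = 5e6), 5e4, 5e4)  # 100 regions
  n_terms <- 40
  region_terms <- lapply(seq_len(nrow(grid)), function(i)
    paste0("T", which(runif(n_terms) < 0.25)))
  # genes: one per region carrying that region's terms
  genes <- GenomicRanges::GRanges("chr",
                                  IRanges::IRanges(grid$start + 100,
                                                   grid$start + 200))
  names(genes) <- paste0("g", seq_len(nrow(grid)))
  go <- stats::setNames(region_terms, names(genes))
  hits <- 0; total <- 0
  for (perm in 1:40) {
    sw <- grid[sample(nrow(grid), 10), c("scaffold_id", "start", "end")]
    r <- region_enrichment(sw, grid, genes, go)
    hits <- hits + sum(r$p < 0.005)
    total <- total + nrow(r)
  }
  expect_lte(hits / total, 0.005 + 3 * sqrt(0.005 / total))
})

test_that("OBO ancestor propagation expands annotations transitively", {
  obo <- tempfile(fileext = ".obo")
  writeLines(c("format-version: 1.2", "",
               "[Term]", "id: GO:1", "name: root", "",
               "[Term]", "id: GO:2", "is_a: GO:1 ! root", "",
               "[Term]", "id: GO:3", "is_a: GO:2 ! mid"), obo)
  par <- read_obo_parents(obo)
  expect_equal(par[["GO:3"]], "GO:2")
  go <- list(g1 = "GO:3", g2 = "GO:1", g3 = character(0), g4 = "GO:2")
  bg <- paste0("g", 1:4)
  r <- gene_enrichment("g1", bg, go, ontology = par)
  row1 <- r[r$term == "GO:1", ]
  # with propagation, GO:1 annotates g1, g2 and g4
  expect_equal(row1$n_background_with_term, 3)
  expect_equal(row1$n_target_with_term, 1)
  # without propagation GO:1 stays direct-only
  r0 <- gene_enrichment("g1", bg, go)
  expect_equal(r0[r0$term == "GO:1", "n_background_with_term"], 1)
})
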