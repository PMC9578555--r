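#' Hudson's Fst from allele counts
#'
#' Per-site Hudson components follow the two-population estimator
#' numerator = (p1 - p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1),
#' denominator = p1(1-p2) + p2(1-p1), aggregated per window or genome-wide
#' as a ratio of averages (sum of numerators over sum of denominators).
#' Sites with fewer than two called alleles in either population are
#' excluded.  Negative aggregates are reported as computed.
#'
#' @param derived1,called1 per-site derived and called allele counts, pop 1.
#' @param derived2,called2 same for pop 2.
#' @param positions optional 1-based site positions (needed with `grid`).
#' @param grid optional [make_windows()] grid restricted to one scaffold;
#'   when supplied, per-window ratio-of-averages Fst is returned as well.
#' @param scaffold_id scaffold the positions belong to.
#' @return list with per-site `numerator`, `denominator`, `fst` (NA where
#'   the denominator is 0), `fst_overall`, and optionally `windows`.
#' @export
hudson_fst <- function(derived1, called1, derived2, called2,
                       positions = NULL, grid = NULL,
                       scaffold_id = NULL) {
  ok <- called1 >= 2 & called2 >= 2
  if (any(!ok))
    message("hudson_fst: excluded ", sum(!ok),
            " site(s) with fewer than 2 called alleles")
  p1 <- derived1 / called1
  p2 <- derived2 / called2
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (called1 - 1) -
    p2 * (1 - p2) / (called2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  num[!ok] <- NA_real_
  den[!ok] <- NA_real_
  site_fst <- ifelse(!is.na(den) & den > 0, num / den, NA_real_)
  res <- list(numerator = num, denominator = den, fst = site_fst,
              fst_overall = sum(num[ok & den > 0]) / sum(den[ok & den > 0]))
  if (!is.null(grid)) {
    if (is.null(positions)) stop("positions required with a window grid")
    if (is.null(scaffold_id)) scaffold_id <- grid$scaffold_id[1]
    win <- sites_in_windows(grid, scaffold_id, positions)
    g <- grid[grid$scaffold_id == scaffold_id, , drop = FALSE]
    g$fst <- vapply(win, function(ix) {
      ix <- ix[ok[ix] & !is.na(den[ix]) & den[ix] > 0]
      if (!length(ix)) return(NA_real_)
      sum(num[ix]) / sum(den[ix])
    }, numeric(1))
    g$n_snps <- vapply(win, function(ix) sum(ok[ix]), numeric(1))
    res$windows <- g
  }
  res
}

#' Population branch statistic
#'
#' Branch lengths are `T = -log(1 - Fst)` (natural log) per population pair;
#' the focal branch is `PBS_A = (T_AB + T_AC - T_BC) / 2`.  Negative Fst is
#' clamped to 0 before the log; `Fst >= 1` yields an infinite branch and a
#' `+Inf` PBS flag rather than silent truncation.  The three branch values
#' satisfy `PBS_A + PBS_B + PBS_C = (T_AB + T_AC + T_BC) / 2`.
#'
#' @param fst_ab,fst_ac,fst_bc pairwise Fst values (vectors allowed) for
#'   populations A, B and C.
#' @return data frame with `T_ab`, `T_ac`, `T_bc`, `pbs_a`, `pbs_b`, `pbs_c`.
#' @export
pbs <- function(fst_ab, fst_ac, fst_bc) {
  branch <- function(f) {
    f <- pmax(f, 0)
    ifelse(f >= 1, Inf, -log(1 - f))
  }
  t_ab <- branch(fst_ab)
  t_ac <- branch(fst_ac)
  t_bc <- branch(fst_bc)
  data.frame(T_ab = t_ab, T_ac = t_ac, T_bc = t_bc,
             pbs_a = (t_ab + t_ac - t_bc) / 2,
             pbs_b = (t_ab + t_bc - t_ac) / 2,
             pbs_c = (t_ac + t_bc - t_ab) / 2)
}

#' Per-SNP PBS for each population of a three-population panel
#'
#' Convenience wrapper: computes the three pairwise per-site Hudson Fst
#' ratios and the PBS of every branch at every site.
#'
#' @param panel a [haplotype_panel()] containing (at least) three populations.
#' @param pops character vector of exactly three population labels
#'   (A, B, C); the returned `pbs_A` column etc. follow this order.
#' @return data frame with `position` and one PBS column per population.
#' @export
pbs_per_snp <- function(panel, pops) {
  stopifnot(length(pops) == 3)
  ac <- pop_allele_counts(panel, pops)
  f <- function(i, j) {
    h <- hudson_fst(ac$derived[, i], ac$called[, i],
                    ac$derived[, j], ac$called[, j])
    h$fst
  }
  p <- pbs(f(1, 2), f(1, 3), f(2, 3))
  out <- data.frame(position = panel$positions,
                    a = p$pbs_a, b = p$pbs_b, c = p$pbs_c)
  names(out)[2:4] <- paste0("pbs_", pops)
  out
}
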