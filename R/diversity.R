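#' Windowed diversity statistics
#'
#' Per window and population: segregating sites S, nucleotide diversity per
#' callable base (`pi = sum over sites of 2 p (1-p) n/(n-1)` divided by the
#' callable window length), Tajima's D, and for each population pair the
#' absolute divergence per base
#' `d_xy = sum over sites of p1 (1-p2) + p2 (1-p1)` over callable length.
#' Windows whose callable fraction is below `min_callable` are flagged
#' excluded.  Tajima's D uses the standard constants a1, a2, b1, b2, c1, c2,
#' e1, e2 derived from the haplotype count n and S, and is reported missing
#' when `S < 4` or the variance term is not positive.
#'
#' @param panel a [haplotype_panel()].
#' @param pops populations to evaluate (default all).
#' @param grid a [make_windows()] grid covering the panel's scaffold.
#' @param callable optional data frame of callable intervals (`start`,`end`,
#'   0-based half-open) on the panel's scaffold; default all bases callable.
#' @param min_callable exclusion threshold on the callable fraction.
#' @return list of class `window_stat_table` with elements `stats` (per
#'   window x population) and `dxy` (per window x population pair).
#' @export
window_diversity <- function(panel, pops = unique(panel$pop_labels), grid,
                             callable = NULL, min_callable = 0.7) {
  stopifnot(inherits(panel, "haplotype_panel"))
  ac <- pop_allele_counts(panel, pops)
  if (any(ac$called < 2))
    stop("every population needs at least 2 called alleles at every site")
  g <- grid[grid$scaffold_id == panel$scaffold_id, , drop = FALSE]
  if (!nrow(g)) stop("grid contains no windows for ", panel$scaffold_id)
  win <- sites_in_windows(grid, panel$scaffold_id, panel$positions)

  cal_len <- g$end - g$start
  if (!is.null(callable)) {
    ir_w <- IRanges::IRanges(start = g$start + 1, end = g$end)
    ir_c <- IRanges::IRanges(start = callable$start + 1, end = callable$end)
    ir_c <- IRanges::reduce(ir_c)
    ov <- IRanges::findOverlaps(ir_w, ir_c)
    inter <- IRanges::pintersect(ir_w[S4Vectors::queryHits(ov)],
                                 ir_c[S4Vectors::subjectHits(ov)])
    cal_len <- rep(0, nrow(g))
    tab <- tapply(IRanges::width(inter), S4Vectors::queryHits(ov), sum)
    cal_len[as.integer(names(tab))] <- tab
  }
  cal_frac <- cal_len / (g$end - g$start)

  stats <- do.call(rbind, lapply(seq_along(pops), function(i) {
    p <- ac$freq[, i]
    n <- ac$called[, i]
    site_pi <- 2 * p * (1 - p) * n / (n - 1)
    seg <- p > 0 & p < 1
    n_hap <- max(n)
    df <- g[, c("scaffold_id", "start", "end")]
    df$pop <- pops[i]
    df$S <- vapply(win, function(ix) sum(seg[ix]), numeric(1))
    df$n_snps <- vapply(win, length, numeric(1))
    df$pi <- vapply(win, function(ix) sum(site_pi[ix]), numeric(1)) /
      ifelse(cal_len > 0, cal_len, NA)
    # window-level convention: D reported missing below S = 4
    df$tajima_d <- mapply(function(ix, S) {
      if (S < 4) NA_real_ else tajima_d(S, n_hap, sum(site_pi[ix]))
    }, win, df$S)
    df$callable_fraction <- cal_frac
    df$excluded <- cal_frac < min_callable
    df
  }))
  rownames(stats) <- NULL

  pairs <- if (length(pops) >= 2) utils::combn(pops, 2) else
    matrix(character(0), nrow = 2)
  dxy <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    i <- match(pairs[1, k], pops); j <- match(pairs[2, k], pops)
    p1 <- ac$freq[, i]; p2 <- ac$freq[, j]
    site_dxy <- p1 * (1 - p2) + p2 * (1 - p1)
    df <- g[, c("scaffold_id", "start", "end")]
    df$pop1 <- pairs[1, k]; df$pop2 <- pairs[2, k]
    df$dxy <- vapply(win, function(ix) sum(site_dxy[ix]), numeric(1)) /
      ifelse(cal_len > 0, cal_len, NA)
    df$callable_fraction <- cal_frac
    df$excluded <- cal_frac < min_callable
    df
  }))
  if (!is.null(dxy)) rownames(dxy) <- NULL
  structure(list(stats = stats, dxy = dxy), class = "window_stat_table")
}

#' Tajima's D
#'
#' @param S number of segregating sites.
#' @param n number of haplotypes.
#' @param pi_sum sum over sites of `2 p (1-p) n/(n-1)` (mean pairwise
#'   differences).
#' @return D, or NA when `S = 0` or the variance term is not positive.
#' @export
tajima_d <- function(S, n, pi_sum) {
  if (n < 2) stop("Tajima's D needs n >= 2 haplotypes")
  if (is.na(S) || S < 1) return(NA_real_)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  v <- e1 * S + e2 * S * (S - 1)
  if (v <= 0) return(NA_real_)
  (pi_sum - S / a1) / sqrt(v)
}
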