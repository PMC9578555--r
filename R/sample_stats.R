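#' LD decay: binned mean r-squared versus physical distance
#'
#' Computes squared Pearson correlation of 0/1/2 genotype dosages for all
#' site pairs within `max_dist`, on an equal-sized seeded subsample of the
#' population, and averages within distance bins.  Monomorphic sites and
#' pairs with zero variance are skipped.
#'
#' @param panel a [haplotype_panel()].
#' @param pop population label.
#' @param max_dist maximum pair distance in bp.
#' @param n_samples diploid subsample size (`NULL` = all samples of `pop`).
#' @param bin_width distance bin width in bp.
#' @param seed subsampling seed.
#' @return data frame with `dist` (bin midpoint), `mean_r2`, `n_pairs`.
#' @export
ld_decay <- function(panel, pop, max_dist = 1e6, n_samples = NULL,
                     bin_width = 1e4, seed = 1) {
  idx <- which(panel$pop_labels == pop)
  if (!is.null(n_samples)) {
    if (n_samples > length(idx))
      stop("requested subsample exceeds available samples in ", pop)
    set.seed(seed)
    idx <- sort(sample(idx, n_samples))
  }
  rows <- as.vector(rbind(2 * idx - 1, 2 * idx))
  hm <- panel$hap_matrix[rows, , drop = FALSE]
  dos <- hm[seq(1, nrow(hm), 2), , drop = FALSE] +
    hm[seq(2, nrow(hm), 2), , drop = FALSE]
  v <- apply(dos, 2, stats::var)
  keep <- !is.na(v) & v > 0
  dos <- dos[, keep, drop = FALSE]
  pos <- panel$positions[keep]
  S <- ncol(dos)
  if (S < 2) return(data.frame(dist = numeric(0), mean_r2 = numeric(0),
                               n_pairs = integer(0)))
  cc <- suppressWarnings(stats::cor(dos, use = "pairwise.complete.obs"))^2
  pr <- which(upper.tri(cc), arr.ind = TRUE)
  d <- abs(pos[pr[, 2]] - pos[pr[, 1]])
  r2 <- cc[pr]
  in_range <- d <= max_dist & !is.na(r2)
  d <- d[in_range]; r2 <- r2[in_range]
  bin <- floor(d / bin_width)
  agg <- tapply(r2, bin, mean)
  npr <- tapply(r2, bin, length)
  data.frame(dist = (as.numeric(names(agg)) + 0.5) * bin_width,
             mean_r2 = as.numeric(agg), n_pairs = as.integer(npr))
}

#' Per-sample inbreeding coefficient
#'
#' Method-of-moments F per sample: `F = (O - E) / (N - E)` where O is the
#' observed homozygous-site count, `E = sum over sites of
#' 1 - 2 p (1-p) n/(n-1)` the count expected under Hardy-Weinberg, and N the
#' number of polymorphic sites used.  Allele frequencies are computed from
#' the same population's samples; sites monomorphic in the population are
#' excluded.
#'
#' @param panel a [haplotype_panel()].
#' @param pop population label.
#' @return data frame with `sample_id`, `O_hom`, `E_hom`, `N_sites`, `F`.
#' @export
inbreeding_f <- function(panel, pop) {
  idx <- which(panel$pop_labels == pop)
  if (!length(idx)) stop("no samples in population ", pop)
  rows <- as.vector(rbind(2 * idx - 1, 2 * idx))
  hm <- panel$hap_matrix[rows, , drop = FALSE]
  n <- colSums(!is.na(hm))
  dc <- colSums(hm, na.rm = TRUE)
  p <- dc / n
  poly <- n >= 2 & p > 0 & p < 1
  hm <- hm[, poly, drop = FALSE]
  p <- p[poly]; n <- n[poly]
  e_site <- 1 - 2 * p * (1 - p) * n / (n - 1)
  a1 <- hm[seq(1, nrow(hm), 2), , drop = FALSE]
  a2 <- hm[seq(2, nrow(hm), 2), , drop = FALSE]
  called <- !is.na(a1) & !is.na(a2)
  O <- rowSums(a1 == a2 & called, na.rm = TRUE)
  E <- as.vector(called %*% e_site)
  N <- rowSums(called)
  data.frame(sample_id = panel$sample_ids[idx], O_hom = O, E_hom = E,
             N_sites = N, F = (O - E) / (N - E))
}

#' Homozygosity-by-descent segments
#'
#' Per-site LOD scores contrast an HBD model (`P(hom_a) = p_a (1-e) +
#' e p_a^2`, `P(het) = e 2 p (1-p)`) against Hardy-Weinberg expectations
#' (`p_a^2`, `2 p (1-p)`), with genotyping-error rate `e`.  Maximal-scoring
#' disjoint segments are extracted recursively (best segment by Kadane's
#' scan, then recurse left and right) and reported when the segment LOD
#' reaches `lod_min` and the physical span reaches `len_min`.  Missing
#' genotypes contribute LOD 0.
#'
#' @param panel a [haplotype_panel()].
#' @param pop population label (frequencies are taken from this population).
#' @param error_rate genotyping error rate e.
#' @param lod_min minimum segment LOD.
#' @param len_min minimum segment length in bp.
#' @return list with `segments` (data frame: sample_id, start, end (0-based
#'   half-open), lod, length) and `total_hbd` (named bp total per sample).
#' @export
hbd_segments <- function(panel, pop, error_rate = 0.005, lod_min = 3,
                         len_min = 5e4) {
  idx <- which(panel$pop_labels == pop)
  if (length(idx) < 10)
    stop("HBD detection needs frequencies from at least 10 samples")
  rows <- as.vector(rbind(2 * idx - 1, 2 * idx))
  hm <- panel$hap_matrix[rows, , drop = FALSE]
  n <- colSums(!is.na(hm))
  p <- colSums(hm, na.rm = TRUE) / n     # derived allele frequency
  poly <- n >= 2 & p > 0 & p < 1
  e <- error_rate
  segs <- list()
  totals <- stats::setNames(numeric(length(idx)), panel$sample_ids[idx])
  for (k in seq_along(idx)) {
    g1 <- hm[2 * k - 1, ]; g2 <- hm[2 * k, ]
    lod <- numeric(ncol(hm))
    ok <- poly & !is.na(g1) & !is.na(g2)
    hom1 <- ok & g1 == 1 & g2 == 1
    hom0 <- ok & g1 == 0 & g2 == 0
    het <- ok & g1 != g2
    lod[hom1] <- log10((p[hom1] * (1 - e) + e * p[hom1]^2) / p[hom1]^2)
    lod[hom0] <- log10(((1 - p[hom0]) * (1 - e) + e * (1 - p[hom0])^2) /
                         (1 - p[hom0])^2)
    lod[het] <- log10(e)
    found <- max_scoring_segments(lod, panel$positions, lod_min, len_min)
    if (nrow(found)) {
      found$sample_id <- panel$sample_ids[idx[k]]
      segs[[length(segs) + 1]] <- found
      totals[k] <- sum(found$length)
    }
  }
  segments <- if (length(segs)) do.call(rbind, segs) else
    data.frame(start = numeric(0), end = numeric(0), lod = numeric(0),
               length = numeric(0), sample_id = character(0))
  segments <- segments[, c("sample_id", "start", "end", "lod", "length")]
  list(segments = segments, total_hbd = totals)
}

# disjoint maximal-scoring segments: Kadane for the best segment, recurse on
# the flanks; segments failing the length filter are discarded but their
# flanks are still searched
max_scoring_segments <- function(score, positions, lod_min, len_min) {
  out <- data.frame(start = numeric(0), end = numeric(0), lod = numeric(0),
                    length = numeric(0))
  recurse <- function(lo, hi) {
    if (lo > hi) return()
    best <- -Inf; bi <- bj <- lo
    cur <- 0; ci <- lo
    for (i in lo:hi) {
      cur <- cur + score[i]
      if (cur > best) { best <- cur; bi <- ci; bj <- i }
      if (cur < 0) { cur <- 0; ci <- i + 1 }
    }
    if (best < lod_min) return()
    len <- positions[bj] - positions[bi] + 1
    if (len >= len_min)
      out[nrow(out) + 1, ] <<- c(positions[bi] - 1, positions[bj], best, len)
    recurse(lo, bi - 1)
    recurse(bj + 1, hi)
  }
  recurse(1, length(score))
  out
}

#' Near-privately fixed SNPs
#'
#' Sites whose derived allele is at frequency `>= freq_min` in the focal
#' population and exactly absent (frequency 0) in every other population.
#'
#' @param panel a polarized [haplotype_panel()].
#' @param focal_pop focal population label.
#' @param freq_min focal frequency threshold.
#' @param grid optional window grid for a per-window tally.
#' @param genes optional `GRanges` of genes for a per-gene tally.
#' @return list with `sites` (data frame position, focal frequency) and
#'   optional `window_tally` / `gene_tally`.
#' @export
near_fixed_private <- function(panel, focal_pop, freq_min = 0.9,
                               grid = NULL, genes = NULL) {
  if (!panel$polarized)
    stop("near_fixed_private requires a polarized panel")
  pops <- unique(panel$pop_labels)
  ac <- pop_allele_counts(panel, pops)
  i <- match(focal_pop, pops)
  if (is.na(i)) stop("unknown focal population ", focal_pop)
  others <- ac$derived[, -i, drop = FALSE]
  hit <- ac$freq[, i] >= freq_min & rowSums(others) == 0
  hit[is.na(hit)] <- FALSE
  sites <- data.frame(position = panel$positions[hit],
                      freq_focal = ac$freq[hit, i])
  out <- list(sites = sites)
  if (!is.null(grid)) {
    win <- sites_in_windows(grid, panel$scaffold_id, sites$position)
    g <- grid[grid$scaffold_id == panel$scaffold_id, , drop = FALSE]
    g$n_private <- vapply(win, length, numeric(1))
    out$window_tally <- g
  }
  if (!is.null(genes)) {
    gr <- GenomicRanges::GRanges(panel$scaffold_id,
                                 IRanges::IRanges(sites$position,
                                                  sites$position))
    ov <- GenomicRanges::countOverlaps(genes, gr)
    out$gene_tally <- data.frame(gene_id = names(genes), n_private = ov)
  }
  out
}
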