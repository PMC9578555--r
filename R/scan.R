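#' Flag SNPs with extreme standardized scores
#'
#' iHS flags use the fixed two-sided rule `|std| > 2`; XP-EHH and XP-nSL
#' flags use the empirical 99th percentile of the supplied scores for that
#' ordered population pair (strictly greater in both cases, so a score equal
#' to the threshold is not flagged).
#'
#' @param std standardized scores (NA allowed; never flagged).
#' @param statistic one of `"ihs"`, `"xpehh"`, `"xpnsl"`.
#' @param upper_quantile percentile used for the XP statistics.
#' @return logical vector (NA scores give FALSE).
#' @export
flag_extreme <- function(std, statistic = c("ihs", "xpehh", "xpnsl"),
                         upper_quantile = 0.99) {
  statistic <- match.arg(statistic)
  flags <- rep(FALSE, length(std))
  ok <- !is.na(std)
  if (statistic == "ihs") {
    flags[ok] <- abs(std[ok]) > 2
  } else {
    if (sum(ok) < 100)
      stop("need at least 100 scores to take an empirical percentile (got ",
           sum(ok), ")")
    thr <- stats::quantile(std[ok], upper_quantile, names = FALSE)
    flags[ok] <- std[ok] > thr
  }
  flags
}

#' Candidate sweep windows from flagged SNPs
#'
#' Computes per window the proportion of flagged SNPs among SNPs with a
#' computed score, drops windows with fewer than `min_snps` scored SNPs,
#' and marks as candidates the windows whose proportion reaches the
#' `1 - top_fraction` empirical quantile of window proportions (ties at the
#' threshold included).
#'
#' @param snps data frame with `scaffold_id`, `position`, `scored`
#'   (logical) and `flagged` (logical).
#' @param grid a [make_windows()] grid (the 50-kb tiling in the standard
#'   analysis).
#' @param min_snps minimum scored SNPs per ranked window.
#' @param top_fraction ranked tail reported as candidates.
#' @return data frame of windows with `n_scored`, `n_flagged`, `prop`,
#'   `candidate`.
#' @export
window_outliers <- function(snps, grid, min_snps = 10, top_fraction = 0.01) {
  if (!nrow(grid)) stop("empty window grid")
  out <- do.call(rbind, lapply(unique(grid$scaffold_id), function(sc) {
    g <- grid[grid$scaffold_id == sc, , drop = FALSE]
    s <- snps[snps$scaffold_id == sc & snps$scored, , drop = FALSE]
    win <- sites_in_windows(grid, sc, s$position)
    g$n_scored <- vapply(win, length, numeric(1))
    g$n_flagged <- vapply(win, function(ix) sum(s$flagged[ix]), numeric(1))
    g
  }))
  out <- out[out$n_scored >= min_snps, , drop = FALSE]
  out$prop <- out$n_flagged / out$n_scored
  if (!nrow(out)) return(cbind(out, candidate = logical(0)))
  thr <- stats::quantile(out$prop, 1 - top_fraction, names = FALSE)
  # ties at the threshold are included; windows without any extreme SNP are
  # never candidates (relevant when the ranked tail threshold is zero)
  out$candidate <- out$prop >= thr & out$prop > 0
  rownames(out) <- NULL
  out
}

#' Combine per-statistic candidates into sweep regions
#'
#' Takes candidate windows per population and statistic, unions them per
#' population, and applies the uniqueness rule: a window that is an iHS
#' candidate in more than one population loses its iHS support everywhere
#' (and is dropped entirely if no other statistic contributes).  XP
#' candidacies are left untouched -- the cross-population statistics already
#' target differences between populations.
#'
#' @param candidates data frame with `scaffold_id`, `start`, `end`, `pop`,
#'   `statistic`, `prop` (one row per candidate window x statistic x pop).
#' @return data frame of class `sweep_regions`: one row per window x pop
#'   with `stats` (comma-joined contributing statistics), `n_stats`,
#'   `max_prop`.
#' @export
combine_and_filter <- function(candidates) {
  need <- c("scaffold_id", "start", "end", "pop", "statistic", "prop")
  stopifnot(all(need %in% names(candidates)))
  if (!nrow(candidates)) {
    out <- data.frame(scaffold_id = character(0), start = numeric(0),
                      end = numeric(0), pop = character(0),
                      stats = character(0), n_stats = integer(0),
                      max_prop = numeric(0))
    class(out) <- c("sweep_regions", "data.frame")
    return(out)
  }
  key <- function(d) paste(d$scaffold_id, d$start, d$end, sep = ":")
  ihs <- candidates[candidates$statistic == "ihs", , drop = FALSE]
  multi <- names(which(tapply(ihs$pop, key(ihs),
                              function(p) length(unique(p))) > 1))
  drop <- candidates$statistic == "ihs" & key(candidates) %in% multi
  kept <- candidates[!drop, , drop = FALSE]
  if (!nrow(kept)) return(combine_and_filter(kept[0, , drop = FALSE]))
  grp <- paste(key(kept), kept$pop, sep = "|")
  agg <- lapply(split(kept, grp), function(d) {
    data.frame(scaffold_id = d$scaffold_id[1], start = d$start[1],
               end = d$end[1], pop = d$pop[1],
               stats = paste(sort(unique(d$statistic)), collapse = ","),
               n_stats = length(unique(d$statistic)),
               max_prop = max(d$prop))
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$pop, out$scaffold_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("sweep_regions", "data.frame")
  out
}

#' Calibrate a PBS significance threshold on neutral simulations
#'
#' The threshold is the empirical `1 - fpr` quantile (type-1, i.e. an order
#' statistic) of per-SNP PBS values for the focal branch under the supplied
#' neutral demographic model, so that the exceedance rate on the calibration
#' data is at most `fpr`.
#'
#' @param pbs_values numeric vector of per-SNP focal-branch PBS values
#'   pooled over neutral replicates; alternatively a list of panels plus
#'   `pops`/`focal_pop` below.
#' @param focal_pop focal population label (for labelling, and to extract
#'   the right branch when panels are supplied).
#' @param fpr target false-positive rate.
#' @param pops the three population labels (required when panels are given).
#' @param min_snps minimum pooled SNP count.
#' @return list of class `calibrated_threshold`: `population`, `statistic`,
#'   `threshold`, `fpr`, `n_snps`.
#' @export
calibrate_pbs_threshold <- function(pbs_values, focal_pop, fpr = 0.01,
                                    pops = NULL, min_snps = 1e4) {
  if (is.list(pbs_values) && !is.numeric(pbs_values)) {
    stopifnot(!is.null(pops), length(pops) == 3)
    pbs_values <- unlist(lapply(pbs_values, function(p) {
      d <- pbs_per_snp(p, pops)
      d[[paste0("pbs_", focal_pop)]]
    }))
  }
  pbs_values <- pbs_values[is.finite(pbs_values)]
  if (length(pbs_values) < min_snps)
    stop("calibration needs at least ", min_snps, " neutral SNPs; got ",
         length(pbs_values))
  structure(list(population = focal_pop, statistic = "PBS",
                 threshold = stats::quantile(pbs_values, 1 - fpr,
                                             type = 1, names = FALSE),
                 fpr = fpr, n_snps = length(pbs_values)),
            class = "calibrated_threshold")
}

#' Intersect sweep regions with significant PBS SNPs
#'
#' Marks each sweep region with whether it contains at least one SNP whose
#' focal-branch PBS exceeds the calibrated threshold of the region's
#' population, and records the maximum PBS inside the window.
#'
#' @param regions a [combine_and_filter()] result.
#' @param pbs_snps data frame with `scaffold_id`, `position` and one
#'   `pbs_<pop>` column per population (see [pbs_per_snp()]).
#' @param thresholds named list/vector of per-population thresholds, or a
#'   list of `calibrated_threshold` objects.
#' @return `regions` with `pbs_overlap` and `pbs_max` columns, plus a
#'   `per_pop_fraction` attribute (fraction of each population's regions
#'   with PBS support).
#' @export
pbs_overlap <- function(regions, pbs_snps, thresholds) {
  if (is.list(thresholds) && all(vapply(thresholds, inherits, logical(1),
                                        "calibrated_threshold")))
    thresholds <- stats::setNames(
      vapply(thresholds, function(x) x$threshold, numeric(1)),
      vapply(thresholds, function(x) x$population, character(1)))
  missing_pop <- setdiff(unique(regions$pop), names(thresholds))
  if (length(missing_pop))
    stop("missing PBS threshold for population(s): ",
         paste(missing_pop, collapse = ", "))
  regions$pbs_overlap <- FALSE
  regions$pbs_max <- NA_real_
  for (i in seq_len(nrow(regions))) {
    col <- paste0("pbs_", regions$pop[i])
    if (!col %in% names(pbs_snps))
      stop("pbs_snps lacks column ", col)
    ix <- pbs_snps$scaffold_id == regions$scaffold_id[i] &
      pbs_snps$position > regions$start[i] &
      pbs_snps$position <= regions$end[i]
    vals <- pbs_snps[[col]][ix]
    vals <- vals[!is.na(vals)]
    if (length(vals)) {
      regions$pbs_max[i] <- max(vals)
      regions$pbs_overlap[i] <-
        any(vals > thresholds[[regions$pop[i]]])
    }
  }
  frac <- tapply(regions$pbs_overlap, regions$pop, mean)
  attr(regions, "per_pop_fraction") <- frac
  regions
}

#' Full EHH-based sweep scan over one or more panels
#'
#' Convenience orchestration of the standard window outlier procedure:
#' per-population iHS and per-ordered-pair XP-EHH / XP-nSL scans,
#' 50-frequency-bin normalization pooled across scaffolds, extreme-SNP
#' flagging, per-population top-fraction window ranking and the iHS
#' population-uniqueness rule.
#'
#' @param panels list of [haplotype_panel()] (or a single panel).
#' @param pops populations to scan.
#' @param grid window grid (typically 50-kb tiles).
#' @param maf_min,ehh_cutoff,max_extend,max_sites passed to the scans.
#' @param n_bins,min_bin_count normalization bins.
#' @param min_snps,top_fraction window ranking knobs.
#' @return list with `regions` ([combine_and_filter()] output),
#'   `candidates`, and the per-SNP `scores` table.
#' @export
sweep_scan <- function(panels, pops, grid, maf_min = 0.05,
                       ehh_cutoff = 0.05, max_extend = 1e6,
                       max_sites = 100, n_bins = 50, min_bin_count = 20,
                       min_snps = 10, top_fraction = 0.01) {
  if (inherits(panels, "haplotype_panel")) panels <- list(panels)
  tracks <- list()
  for (p in pops) {
    w <- do.call(rbind, lapply(panels, within_pop_scan, pop = p,
                               maf_min = maf_min, ehh_cutoff = ehh_cutoff,
                               max_extend = max_extend,
                               max_sites = max_sites))
    tracks[[paste0("ihs|", p)]] <-
      data.frame(scaffold_id = w$scaffold_id, position = w$position,
                 freq = w$freq, raw = w$ihs_raw, pop = p,
                 statistic = "ihs", stringsAsFactors = FALSE)
  }
  # XP statistics are antisymmetric in the ordered pair, so each unordered
  # pair is scanned once and the reverse track is the negation
  if (length(pops) >= 2) {
    pair_mat <- utils::combn(pops, 2)
    for (k in seq_len(ncol(pair_mat))) {
      p <- pair_mat[1, k]; q <- pair_mat[2, k]
      x <- do.call(rbind, lapply(panels, cross_pop_scan, popA = p,
                                 popB = q, maf_min = maf_min,
                                 ehh_cutoff = ehh_cutoff,
                                 max_extend = max_extend,
                                 max_sites = max_sites))
      for (st in c("xpehh", "xpnsl")) {
        raw <- x[[paste0(st, "_raw")]]
        tracks[[paste0(st, "|", p, "|", q)]] <-
          data.frame(scaffold_id = x$scaffold_id, position = x$position,
                     freq = x$freq, raw = raw, pop = p,
                     statistic = st, stringsAsFactors = FALSE)
        tracks[[paste0(st, "|", q, "|", p)]] <-
          data.frame(scaffold_id = x$scaffold_id, position = x$position,
                     freq = x$freq, raw = -raw, pop = q,
                     statistic = st, stringsAsFactors = FALSE)
      }
    }
  }
  cand_list <- list()
  scores <- list()
  for (nm in names(tracks)) {
    tr <- tracks[[nm]]
    tr$std <- normalize_bins(tr$raw, tr$freq, n_bins = n_bins,
                             min_bin_count = min_bin_count)
    tr$flagged <- flag_extreme(tr$std, tr$statistic[1])
    tr$scored <- !is.na(tr$std)
    scores[[nm]] <- tr
    wo <- window_outliers(tr, grid, min_snps = min_snps,
                          top_fraction = top_fraction)
    cand <- wo[wo$candidate, , drop = FALSE]
    if (nrow(cand))
      cand_list[[nm]] <- data.frame(scaffold_id = cand$scaffold_id,
                                    start = cand$start, end = cand$end,
                                    pop = tr$pop[1],
                                    statistic = tr$statistic[1],
                                    prop = cand$prop,
                                    stringsAsFactors = FALSE)
  }
  candidates <- if (length(cand_list)) do.call(rbind, cand_list) else
    data.frame(scaffold_id = character(0), start = numeric(0),
               end = numeric(0), pop = character(0),
               statistic = character(0), prop = numeric(0))
  rownames(candidates) <- NULL
  list(regions = combine_and_filter(candidates), candidates = candidates,
       scores = do.call(rbind, scores))
}
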