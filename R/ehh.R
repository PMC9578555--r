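#' Extended haplotype homozygosity curve from a core SNP
#'
#' EHH at marker x is the fraction of carrier pairs identical at every SNP
#' between the core and x inclusive; it is 1 at the core and monotonically
#' non-increasing with distance.
#'
#' @param panel a [haplotype_panel()].
#' @param core_index column index of the core SNP.
#' @param core_allele 0 (ancestral/REF) or 1 (derived/ALT).
#' @param direction `"left"`, `"right"` or `"both"`.
#' @param pop optional population label restricting the carrier set.
#' @return data frame with `position`, `ehh` (including the core row with
#'   EHH 1), ordered by position.
#' @export
ehh_curve <- function(panel, core_index, core_allele,
                      direction = c("both", "left", "right"), pop = NULL) {
  direction <- match.arg(direction)
  rows <- seq_len(nrow(panel$hap_matrix))
  if (!is.null(pop)) rows <- which(hap_pops(panel) == pop)
  carriers <- rows[panel$hap_matrix[rows, core_index] == core_allele]
  if (length(carriers) < 2)
    stop("EHH undefined: fewer than 2 carriers of the core allele")
  res <- data.frame(position = panel$positions[core_index], ehh = 1)
  if (direction %in% c("left", "both") && core_index > 1) {
    v <- ehh_curve_cpp(panel$hap_matrix, carriers - 1L,
                       core_index - 1L, -1L, FALSE)
    res <- rbind(data.frame(position =
                              rev(panel$positions[seq_len(core_index - 1)]),
                            ehh = v)[length(v):1, ], res)
  }
  if (direction %in% c("right", "both") && core_index < ncol(panel$hap_matrix)) {
    v <- ehh_curve_cpp(panel$hap_matrix, carriers - 1L,
                       core_index - 1L, 1L, FALSE)
    res <- rbind(res, data.frame(position =
                                   panel$positions[(core_index + 1):ncol(panel$hap_matrix)],
                                 ehh = v))
  }
  rownames(res) <- NULL
  res
}

#' Within-population haplotype scan: raw iHS and nSL
#'
#' For every core SNP passing the minor-allele-frequency filter, integrates
#' EHH over physical distance separately for derived and ancestral carriers
#' (trapezoid rule, truncated where EHH drops below `ehh_cutoff`) giving
#' iHH_D and iHH_A, and computes mean pairwise identity lengths in
#' segregating-site units (SL_D, SL_A, no cutoff).  Raw scores are
#' `iHS = log(iHH_A / iHH_D)` and `nSL = log(SL_A / SL_D)`.  A core whose
#' EHH curve fails to reach the cutoff before `max_extend` or the scaffold
#' edge is reported with status `skipped_truncated`.
#'
#' Note the sign convention: positive raw iHS marks unusually long
#' haplotypes around the *ancestral* allele; sweeps on the derived allele
#' give strongly negative raw iHS.  Outlier flagging uses `|iHS|`.
#'
#' @param panel a polarized [haplotype_panel()].
#' @param pop population label.
#' @param maf_min minimum minor-allele frequency for a core.
#' @param ehh_cutoff EHH truncation level for the iHH integral.
#' @param max_extend maximum extension distance in bp.
#' @param max_sites cap on nSL extension in segregating-site units.
#' @param max_missing cores with more than this missing fraction in the
#'   population are excluded.
#' @return data frame of class `ehh_result`: `scaffold_id`, `position`,
#'   `freq` (derived), `ihh_d`, `ihh_a`, `sl_d`, `sl_a`, `ihs_raw`,
#'   `nsl_raw`, `status`.
#' @export
within_pop_scan <- function(panel, pop, maf_min = 0.05, ehh_cutoff = 0.05,
                            max_extend = 1e6, max_sites = 100,
                            max_missing = 0.1) {
  if (!panel$polarized)
    stop("within-population scan requires a polarized panel")
  rows <- which(hap_pops(panel) == pop)
  if (length(rows) < 4) stop("population ", pop, " has too few haplotypes")
  hm <- panel$hap_matrix
  called <- colSums(!is.na(hm[rows, , drop = FALSE]))
  dc <- colSums(hm[rows, , drop = FALSE], na.rm = TRUE)
  freq <- dc / called
  maf <- pmin(freq, 1 - freq)
  miss_ok <- (1 - called / length(rows)) <= max_missing
  is_core <- maf >= maf_min & miss_ok
  cores <- which(is_core)
  status <- rep("skipped_maf", ncol(hm))
  res <- data.frame(scaffold_id = panel$scaffold_id,
                    position = panel$positions, freq = freq,
                    ihh_d = NA_real_, ihh_a = NA_real_,
                    sl_d = NA_real_, sl_a = NA_real_,
                    ihs_raw = NA_real_, nsl_raw = NA_real_,
                    status = status, stringsAsFactors = FALSE)
  if (length(cores)) {
    hm0 <- hm; hm0[is.na(hm0)] <- 0L  # missing treated as ancestral in walks
    m <- ehh_within_scan_cpp(hm0, as.numeric(panel$positions),
                             rows - 1L, cores - 1L,
                             ehh_cutoff, max_extend, as.integer(max_sites))
    res$ihh_d[cores] <- m[, "ihh_d"]
    res$ihh_a[cores] <- m[, "ihh_a"]
    res$sl_d[cores] <- m[, "sl_d"]
    res$sl_a[cores] <- m[, "sl_a"]
    ok <- m[, "enough"] == 1 & m[, "complete"] == 1 &
      m[, "ihh_d"] > 0 & m[, "ihh_a"] > 0
    res$status[cores] <- ifelse(m[, "enough"] == 0, "skipped_maf",
                                ifelse(ok, "ok", "skipped_truncated"))
    oc <- cores[ok]
    res$ihs_raw[oc] <- log(res$ihh_a[oc] / res$ihh_d[oc])
    nz <- cores[m[, "enough"] == 1 & m[, "sl_d"] > 0 & m[, "sl_a"] > 0]
    res$nsl_raw[nz] <- log(res$sl_a[nz] / res$sl_d[nz])
  }
  class(res) <- c("ehh_result", "data.frame")
  res
}

#' Cross-population haplotype scan: raw XP-EHH and XP-nSL
#'
#' iHH is integrated over all haplotypes of each population from the core
#' (not allele-partitioned; the walk starts at the core homozygosity), and
#' `XP-EHH = log(iHH_popA / iHH_popB)`; positive values mean longer
#' haplotype homozygosity in `popA`.  XP-nSL is the same contrast on mean
#' pairwise identity lengths in segregating-site units.
#'
#' @param panel a [haplotype_panel()].
#' @param popA,popB population labels (A is the focal population).
#' @param maf_min minimum pooled minor-allele frequency for a core.
#' @inheritParams within_pop_scan
#' @return data frame of class `ehh_result`: `scaffold_id`, `position`,
#'   `freq` (pooled derived), `ihh_a`, `ihh_b`, `sl_a`, `sl_b`,
#'   `xpehh_raw`, `xpnsl_raw`, `status`.
#' @export
cross_pop_scan <- function(panel, popA, popB, maf_min = 0.05,
                           ehh_cutoff = 0.05, max_extend = 1e6,
                           max_sites = 100, max_missing = 0.1) {
  rowsA <- which(hap_pops(panel) == popA)
  rowsB <- which(hap_pops(panel) == popB)
  if (length(rowsA) < 4 || length(rowsB) < 4)
    stop("both populations need at least 4 haplotypes")
  hm <- panel$hap_matrix
  un <- c(rowsA, rowsB)
  called <- colSums(!is.na(hm[un, , drop = FALSE]))
  dc <- colSums(hm[un, , drop = FALSE], na.rm = TRUE)
  freq <- dc / called
  seg <- freq > 0 & freq < 1 & pmin(freq, 1 - freq) >= maf_min
  miss_ok <- (1 - called / length(un)) <= max_missing
  cores <- which(seg & miss_ok)
  res <- data.frame(scaffold_id = panel$scaffold_id,
                    position = panel$positions, freq = freq,
                    ihh_a = NA_real_, ihh_b = NA_real_,
                    sl_a = NA_real_, sl_b = NA_real_,
                    xpehh_raw = NA_real_, xpnsl_raw = NA_real_,
                    status = "skipped_maf", stringsAsFactors = FALSE)
  if (length(cores)) {
    hm0 <- hm; hm0[is.na(hm0)] <- 0L
    pos <- as.numeric(panel$positions)
    mA <- ehh_pop_scan_cpp(hm0, pos, rowsA - 1L, cores - 1L, ehh_cutoff,
                           max_extend, as.integer(max_sites))
    mB <- ehh_pop_scan_cpp(hm0, pos, rowsB - 1L, cores - 1L, ehh_cutoff,
                           max_extend, as.integer(max_sites))
    res$ihh_a[cores] <- mA[, "ihh"]
    res$ihh_b[cores] <- mB[, "ihh"]
    res$sl_a[cores] <- mA[, "sl"]
    res$sl_b[cores] <- mB[, "sl"]
    ok <- mA[, "complete"] == 1 & mB[, "complete"] == 1 &
      mA[, "ihh"] > 0 & mB[, "ihh"] > 0
    res$status[cores] <- ifelse(ok, "ok", "skipped_truncated")
    oc <- cores[ok]
    res$xpehh_raw[oc] <- log(res$ihh_a[oc] / res$ihh_b[oc])
    nz <- cores[mA[, "sl"] > 0 & mB[, "sl"] > 0]
    res$xpnsl_raw[nz] <- log(res$sl_a[nz] / res$sl_b[nz])
  }
  class(res) <- c("ehh_result", "data.frame")
  res
}

#' Frequency-bin normalization of raw haplotype scores
#'
#' Standardizes raw scores within equal-width derived-allele-frequency bins
#' on `[0, 1]`: `std = (raw - bin mean) / bin sd`.  Bins holding fewer than
#' `min_bin_count` scores are merged with their nearest (by bin index)
#' non-deficient neighbour before standardization.  With `n_bins = 1` this
#' reduces to a global z-score.
#'
#' @param raw numeric raw scores (NA allowed, passed through as NA).
#' @param freq derived-allele frequency per score.
#' @param n_bins number of equal-width frequency bins.
#' @param min_bin_count minimum scores per bin after merging.
#' @return numeric vector of standardized scores.
#' @export
normalize_bins <- function(raw, freq, n_bins = 50, min_bin_count = 20) {
  stopifnot(length(raw) == length(freq))
  ok <- !is.na(raw) & !is.na(freq)
  bin <- pmin(pmax(ceiling(freq * n_bins), 1L), n_bins)
  counts <- tabulate(bin[ok], n_bins)
  # merge deficient bins into the nearest populated neighbour
  merged <- seq_len(n_bins)
  good <- which(counts >= min_bin_count)
  if (!length(good)) {
    merged[] <- 1L
  } else {
    for (b in seq_len(n_bins)) {
      if (counts[b] < min_bin_count)
        merged[b] <- good[which.min(abs(good - b))]
    }
  }
  grp <- merged[bin]
  std <- rep(NA_real_, length(raw))
  for (g in unique(grp[ok])) {
    ix <- ok & grp == g
    m <- mean(raw[ix])
    s <- stats::sd(raw[ix])
    if (is.na(s) || s == 0) {
      warning("zero score spread in frequency bin ", g,
              "; scores set to missing")
      next
    }
    std[ix] <- (raw[ix] - m) / s
  }
  std
}
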