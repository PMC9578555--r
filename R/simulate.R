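#' Specify a beneficial allele for a hard or standing sweep
#'
#' Genotype fitnesses at the focal site are 1, 1 + h*s and 1 + s for
#' ancestral homozygotes, heterozygotes and derived homozygotes; selection
#' acts as viability weighting of parents in the focal population.
#'
#' @param focal_pop population label (e.g. `"IN"`) carrying the sweep.
#' @param s selection coefficient (>= 0).
#' @param h dominance coefficient in `[0, 1]`.
#' @param origin_time generations before present at which the allele arises
#'   (`mode = "denovo"`) or begins being selected (`mode = "standing"`, which
#'   recruits the segregating variant nearest `focal_position`).
#' @param focal_position target position in bp within `[1, L]`.
#' @param mode `"denovo"` or `"standing"`.
#' @param freq_range in `"standing"` mode, admissible initial derived
#'   frequency of the recruited variant in the focal population; the default
#'   `c(0, 1)` takes the nearest segregating variant regardless of frequency.
#' @param require_establishment if `TRUE`, replicates are conditioned on the
#'   final derived frequency in the focal population reaching `min_freq`.
#' @param min_freq establishment frequency threshold.
#' @param max_tries maximum replicate attempts when conditioning.
#' @return an object of class `selection_spec`.
#' @export
selection_spec <- function(focal_pop, s, h = 0.5, origin_time,
                           focal_position, mode = c("standing", "denovo"),
                           freq_range = c(0, 1),
                           require_establishment = TRUE, min_freq = 0.8,
                           max_tries = 50) {
  mode <- match.arg(mode)
  stopifnot(s >= 0, h >= 0, h <= 1, origin_time >= 1, focal_position >= 1,
            max_tries >= 1, min_freq > 0, min_freq <= 1,
            length(freq_range) == 2, freq_range[1] <= freq_range[2])
  structure(list(focal_pop = focal_pop, s = s, h = h,
                 origin_time = origin_time, focal_position = focal_position,
                 mode = mode, freq_range = freq_range,
                 require_establishment = require_establishment,
                 min_freq = min_freq, max_tries = max_tries),
            class = "selection_spec")
}

#' Forward Wright-Fisher simulation
#'
#' Simulates the supplied demography forward in discrete generations
#' (migration, viability selection, random mating with per-gamete
#' Poisson(rec*L) crossovers and Poisson(mu*L) infinite-sites mutations) and
#' returns one polarized [haplotype_panel()] per scaffold for a present-day
#' sample.  Output is fully reproducible from `seed`; scaffold `i` of the
#' replicate uses a sub-seed derived from `seed` and `i`.
#'
#' @param model a demography from [demography_imc()], [demography_constant()],
#'   [demography_split()] or [demography_expansion()].
#' @param n_per_pop diploid sample size per population; a single number or a
#'   named vector over the model's populations.
#' @param selection optional [selection_spec()]; the sweep is placed on the
#'   first scaffold.  With `s = 0` the output is identical to a neutral run
#'   with the same seed.
#' @param seed integer seed.
#' @param burn_mult burn-in length in units of the ancestral size (the engine
#'   runs `burn_mult * N_anc` generations before the first split; must give
#'   at least 8 N_anc generations).
#' @param purge_every generations between sweeps for fixed-mutation cleanup.
#' @return a `sim_result`: list with `panels` (one per scaffold),
#'   `sweep_truth` (data frame or NULL) and `seed`.
#' @export
wf_simulate <- function(model, n_per_pop = 20, selection = NULL, seed = 1,
                        burn_mult = 10, purge_every = 100) {
  if (burn_mult < 8)
    stop("burn-in must be at least 8 ancestral-size generations")
  sched <- build_schedule(model, burn_mult = burn_mult)
  pops <- sched$demes
  if (length(n_per_pop) == 1 && is.null(names(n_per_pop)))
    n_per_pop <- stats::setNames(rep(n_per_pop, length(pops)), pops)
  if (!all(pops %in% names(n_per_pop)))
    stop("n_per_pop must name every population: ",
         paste(pops, collapse = ", "))
  n_per_pop <- n_per_pop[pops]
  final_sizes <- sched$sizes[sched$deme_idx + 1, ncol(sched$sizes)]
  if (any(n_per_pop > final_sizes))
    stop("sample size exceeds deme size for: ",
         paste(pops[n_per_pop > final_sizes], collapse = ", "))
  samples <- cbind(as.integer(sched$deme_idx), as.integer(n_per_pop))

  sel_list <- list()
  if (!is.null(selection)) {
    stopifnot(inherits(selection, "selection_spec"))
    if (!selection$focal_pop %in% pops)
      stop("focal_pop not in model populations")
    if (selection$focal_position > sched$L)
      stop("focal_position outside [1, L]")
    origin_gen <- sched$T_end - selection$origin_time
    if (origin_gen < 1)
      stop("origin_time predates the simulation start")
    d_idx <- sched$deme_idx[match(selection$focal_pop, pops)]
    if (sched$sizes[d_idx + 1, origin_gen + 1] == 0)
      stop("focal population does not exist at origin_time")
    sel_list <- list(deme = as.integer(d_idx), s = selection$s,
                     h = selection$h,
                     pos = selection$focal_position - 0.5,
                     origin_gen = as.integer(origin_gen),
                     standing = selection$mode == "standing",
                     freq_lo = selection$freq_range[1],
                     freq_hi = selection$freq_range[2])
  }

  run_one <- function(sub_seed, with_sel) {
    wf_engine_cpp(sched$sizes, sched$founders, sched$migrations,
                  sched$L, sched$mu, sched$rec,
                  if (with_sel) sel_list else list(),
                  samples, as.integer(purge_every), as.double(sub_seed))
  }

  panels <- vector("list", sched$n_scaffolds)
  truth <- NULL
  sample_ids <- unlist(lapply(seq_along(pops), function(i)
    sprintf("%s_%02d", pops[i], seq_len(n_per_pop[i]))))
  pop_labels <- rep(pops, n_per_pop)

  for (sc in seq_len(sched$n_scaffolds)) {
    with_sel <- length(sel_list) > 0 && sc == 1
    sub_seed <- as.double(seed) * 1009 + sc
    res <- run_one(sub_seed, with_sel)
    if (with_sel && !is.null(selection) && selection$s > 0 &&
        selection$require_establishment) {
      tries <- 1
      focal_i <- sched$deme_idx[match(selection$focal_pop, pops)] + 1
      while ((res$standing_failed ||
              is.na(res$ben_freq[focal_i]) ||
              res$ben_freq[focal_i] < selection$min_freq) &&
             tries < selection$max_tries) {
        tries <- tries + 1
        res <- run_one(sub_seed + tries * 7919993, with_sel)
      }
      if (res$standing_failed || is.na(res$ben_freq[focal_i]) ||
          res$ben_freq[focal_i] < selection$min_freq)
        stop("sweep failed to establish after ", tries, " tries")
    }
    scaffold <- sprintf("scaffold_%d", sc)
    conv <- positions_to_bp(res$positions)
    keep <- conv$keep
    hm <- res$hap[, keep, drop = FALSE]
    colnames(hm) <- NULL
    panels[[sc]] <- haplotype_panel(scaffold_id = scaffold,
                                    positions = conv$bp,
                                    hap_matrix = hm,
                                    sample_ids = sample_ids,
                                    pop_labels = pop_labels,
                                    polarized = TRUE)
    if (with_sel && !is.null(selection) && selection$s > 0) {
      bf <- res$ben_freq
      names(bf) <- rownames(sched$sizes)
      truth <- data.frame(scaffold_id = scaffold,
                          position = floor(res$ben_pos) + 1,
                          t(bf[pops]), row.names = NULL)
      names(truth)[3:(2 + length(pops))] <- paste0("freq_", pops)
    }
  }
  structure(list(panels = panels, sweep_truth = truth, seed = seed,
                 model = model),
            class = "sim_result")
}

# round continuous coordinates to unique integer bp (1-based); colliding
# sites keep the first occurrence
positions_to_bp <- function(pos) {
  bp <- floor(pos) + 1
  keep <- !duplicated(bp)
  list(bp = as.integer(bp[keep]), keep = which(keep))
}

#' Joint (optionally folded) site-frequency spectrum
#'
#' Builds the joint SFS over one or more populations from one or more
#' haplotype panels.  Entry `[i1, ..., ik]` counts sites whose allele
#' configuration is `(i1-1, ..., ik-1)` copies per population; when
#' `folded = TRUE` the fold is over the global minor allele (the derived
#' configuration is replaced by the ancestral one whenever the pooled derived
#' count exceeds half the pooled allele count, ties kept as-is).
#'
#' @param panels a [haplotype_panel()] or list of panels.
#' @param pops character vector of population labels to include.
#' @param folded fold over the global minor allele?
#' @return an array of dimension `2*n_hap + 1` per population; the sum over
#'   all entries equals the number of retained sites.
#' @export
joint_sfs <- function(panels, pops, folded = TRUE) {
  if (inherits(panels, "haplotype_panel")) panels <- list(panels)
  p1 <- panels[[1]]
  if (!all(pops %in% p1$pop_labels)) {
    bad <- setdiff(pops, p1$pop_labels)
    stop("population(s) with zero samples: ", paste(bad, collapse = ", "))
  }
  hap_pops <- rep(p1$pop_labels, each = 2)
  n_hap <- vapply(pops, function(p) sum(hap_pops == p), integer(1))
  arr <- array(0L, dim = n_hap + 1L)
  n_dropped <- 0L
  for (panel in panels) {
    hm <- panel$hap_matrix
    if (ncol(hm) == 0) next
    sel_rows <- rep(panel$pop_labels, each = 2) %in% pops
    miss <- colSums(is.na(hm[sel_rows, , drop = FALSE])) > 0
    n_dropped <- n_dropped + sum(miss)
    hm <- hm[, !miss, drop = FALSE]
    if (ncol(hm) == 0) next
    cnt <- vapply(pops, function(p)
      colSums(hm[rep(panel$pop_labels, each = 2) == p, , drop = FALSE]),
      numeric(ncol(hm)))
    if (ncol(hm) == 1) cnt <- matrix(cnt, nrow = 1)
    if (folded) {
      tot_d <- rowSums(cnt)
      flip <- tot_d > sum(n_hap) / 2
      if (any(flip))
        cnt[flip, ] <- rep(n_hap, each = sum(flip)) - cnt[flip, ]
    }
    strides <- cumprod(c(1, utils::head(n_hap + 1L, -1)))
    lin <- as.integer(cnt %*% strides) + 1L
    arr <- arr + array(tabulate(lin, length(arr)), dim = dim(arr))
  }
  if (n_dropped > 0)
    message("joint_sfs: dropped ", n_dropped, " site(s) with missing calls")
  dimnames(arr) <- stats::setNames(lapply(n_hap, function(n) as.character(0:n)),
                                   pops)
  arr
}
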