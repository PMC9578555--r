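#' Three-population founder-effect demography (IMc)
#'
#' Parameterizes a forward-in-time model of one ancestral population that
#' splits twice: first an inshore lineage (IN) buds off from the ancestor of
#' the offshore populations, then the offshore ancestor splits into north
#' (NO) and south (SO) offshore populations.  Each split founds the new
#' deme(s) through a bottleneck followed by exponential growth to the present
#' size.  The two offshore demes exchange migrants at a constant
#' per-individual probability from their split onward; inshore--offshore
#' migration is switched on only at a later secondary-contact time.
#'
#' Defaults are desk-scale: an ancestral size of 1000 diploids with mutation
#' rate, recombination rate, split times and migration probabilities rescaled
#' by a factor of 30 from a large-population parameterization (diploid size
#' ~3e4, mu = 1.2e-8 and rec = 3.2e-8 per base per generation, splits within
#' the last few thousand generations, migration probability ~1e-4 per
#' individual per generation) so that the population-scaled compounds
#' 4*N*mu, 4*N*rec, T/N and N*m are preserved.  They are shaped like a
#' post-glacial founder-effect history -- the strongest bottleneck inshore,
#' the mildest in the north offshore deme -- and are not fitted values.
#'
#' @param N_anc ancestral diploid population size.
#' @param T_div2 inshore/offshore-ancestor split, generations before present.
#' @param T_div1 north/south offshore split, generations before present.
#' @param T_sec onset of inshore--offshore secondary contact, generations
#'   before present.
#' @param N_founder_IN,N_founder_NO,N_founder_SO founder (bottleneck) sizes.
#' @param N_cur_IN,N_cur_NO,N_cur_SO present-day sizes reached by exponential
#'   growth from the founder sizes.
#' @param N_offanc size of the offshore ancestor between the two splits.
#' @param m_off migration probability per individual per generation between
#'   the two offshore demes, constant since `T_div1`.
#' @param m_sec inshore--offshore migration probability, active only since
#'   `T_sec`.
#' @param mu per-base per-generation mutation rate.
#' @param rec per-base per-generation recombination rate.
#' @param L scaffold length in bp.
#' @param n_scaffolds number of independent scaffolds to simulate.
#' @param gen_years years per generation (reporting only).
#' @return an object of class `imc_demography`.
#' @seealso [constant_n_variant()], [wf_simulate()]
#' @export
demography_imc <- function(N_anc = 1000,
                           T_div2 = 48, T_div1 = 32, T_sec = 16,
                           N_founder_IN = 30, N_founder_NO = 60,
                           N_founder_SO = 50,
                           N_cur_IN = 250, N_cur_NO = 400, N_cur_SO = 350,
                           N_offanc = N_anc,
                           m_off = 3e-3, m_sec = 3e-3,
                           mu = 3.6e-7, rec = 9.6e-7,
                           L = 5e5, n_scaffolds = 1, gen_years = 5) {
  stopifnot(T_div2 > T_div1, T_div1 > T_sec, T_sec >= 0)
  sizes <- c(N_anc, N_founder_IN, N_founder_NO, N_founder_SO,
             N_cur_IN, N_cur_NO, N_cur_SO, N_offanc)
  if (any(sizes < 2)) stop("all population sizes must be >= 2")
  if (m_off < 0 || m_off > 0.5 || m_sec < 0 || m_sec > 0.5)
    stop("migration probabilities must lie in [0, 0.5]")
  if (mu < 0 || rec < 0) stop("mu and rec must be >= 0")
  structure(list(N_anc = N_anc, T_div2 = T_div2, T_div1 = T_div1,
                 T_sec = T_sec, N_founder_IN = N_founder_IN,
                 N_founder_NO = N_founder_NO, N_founder_SO = N_founder_SO,
                 N_cur_IN = N_cur_IN, N_cur_NO = N_cur_NO,
                 N_cur_SO = N_cur_SO, N_offanc = N_offanc,
                 m_off = m_off, m_sec = m_sec, mu = mu, rec = rec, L = L,
                 n_scaffolds = n_scaffolds, gen_years = gen_years,
                 constant_ne = FALSE),
            class = "imc_demography")
}

#' Rescaled IMc demography
#'
#' Derives an [demography_imc()] parameterization from a single large-
#' population reference (diploid ancestral size 30000, mu = 1.2e-8 and
#' rec = 3.2e-8 per base per generation, splits at 1440 / 960 generations,
#' secondary contact at 480 generations, migration probability 1e-4) by
#' dividing sizes and times by `scale` while multiplying the per-generation
#' rates by it, which preserves the population-scaled compounds 4 N mu,
#' 4 N rec, T/N and N m.  `scale = 30` reproduces the desk-scale defaults
#' of [demography_imc()]; larger factors give faster, smaller models with
#' the same expected diversity and differentiation.
#'
#' @param scale rescaling factor (>= 1).
#' @param L scaffold length bp.
#' @param n_scaffolds scaffold count.
#' @param ... further overrides passed to [demography_imc()].
#' @return an `imc_demography`.
#' @export
demography_imc_scaled <- function(scale = 30, L = 5e5, n_scaffolds = 1,
                                  ...) {
  stopifnot(scale >= 1)
  r <- function(x) max(2L, as.integer(round(x / scale)))
  demography_imc(N_anc = r(30000),
                 T_div2 = max(3L, as.integer(round(1440 / scale))),
                 T_div1 = max(2L, as.integer(round(960 / scale))),
                 T_sec = max(1L, as.integer(round(480 / scale))),
                 N_founder_IN = r(900), N_founder_NO = r(1800),
                 N_founder_SO = r(1500),
                 N_cur_IN = r(7500), N_cur_NO = r(12000),
                 N_cur_SO = r(10500), N_offanc = r(30000),
                 m_off = 1e-4 * scale, m_sec = 1e-4 * scale,
                 mu = 1.2e-8 * scale, rec = 3.2e-8 * scale,
                 L = L, n_scaffolds = n_scaffolds, ...)
}

#' Constant-Ne counterfactual of an IMc demography
#'
#' Returns a copy of the model in which the total population size is held at
#' the ancestral value through time, divided equally among the demes extant
#' in each epoch (one deme before the first split, two between the splits,
#' three afterwards).  Split times and migration probabilities are untouched;
#' founder/growth parameters are ignored by construction.  Applying the
#' transformation twice equals applying it once.
#'
#' @param model an `imc_demography`.
#' @return an `imc_demography` with constant total size.
#' @export
constant_n_variant <- function(model) {
  stopifnot(inherits(model, "imc_demography"))
  model$constant_ne <- TRUE
  model
}

#' Single constant-size population
#'
#' @param N diploid size.
#' @param mu,rec per-base per-generation rates.
#' @param L scaffold length bp.
#' @param n_scaffolds scaffold count.
#' @return an object of class `simple_demography`.
#' @export
demography_constant <- function(N = 100, mu = 3.6e-6, rec = 9.6e-6,
                                L = 5e4, n_scaffolds = 1) {
  stopifnot(N >= 2, mu >= 0, rec >= 0, L > 0)
  structure(list(kind = "constant", N = N, mu = mu, rec = rec, L = L,
                 n_scaffolds = n_scaffolds),
            class = "simple_demography")
}

#' Two populations splitting from a common ancestor
#'
#' An ancestral deme of size `N` splits `T_split` generations before present
#' into two demes of sizes `N1` and `N2` exchanging migrants at probability
#' `m` per individual per generation.
#'
#' @param N ancestral (and default daughter) diploid size.
#' @param T_split generations before present.
#' @param m symmetric migration probability after the split.
#' @param N1,N2 daughter deme sizes.
#' @inheritParams demography_constant
#' @return an object of class `simple_demography`.
#' @export
demography_split <- function(N = 100, T_split = 4 * N, m = 0, N1 = N, N2 = N,
                             mu = 3.6e-6, rec = 9.6e-6, L = 5e4,
                             n_scaffolds = 1) {
  stopifnot(N >= 2, N1 >= 2, N2 >= 2, T_split >= 1, m >= 0, m <= 0.5)
  structure(list(kind = "split", N = N, T_split = T_split, m = m,
                 N1 = N1, N2 = N2, mu = mu, rec = rec, L = L,
                 n_scaffolds = n_scaffolds),
            class = "simple_demography")
}

#' Bottleneck-then-expansion population
#'
#' A deme of ancestral size `N` collapses to `N_bot` at `T_bot` generations
#' before present and grows exponentially back to `N_cur`.  With enough
#' post-expansion time this regime rebuilds an excess of rare variants and
#' drives Tajima's D negative.
#'
#' @param N ancestral diploid size.
#' @param N_bot bottleneck size.
#' @param N_cur present size.
#' @param T_bot generations before present at which the bottleneck occurs.
#' @inheritParams demography_constant
#' @return an object of class `simple_demography`.
#' @export
demography_expansion <- function(N = 100, N_bot = 10, N_cur = 400,
                                 T_bot = 200, mu = 3.6e-6, rec = 9.6e-6,
                                 L = 5e4, n_scaffolds = 1) {
  stopifnot(N >= 2, N_bot >= 2, N_cur >= 2, T_bot >= 1)
  structure(list(kind = "expansion", N = N, N_bot = N_bot, N_cur = N_cur,
                 T_bot = T_bot, mu = mu, rec = rec, L = L,
                 n_scaffolds = n_scaffolds),
            class = "simple_demography")
}

# exponential size trajectory from `from` at generation t0 to `to` at T
exp_schedule <- function(from, to, t0, T_end) {
  if (T_end <= t0) return(rep(to, max(0L, T_end - t0 + 1L)))
  tt <- t0:T_end
  pmax(2L, as.integer(round(from * (to / from)^((tt - t0) / (T_end - t0)))))
}

# Build the engine schedule (size matrix, founding events, migrations) for a
# demography object.  Columns of `sizes` index generations 0..T; founding
# events fire when the new deme's first generation is produced.
build_schedule <- function(model, burn_mult = 10) {
  if (inherits(model, "imc_demography")) {
    T_burn <- as.integer(ceiling(burn_mult * model$N_anc))
    T_end <- T_burn + model$T_div2
    t_in <- T_end - model$T_div2 + 1L   # first generation of IN
    t_off <- T_end - model$T_div1 + 1L  # first generation of NO and SO
    sizes <- matrix(0L, nrow = 4, ncol = T_end + 1)
    rownames(sizes) <- c("ANC", "IN", "NO", "SO")
    if (model$constant_ne) {
      n2 <- max(2L, as.integer(round(model$N_anc / 2)))
      n3 <- max(2L, as.integer(round(model$N_anc / 3)))
      sizes["ANC", 1:t_in] <- model$N_anc
      sizes["ANC", (t_in + 1):t_off] <- n2
      sizes["IN", (t_in + 1):(T_end + 1)] <-
        c(rep(n2, t_off - t_in), rep(n3, T_end - t_off + 1))
      sizes["NO", (t_off + 1):(T_end + 1)] <- n3
      sizes["SO", (t_off + 1):(T_end + 1)] <- n3
    } else {
      sizes["ANC", 1:t_in] <- model$N_anc
      sizes["ANC", (t_in + 1):t_off] <- model$N_offanc
      sizes["IN", (t_in + 1):(T_end + 1)] <-
        exp_schedule(model$N_founder_IN, model$N_cur_IN, t_in, T_end)
      sizes["NO", (t_off + 1):(T_end + 1)] <-
        exp_schedule(model$N_founder_NO, model$N_cur_NO, t_off, T_end)
      sizes["SO", (t_off + 1):(T_end + 1)] <-
        exp_schedule(model$N_founder_SO, model$N_cur_SO, t_off, T_end)
    }
    founders <- rbind(c(t_in, 1L, 0L),   # IN buds from ANC
                      c(t_off, 2L, 0L),  # NO from offshore ancestor
                      c(t_off, 3L, 0L))  # SO from offshore ancestor
    r_off <- numeric(T_end); r_off[t_off:T_end] <- model$m_off
    r_sec <- numeric(T_end)
    if (model$T_sec > 0) r_sec[(T_end - model$T_sec + 1):T_end] <- model$m_sec
    migrations <- list(list(a = 2L, b = 3L, rates = r_off),
                       list(a = 1L, b = 2L, rates = r_sec),
                       list(a = 1L, b = 3L, rates = r_sec))
    list(sizes = sizes, founders = founders, migrations = migrations,
         T_end = T_end, demes = c("IN", "NO", "SO"), deme_idx = 1:3,
         L = model$L, mu = model$mu, rec = model$rec,
         n_scaffolds = model$n_scaffolds)
  } else if (inherits(model, "simple_demography")) {
    if (model$kind == "constant") {
      T_end <- as.integer(ceiling(burn_mult * model$N))
      sizes <- matrix(as.integer(model$N), nrow = 1, ncol = T_end + 1)
      list(sizes = sizes, founders = matrix(integer(0), ncol = 3),
           migrations = list(), T_end = T_end, demes = "POP1",
           deme_idx = 0L, L = model$L, mu = model$mu, rec = model$rec,
           n_scaffolds = model$n_scaffolds)
    } else if (model$kind == "split") {
      T_burn <- as.integer(ceiling(burn_mult * model$N))
      T_end <- T_burn + as.integer(model$T_split)
      t_sp <- T_burn + 1L  # first generation of the daughter demes
      sizes <- matrix(0L, nrow = 3, ncol = T_end + 1)
      sizes[1, 1:t_sp] <- as.integer(model$N)  # ancestor through gen T_burn
      sizes[2, (t_sp + 1):(T_end + 1)] <- as.integer(model$N1)
      sizes[3, (t_sp + 1):(T_end + 1)] <- as.integer(model$N2)
      founders <- rbind(c(t_sp, 1L, 0L), c(t_sp, 2L, 0L))
      rates <- numeric(T_end); rates[t_sp:T_end] <- model$m
      list(sizes = sizes, founders = founders,
           migrations = list(list(a = 1L, b = 2L, rates = rates)),
           T_end = T_end, demes = c("POP1", "POP2"), deme_idx = 1:2,
           L = model$L, mu = model$mu, rec = model$rec,
           n_scaffolds = model$n_scaffolds)
    } else {  # expansion
      T_burn <- as.integer(ceiling(burn_mult * model$N))
      T_end <- T_burn + as.integer(model$T_bot)
      t_bot <- T_burn + 1L  # first post-collapse generation
      traj <- exp_schedule(model$N_bot, model$N_cur, t_bot, T_end)
      sizes <- matrix(0L, nrow = 1, ncol = T_end + 1)
      sizes[1, 1:t_bot] <- as.integer(model$N)
      sizes[1, (t_bot + 1):(T_end + 1)] <- traj
      list(sizes = sizes, founders = matrix(integer(0), ncol = 3),
           migrations = list(), T_end = T_end, demes = "POP1",
           deme_idx = 0L, L = model$L, mu = model$mu, rec = model$rec,
           n_scaffolds = model$n_scaffolds)
    }
  } else {
    stop("unknown demography object")
  }
}
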