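# fixtures and independent brute-force oracles used across test files

# quick panel builder: hm rows are haplotypes (2 per sample)
make_panel <- function(hm, pos = seq_len(ncol(hm)) * 100L,
                       pops = rep("P1", nrow(hm) / 2),
                       scaffold = "scf1", polarized = TRUE) {
  n <- nrow(hm) / 2
  haplotype_panel(scaffold_id = scaffold, positions = pos, hap_matrix = hm,
                  sample_ids = sprintf("s%02d", seq_len(n)),
                  pop_labels = pops, polarized = polarized)
}

rand_hap <- function(n_hap, n_site, seed, p = 0.3) {
  set.seed(seed)
  matrix(rbinom(n_hap * n_site, 1, p), nrow = n_hap)
}

# mean pairwise difference per site pair-enumeration oracle (sums over all
# haplotype pairs), returns the window pi numerator
bf_pi_sum <- function(hm) {
  n <- nrow(hm)
  tot <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    tot <- tot + sum(hm[i, ] != hm[j, ])
  tot / choose(n, 2)
}

# Hudson per-site components by explicit pair enumeration:
# denominator = between-pop difference probability, numerator = that minus
# the mean within-pop difference probability (pairs without replacement)
bf_hudson_site <- function(col1, col2) {
  hw <- function(x) {
    n <- length(x)
    d <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n) d <- d + (x[i] != x[j])
    d / choose(n, 2)
  }
  hb <- mean(outer(col1, col2, "!="))
  c(num = hb - (hw(col1) + hw(col2)) / 2, den = hb)
}

# EHH by explicit pair enumeration over the inclusive marker range
bf_ehh <- function(hm, carriers, core, marker) {
  rng <- min(core, marker):max(core, marker)
  n <- length(carriers)
  same <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    same <- same + all(hm[carriers[i], rng] == hm[carriers[j], rng])
  same / choose(n, 2)
}

# iHH oracle: walk out in both directions evaluating the pair-enumeration
# EHH at each marker, trapezoid over physical distance, truncating at the
# first marker with EHH < cutoff (that trapezoid included); complete = FALSE
# when an edge or max_extend is hit while still at or above the cutoff
bf_ihh <- function(hm, pos, carriers, core, cutoff = 0.05,
                   max_extend = Inf, by_core = FALSE) {
  ihh <- 0
  complete <- TRUE
  e0 <- if (by_core) bf_ehh(hm, carriers, core, core) else 1
  for (dir in c(-1, 1)) {
    e_prev <- e0
    if (e_prev < cutoff) next
    x_prev <- pos[core]
    m <- core + dir
    repeat {
      if (m < 1 || m > ncol(hm) || abs(pos[m] - pos[core]) > max_extend) {
        complete <- FALSE
        break
      }
      e <- bf_ehh(hm, carriers, core, m)
      ihh <- ihh + 0.5 * (e_prev + e) * abs(pos[m] - x_prev)
      if (e < cutoff) break
      e_prev <- e
      x_prev <- pos[m]
      m <- m + dir
    }
  }
  list(ihh = ihh, complete = complete)
}

# mean pairwise identity length (marker units) by direct per-pair runs
bf_sl <- function(hm, carriers, core, max_sites = 1000) {
  n <- length(carriers)
  S <- ncol(hm)
  tot <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    a <- hm[carriers[i], ]
    b <- hm[carriers[j], ]
    if (a[core] != b[core]) next
    len <- 1
    m <- core - 1
    while (m >= 1 && core - m <= max_sites && a[m] == b[m]) {
      len <- len + 1
      m <- m - 1
    }
    m <- core + 1
    while (m <= S && m - core <= max_sites && a[m] == b[m]) {
      len <- len + 1
      m <- m + 1
    }
    tot <- tot + len
  }
  tot / choose(n, 2)
}

# exhaustive hypergeometric upper tail
bf_hyper_tail <- function(k, K, N, n) {
  if (k > min(K, n)) return(0)
  sum(vapply(k:min(K, n), function(x)
    choose(K, x) * choose(N - K, n - x), numeric(1))) / choose(N, n)
}

# simulated read set: uniform random fragments of a source sequence with
# substitution noise
sim_reads <- function(source_seq, n_reads, read_len = 100, error = 0.01,
                      seed = 1) {
  set.seed(seed)
  L <- nchar(source_seq)
  starts <- sample(L - read_len + 1, n_reads, replace = TRUE)
  reads <- substring(source_seq, starts, starts + read_len - 1)
  if (error > 0) {
    reads <- vapply(reads, function(r) {
      ch <- strsplit(r, "")[[1]]
      mut <- which(runif(length(ch)) < error)
      if (length(mut))
        ch[mut] <- sample(c("A", "C", "G", "T"), length(mut), replace = TRUE)
      paste(ch, collapse = "")
    }, character(1), USE.NAMES = FALSE)
  }
  reads
}

rand_dna <- function(len, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
        collapse = "")
}
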