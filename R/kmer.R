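#' Canonical k-mer profile of a read set
#'
#' Counts canonical k-mers (lexicographic minimum of a word and its reverse
#' complement; `k` must be odd so canonicalization is unambiguous) across
#' FASTA/FASTQ reads, skipping words containing non-ACGT characters, and
#' fits an order-0 background of nucleotide frequencies from the counted
#' read bases.
#'
#' @param reads path to a FASTA/FASTQ file (gzip accepted), or a
#'   `DNAStringSet`/character vector of read sequences.
#' @param k odd word length.
#' @return object of class `kmer_profile`: `k`, `counts` (named integer),
#'   `n_words`, `background` (ACGT frequencies).
#' @export
count_kmers <- function(reads, k = 21) {
  if (k %% 2 != 1) stop("k must be odd")
  if (is.character(reads) && length(reads) == 1 && file.exists(reads)) {
    fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", reads, ignore.case = TRUE))
      "fastq" else "fasta"
    reads <- Biostrings::readDNAStringSet(reads, format = fmt)
  }
  seqs <- toupper(as.character(reads))
  if (!length(seqs)) stop("empty input: no reads")
  if (all(nchar(seqs) < k))
    stop("k = ", k, " exceeds every read length")
  words <- unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    substring(s, 1:(n - k + 1), k:n)
  }), use.names = FALSE)
  words <- words[!grepl("[^ACGT]", words)]
  if (!length(words)) stop("no valid ACGT k-mers in input")
  canon <- canonical_kmer(words)
  counts <- table(canon)
  bases <- unlist(strsplit(paste(seqs, collapse = ""), ""), use.names = FALSE)
  bases <- bases[bases %in% c("A", "C", "G", "T")]
  bg <- table(factor(bases, levels = c("A", "C", "G", "T")))
  structure(list(k = k,
                 counts = stats::setNames(as.integer(counts), names(counts)),
                 n_words = length(canon),
                 background = as.numeric(bg) / sum(bg)),
            class = "kmer_profile")
}

# canonical form: min(word, reverse complement)
canonical_kmer <- function(words) {
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(words)))
  ifelse(words <= rc, words, rc)
}

# expected probability of a canonical word under an order-0 background:
# product of base probabilities of the word plus that of its reverse
# complement (odd k, so the two are always distinct)
canonical_word_prob <- function(words, background) {
  p <- stats::setNames(background, c("A", "C", "G", "T"))
  prob_of <- function(w) {
    k <- nchar(w[1])
    lp <- numeric(length(w))
    for (i in seq_len(k)) lp <- lp + log(p[substr(w, i, i)])
    exp(lp)
  }
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(words)))
  unname(prob_of(words) + prob_of(rc))
}

#' d2s dissimilarity between two k-mer profiles
#'
#' Counts are centered against each profile's own order-0 background
#' (`X~_w = X_w - n_words * p_w`); the statistic is
#' `D2S = sum X~_w Y~_w / sqrt(X~_w^2 + Y~_w^2)` over words observed in
#' either profile, normalized to a dissimilarity
#' `d2s = 0.5 (1 - D2S / sqrt(A * B))` with
#' `A = sum X~_w^2 / sqrt(X~_w^2 + Y~_w^2)` and symmetrically `B`.
#' Identity gives 0 exactly; values lie in `[0, 1]`.
#'
#' @param x,y `kmer_profile` objects with the same `k`.
#' @return dissimilarity in `[0, 1]`.
#' @export
d2s_distance <- function(x, y) {
  stopifnot(inherits(x, "kmer_profile"), inherits(y, "kmer_profile"))
  if (x$k != y$k) stop("profiles have different k (", x$k, " vs ", y$k, ")")
  words <- union(names(x$counts), names(y$counts))
  cx <- x$counts[words]; cx[is.na(cx)] <- 0
  cy <- y$counts[words]; cy[is.na(cy)] <- 0
  xt <- as.numeric(cx) - x$n_words * canonical_word_prob(words, x$background)
  yt <- as.numeric(cy) - y$n_words * canonical_word_prob(words, y$background)
  denom <- sqrt(xt^2 + yt^2)
  keep <- denom > 0
  if (!any(keep)) stop("all centered counts are zero")
  d2s_num <- sum(xt[keep] * yt[keep] / denom[keep])
  a <- sum(xt[keep]^2 / denom[keep])
  b <- sum(yt[keep]^2 / denom[keep])
  0.5 * (1 - d2s_num / sqrt(a * b))
}

#' Pairwise d2s distance matrix
#'
#' @param profiles named list of `kmer_profile`.
#' @return symmetric matrix with zero diagonal.
#' @export
d2s_matrix <- function(profiles) {
  n <- length(profiles)
  m <- matrix(0, n, n, dimnames = list(names(profiles), names(profiles)))
  if (n >= 2)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      d <- d2s_distance(profiles[[i]], profiles[[j]])
      m[i, j] <- d
      m[j, i] <- d
    }
  m
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centers the squared distance matrix and embeds the top `dims`
#' spectral coordinates; the sign of each axis is fixed so its
#' largest-magnitude loading is positive.  Warns when more than half of the
#' eigenvalue mass is negative (strongly non-Euclidean input).
#'
#' @param d symmetric distance matrix with zero diagonal (or `dist`).
#' @param dims embedding dimension.
#' @return matrix of coordinates (samples x dims).
#' @export
classical_mds <- function(d, dims = 2) {
  m <- as.matrix(d)
  if (any(abs(m - t(m)) > 1e-12)) stop("distance matrix must be symmetric")
  if (any(abs(diag(m)) > 1e-12)) stop("distance matrix diagonal must be 0")
  if (all(m == 0))
    return(matrix(0, nrow(m), dims, dimnames = list(rownames(m), NULL)))
  fit <- stats::cmdscale(m, k = dims, eig = TRUE)
  ev <- fit$eig
  neg_mass <- sum(abs(ev[ev < 0])) / max(sum(abs(ev)), .Machine$double.eps)
  if (neg_mass > 0.5)
    warning("more than half of the eigenvalue mass is negative; ",
            "input is far from Euclidean")
  coords <- fit$points
  if (is.null(dim(coords)) || ncol(coords) < dims) {
    pad <- matrix(0, nrow(m), dims - NCOL(coords))
    coords <- cbind(coords, pad)
  }
  for (j in seq_len(ncol(coords))) {
    i <- which.max(abs(coords[, j]))
    if (length(i) && coords[i, j] < 0) coords[, j] <- -coords[, j]
  }
  rownames(coords) <- rownames(m)
  coords
}
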