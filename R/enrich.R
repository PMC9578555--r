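#' Read a gene -> GO map
#'
#' Two tab-separated columns: gene_id and a comma-separated list of GO
#' identifiers (the second column may be empty).
#'
#' @param path TSV path.
#' @return named list gene_id -> character vector of GO IDs.
#' @export
read_go_map <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                         col.names = c("gene_id", "go"),
                         colClasses = "character", fill = TRUE)
  stats::setNames(lapply(d$go, function(x)
    if (nzchar(x)) strsplit(x, ",")[[1]] else character(0)), d$gene_id)
}

#' Read gene coordinates from BED or GFF3
#'
#' BED input uses columns chrom/start/end/name; GFF3 input keeps `gene`
#' features and their `ID` attribute.  Returned ranges are named by gene id.
#'
#' @param path BED or GFF3 file.
#' @return a `GRanges` with one range per gene.
#' @export
read_genes <- function(path) {
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  gr <- rtracklayer::import(path)
  if (ext %in% c("gff", "gff3", "gtf")) {
    gr <- gr[gr$type == "gene"]
    names(gr) <- gr$ID
  } else {
    names(gr) <- gr$name
  }
  if (any(is.na(names(gr))) || any(!nzchar(names(gr))))
    stop("every gene needs an identifier (BED name / GFF3 ID)")
  gr
}

#' Parse is_a parent relations from an OBO ontology file
#'
#' Minimal OBO reader: `[Term]` stanzas, `id:` and `is_a:` lines.  Used
#' only for ancestor propagation of GO annotations.
#'
#' @param path OBO file.
#' @return named list: term id -> character vector of direct parents.
#' @export
read_obo_parents <- function(path) {
  lines <- readLines(path, warn = FALSE)
  parents <- list()
  cur <- NULL
  for (ln in lines) {
    if (startsWith(ln, "[")) cur <- NULL
    if (startsWith(ln, "id: ")) {
      cur <- sub("^id: ", "", ln)
      if (is.null(parents[[cur]])) parents[[cur]] <- character(0)
    } else if (startsWith(ln, "is_a: ") && !is.null(cur)) {
      parents[[cur]] <- c(parents[[cur]],
                          sub(" !.*$", "", sub("^is_a: ", "", ln)))
    }
  }
  parents
}

# expand each gene's term set with all ancestors under the parent relation
propagate_terms <- function(go_map, parents) {
  closure <- new.env(parent = emptyenv())
  anc <- function(tm) {
    if (!is.null(closure[[tm]])) return(closure[[tm]])
    closure[[tm]] <- tm  # break cycles defensively
    up <- parents[[tm]]
    out <- tm
    for (p in up) out <- union(out, anc(p))
    closure[[tm]] <- out
    out
  }
  lapply(go_map, function(terms) unique(unlist(lapply(terms, anc))))
}

# one-sided upper-tail Fisher p for a 2x2 target/background table:
# P(X >= k) with K annotated among N background units, n targets drawn
fisher_upper <- function(k, K, N, n) {
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Gene-level GO enrichment (Fisher's exact test)
#'
#' One-sided hypergeometric upper-tail test per term, target genes versus
#' all annotated background genes.  A term is reported significant when
#' `p < p_cut` and it is supported by at least `min_regions` distinct sweep
#' regions (when region support is supplied).
#'
#' @param target_genes character vector of target gene ids.
#' @param background_genes character vector of all annotated gene ids.
#' @param go_map named list gene -> GO terms (see [read_go_map()]).
#' @param gene_regions optional named list gene -> vector of region ids, for
#'   the distinct-sweep-region support count.
#' @param ontology optional parent map from [read_obo_parents()]; when
#'   supplied, annotations are propagated to ancestor terms first
#'   (off by default).
#' @param p_cut significance cutoff on the raw p-value.
#' @param min_regions minimum distinct supporting sweep regions.
#' @return data frame of class `enrichment_result`, one row per term, sorted
#'   by p; includes a Benjamini-Hochberg column for information only.
#' @export
gene_enrichment <- function(target_genes, background_genes, go_map,
                            gene_regions = NULL, p_cut = 0.005,
                            min_regions = 2, ontology = NULL) {
  if (!length(background_genes)) stop("empty background gene set")
  if (!is.null(ontology)) go_map <- propagate_terms(go_map, ontology)
  if (!all(target_genes %in% background_genes))
    stop("target genes must be a subset of the background")
  terms_of <- function(g) unique(unlist(go_map[intersect(g, names(go_map))]))
  all_terms <- terms_of(background_genes)
  N <- length(unique(background_genes))
  n <- length(unique(target_genes))
  res <- do.call(rbind, lapply(all_terms, function(tm) {
    with_term <- names(go_map)[vapply(go_map, function(x) tm %in% x,
                                      logical(1))]
    K <- length(intersect(with_term, background_genes))
    k <- length(intersect(with_term, target_genes))
    supp <- if (!is.null(gene_regions))
      length(unique(unlist(gene_regions[intersect(with_term, target_genes)])))
    else NA_integer_
    data.frame(term = tm, n_target_units = n, n_target_with_term = k,
               n_background_units = N, n_background_with_term = K,
               odds_ratio = (k * (N - K - n + k)) / max(1e-300,
                                                        (n - k) * (K - k)),
               p = fisher_upper(k, K, N, n),
               n_distinct_sweep_regions = supp,
               unit = "gene", stringsAsFactors = FALSE)
  }))
  if (is.null(res)) res <- data.frame()
  else {
    res$p_bh <- stats::p.adjust(res$p, "BH")
    res$significant <- res$p < p_cut &
      (is.na(res$n_distinct_sweep_regions) |
         res$n_distinct_sweep_regions >= min_regions)
    res <- res[order(res$p), ]
    rownames(res) <- NULL
  }
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Region-level GO enrichment (Fisher's exact test)
#'
#' Each grid region inherits every GO term of the genes it overlaps by at
#' least 1 bp (half-open intervals); the test then contrasts
#' regions-with-term among sweep regions against all grid regions.
#'
#' @param sweep_regions data frame with `scaffold_id`, `start`, `end`
#'   (0-based half-open); must be a subset of the grid.
#' @param grid the genome-wide region grid ([make_windows()]).
#' @param genes `GRanges` of genes named by gene id.
#' @param go_map named list gene -> GO terms.
#' @param p_cut significance cutoff on the raw p-value.
#' @param ontology optional parent map from [read_obo_parents()] for
#'   ancestor propagation (off by default).
#' @return data frame of class `enrichment_result`, one row per term.
#' @export
region_enrichment <- function(sweep_regions, grid, genes, go_map,
                              p_cut = 0.005, ontology = NULL) {
  if (!nrow(grid)) stop("empty region grid")
  if (!is.null(ontology)) go_map <- propagate_terms(go_map, ontology)
  known <- genes[as.character(GenomicRanges::seqnames(genes)) %in%
                   unique(grid$scaffold_id)]
  if (length(known) < length(genes))
    warning(length(genes) - length(known),
            " gene(s) on scaffolds absent from the grid were ignored")
  gr_grid <- GenomicRanges::GRanges(grid$scaffold_id,
                                    IRanges::IRanges(grid$start + 1,
                                                     grid$end))
  ov <- GenomicRanges::findOverlaps(gr_grid, known)
  region_terms <- vector("list", nrow(grid))
  sp <- split(names(known)[S4Vectors::subjectHits(ov)],
              S4Vectors::queryHits(ov))
  for (q in names(sp))
    region_terms[[as.integer(q)]] <-
      unique(unlist(go_map[intersect(sp[[q]], names(go_map))]))
  key <- paste(grid$scaffold_id, grid$start, grid$end)
  skey <- paste(sweep_regions$scaffold_id, sweep_regions$start,
                sweep_regions$end)
  if (!all(skey %in% key))
    stop("sweep regions must be windows of the supplied grid")
  is_sweep <- key %in% skey
  all_terms <- unique(unlist(region_terms))
  N <- nrow(grid)
  n <- sum(is_sweep)
  res <- do.call(rbind, lapply(all_terms, function(tm) {
    has <- vapply(region_terms, function(x) tm %in% x, logical(1))
    K <- sum(has)
    k <- sum(has & is_sweep)
    data.frame(term = tm, n_target_units = n, n_target_with_term = k,
               n_background_units = N, n_background_with_term = K,
               odds_ratio = (k * (N - K - n + k)) / max(1e-300,
                                                        (n - k) * (K - k)),
               p = fisher_upper(k, K, N, n),
               n_distinct_sweep_regions = k,
               unit = "region", stringsAsFactors = FALSE)
  }))
  if (is.null(res))
    res <- data.frame(term = character(0), p = numeric(0))
  else {
    res$p_bh <- stats::p.adjust(res$p, "BH")
    res$significant <- res$p < p_cut
    res <- res[order(res$p), ]
    rownames(res) <- NULL
  }
  class(res) <- c("enrichment_result", "data.frame")
  res
}
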