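#' Phased haplotype panel
#'
#' The central container: a binary haplotype matrix for one scaffold with
#' 1-based positions, sample identifiers and population labels.  Rows are
#' haplotypes in sample order, two per sample (left then right phase slot);
#' when `polarized` is `TRUE` a 1 codes the derived allele, otherwise it
#' codes ALT relative to REF.  Missing alleles are `NA`.
#'
#' @param scaffold_id scaffold name.
#' @param positions strictly increasing 1-based bp coordinates.
#' @param hap_matrix `2*n_samples x n_sites` matrix of 0/1/`NA`.
#' @param sample_ids character vector, one per sample.
#' @param pop_labels population label per sample.
#' @param polarized is allele 1 the derived allele?
#' @return an object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(scaffold_id, positions, hap_matrix, sample_ids,
                            pop_labels, polarized = FALSE) {
  hap_matrix <- as.matrix(hap_matrix)
  storage.mode(hap_matrix) <- "integer"
  n <- length(sample_ids)
  if (nrow(hap_matrix) != 2 * n)
    stop("hap_matrix must have 2 * n_samples rows")
  if (ncol(hap_matrix) != length(positions))
    stop("hap_matrix must have one column per position")
  if (length(pop_labels) != n)
    stop("every sample needs exactly one population label")
  if (length(positions) && any(diff(positions) <= 0))
    stop("positions must be strictly increasing")
  vals <- hap_matrix[!is.na(hap_matrix)]
  if (length(vals) && !all(vals %in% c(0L, 1L)))
    stop("hap_matrix entries must be 0, 1 or NA")
  structure(list(scaffold_id = as.character(scaffold_id),
                 positions = as.integer(positions),
                 hap_matrix = hap_matrix,
                 sample_ids = as.character(sample_ids),
                 pop_labels = as.character(pop_labels),
                 polarized = isTRUE(polarized)),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("haplotype_panel: %s | %d samples (%d haplotypes) x %d sites | %spolarized\n",
              x$scaffold_id, length(x$sample_ids), nrow(x$hap_matrix),
              ncol(x$hap_matrix), if (x$polarized) "" else "not "))
  cat("populations:", paste(sprintf("%s=%d", names(table(x$pop_labels)),
                                    table(x$pop_labels)), collapse = " "), "\n")
  invisible(x)
}

# haplotype-row population labels (two rows per sample)
hap_pops <- function(panel) rep(panel$pop_labels, each = 2)

#' Load phased haplotypes from a VCF and a population map
#'
#' Reads a VCF of biallelic SNPs plus a two-column tab-separated population
#' map (`sample_id<TAB>population`) and returns one [haplotype_panel()] per
#' scaffold.  Ancestral polarization comes from the `INFO/AA` field when
#' `ancestral_source = "info_aa"` (sites whose AA matches neither allele stay
#' REF-coded and the panel is marked unpolarized); `"ref"` treats REF as
#' ancestral everywhere.
#'
#' @param vcf_path path to a VCF (4.x) with GT fields.
#' @param popmap_path path to the population map TSV.
#' @param require_phased error on any unphased genotype (default); when
#'   `FALSE`, unphased heterozygotes get `NA` alleles.
#' @param ancestral_source `"info_aa"` or `"ref"`.
#' @return a named list of `haplotype_panel`, one per scaffold.
#' @export
load_panel <- function(vcf_path, popmap_path,
                       require_phased = TRUE,
                       ancestral_source = c("info_aa", "ref")) {
  ancestral_source <- match.arg(ancestral_source)
  popmap <- utils::read.table(popmap_path, sep = "\t", header = FALSE,
                              col.names = c("sample_id", "population"),
                              stringsAsFactors = FALSE)
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  multi <- nchar(ref) != 1 | nchar(alt) != 1 | grepl(",", alt)
  if (any(multi))
    stop("multiallelic or non-SNP site at ", fix[which(multi)[1], "CHROM"],
         ":", fix[which(multi)[1], "POS"])
  gt <- vcfR::extract.gt(vcf, element = "GT")
  samples <- colnames(gt)
  missing_map <- setdiff(samples, popmap$sample_id)
  if (length(missing_map))
    stop("sample(s) missing from popmap: ",
         paste(missing_map, collapse = ", "))
  pops <- popmap$population[match(samples, popmap$sample_id)]

  unphased <- !is.na(gt) & grepl("/", gt, fixed = TRUE)
  if (require_phased && any(unphased)) {
    w <- which(unphased, arr.ind = TRUE)[1, ]
    stop("unphased genotype for sample ", samples[w[2]], " at ",
         fix[w[1], "CHROM"], ":", fix[w[1], "POS"])
  }

  aa <- toupper(vcfR::extract.info(vcf, element = "AA"))
  chroms <- fix[, "CHROM"]
  out <- list()
  for (chr in unique(chroms)) {
    idx <- which(chroms == chr)
    pos <- as.integer(fix[idx, "POS"])
    o <- order(pos)
    idx <- idx[o]; pos <- pos[o]
    # 2 rows per sample: left and right phase slot
    hm <- matrix(NA_integer_, nrow = 2 * length(samples), ncol = length(idx))
    for (j in seq_along(samples)) {
      g <- gt[idx, j]
      a1 <- suppressWarnings(as.integer(substr(g, 1, 1)))
      a2 <- suppressWarnings(as.integer(substr(g, 3, 3)))
      het_unphased <- unphased[idx, j] & !is.na(a1) & !is.na(a2) & a1 != a2
      a1[het_unphased] <- NA_integer_
      a2[het_unphased] <- NA_integer_
      hm[2 * j - 1, ] <- a1
      hm[2 * j, ] <- a2
    }
    polarized <- FALSE
    if (ancestral_source == "info_aa" && !all(is.na(aa))) {
      aa_chr <- aa[idx]
      resolves <- !is.na(aa_chr) & (aa_chr == ref[idx] | aa_chr == alt[idx])
      if (all(resolves)) {
        flip <- aa_chr == alt[idx]
        hm[, flip] <- 1L - hm[, flip]
        polarized <- TRUE
      } else {
        warning(sum(!resolves), " site(s) on ", chr,
                " lack a usable INFO/AA; falling back to REF-as-ancestral ",
                "coding and leaving the panel unpolarized")
      }
    }
    out[[chr]] <- haplotype_panel(scaffold_id = chr, positions = pos,
                                  hap_matrix = hm, sample_ids = samples,
                                  pop_labels = pops, polarized = polarized)
  }
  out
}

#' Write a haplotype panel as VCF + population map
#'
#' Emits a minimal VCF 4.2 with phased GT fields and an `INFO/AA` ancestral
#' allele annotation (REF is written as the 0 allele, so `AA=REF` for a
#' polarized panel), plus the matching `sample<TAB>population` map.
#' Re-loading with [load_panel()] reproduces the panel exactly.
#'
#' @param panel a [haplotype_panel()].
#' @param vcf_path,popmap_path output paths.
#' @return invisibly, `vcf_path`.
#' @export
write_panel <- function(panel, vcf_path, popmap_path = NULL) {
  stopifnot(inherits(panel, "haplotype_panel"))
  n <- length(panel$sample_ids)
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s>", panel$scaffold_id),
           "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", panel$sample_ids), collapse = "\t"))
  hm <- panel$hap_matrix
  gt_chr <- matrix(as.character(hm), nrow = nrow(hm))
  gt_chr[is.na(gt_chr)] <- "."
  gts <- matrix("", nrow = ncol(hm), ncol = n)
  for (j in seq_len(n))
    gts[, j] <- paste0(gt_chr[2 * j - 1, ], "|", gt_chr[2 * j, ])
  info <- if (panel$polarized) "AA=A" else "."
  body <- paste(panel$scaffold_id, panel$positions, ".", "A", "T", ".",
                "PASS", info, "GT",
                apply(gts, 1, paste, collapse = "\t"), sep = "\t")
  if (ncol(hm) == 0) body <- character(0)
  writeLines(c(hdr, body), vcf_path)
  if (!is.null(popmap_path))
    utils::write.table(data.frame(panel$sample_ids, panel$pop_labels),
                       popmap_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  invisible(vcf_path)
}

#' Per-site per-population derived-allele counts
#'
#' @param panel a [haplotype_panel()].
#' @param pops populations to tabulate (default: all in the panel).
#' @return a list with matrices `derived` and `called` (sites x populations)
#'   and the numeric `freq` = derived/called.
#' @export
pop_allele_counts <- function(panel, pops = unique(panel$pop_labels)) {
  hp <- hap_pops(panel)
  hm <- panel$hap_matrix
  derived <- vapply(pops, function(p)
    colSums(hm[hp == p, , drop = FALSE], na.rm = TRUE),
    numeric(ncol(hm)))
  called <- vapply(pops, function(p)
    colSums(!is.na(hm[hp == p, , drop = FALSE])),
    numeric(ncol(hm)))
  if (ncol(hm) == 1) {
    derived <- matrix(derived, nrow = 1, dimnames = list(NULL, pops))
    called <- matrix(called, nrow = 1, dimnames = list(NULL, pops))
  }
  list(derived = derived, called = called, freq = derived / called)
}
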