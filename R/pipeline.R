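#' Run the full analysis pipeline from a config file
#'
#' Reads a YAML configuration, obtains data (either simulated under the
#' built-in demographic model or loaded from a VCF + population map), and
#' runs the requested stages: window diversity statistics, the EHH-based
#' sweep scan, PBS threshold calibration and overlap, region-level GO
#' enrichment and the k-mer d2s module.  All outputs are plain-text tables
#' (TSV / BED) under `out_dir`; given the same config and seed the run is
#' deterministic.
#'
#' Recognized top-level keys: `out_dir`, `seed`, `simulate`, `input`,
#' `stats`, `ehh`, `scan`, `enrich`, `kmer`.  Unknown keys raise an error
#' naming them.
#'
#' @param config_path path to the YAML config.
#' @return invisibly, a list with the main in-memory results and the output
#'   directory.
#' @export
run_pipeline <- function(config_path) {
  cfg <- yaml::read_yaml(config_path)
  allowed <- c("out_dir", "seed", "simulate", "input", "stats", "ehh",
               "scan", "enrich", "kmer")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  out_dir <- cfg$out_dir %||% "hapsweep_out"
  seed <- cfg$seed %||% 1

  # fail on missing inputs before any computation starts
  for (f in c(cfg$input$vcf, cfg$input$popmap, cfg$enrich$genes,
              cfg$enrich$go_map, unlist(cfg$kmer$reads)))
    if (!is.null(f) && !file.exists(f)) stop("input file not found: ", f)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("hapsweep %s",
                         as.character(utils::packageVersion("hapsweep"))),
                 sprintf("R %s", getRversion()),
                 sprintf("seed %s", seed),
                 sprintf("config %s", config_path))
  results <- list(out_dir = out_dir)

  model <- NULL
  if (!is.null(cfg$simulate)) {
    sim_args <- cfg$simulate
    mod_args <- sim_args$model %||% list()
    model <- do.call(demography_imc, mod_args)
    sel <- NULL
    if (!is.null(sim_args$selection))
      sel <- do.call(selection_spec, sim_args$selection)
    sim <- wf_simulate(model, n_per_pop = sim_args$n_per_pop %||% 20,
                       selection = sel, seed = seed)
    panels <- sim$panels
    if (!is.null(sim$sweep_truth))
      write_tsv(sim$sweep_truth, file.path(out_dir, "sweep_truth.tsv"))
    for (p in panels)
      write_panel(p, file.path(out_dir, paste0(p$scaffold_id, ".vcf")),
                  file.path(out_dir, "popmap.tsv"))
    log_lines <- c(log_lines, "data: simulated")
  } else if (!is.null(cfg$input)) {
    panels <- load_panel(cfg$input$vcf, cfg$input$popmap,
                         require_phased = cfg$input$require_phased %||% TRUE,
                         ancestral_source =
                           cfg$input$ancestral_source %||% "info_aa")
    log_lines <- c(log_lines, sprintf("data: %s", cfg$input$vcf))
  } else {
    stop("config needs either a 'simulate' or an 'input' section")
  }
  pops <- unique(panels[[1]]$pop_labels)
  lens <- stats::setNames(
    vapply(panels, function(p)
      if (!is.null(model)) model$L else max(p$positions), numeric(1)),
    vapply(panels, function(p) p$scaffold_id, character(1)))

  if (!is.null(cfg$stats) && isTRUE(cfg$stats$run %||% TRUE)) {
    st <- cfg$stats
    grid_d <- make_windows(lens, st$window_size %||% 1e4, st$step %||% 2e3)
    tables <- lapply(panels, window_diversity, pops = pops, grid = grid_d)
    stats_df <- do.call(rbind, lapply(tables, `[[`, "stats"))
    dxy_df <- do.call(rbind, lapply(tables, `[[`, "dxy"))
    write_tsv(stats_df, file.path(out_dir, "window_stats.tsv"))
    write_tsv(dxy_df, file.path(out_dir, "window_dxy.tsv"))
    if (length(pops) >= 2) {
      pr <- utils::combn(pops, 2)
      fst_df <- do.call(rbind, lapply(seq_len(ncol(pr)), function(k) {
        vals <- vapply(panels, function(p) {
          ac <- pop_allele_counts(p, pr[, k])
          hudson_fst(ac$derived[, 1], ac$called[, 1],
                     ac$derived[, 2], ac$called[, 2])$fst_overall
        }, numeric(1))
        data.frame(pop1 = pr[1, k], pop2 = pr[2, k],
                   fst = stats::weighted.mean(vals,
                                              vapply(panels, function(p)
                                                length(p$positions),
                                                numeric(1))))
      }))
      write_tsv(fst_df, file.path(out_dir, "fst_pairs.tsv"))
      results$fst <- fst_df
    }
    results$window_stats <- stats_df
  }

  if (!is.null(cfg$scan) && isTRUE(cfg$scan$run %||% TRUE) &&
      length(pops) >= 2) {
    sc <- cfg$scan
    eh <- cfg$ehh %||% list()
    grid50 <- make_windows(lens, sc$window_size %||% 5e4,
                           sc$step %||% sc$window_size %||% 5e4)
    scan_res <- sweep_scan(panels, pops, grid50,
                           maf_min = eh$maf_min %||% 0.05,
                           ehh_cutoff = eh$ehh_cutoff %||% 0.05,
                           max_extend = eh$max_extend %||% 1e6,
                           min_snps = sc$min_snps %||% 10,
                           top_fraction = sc$top_fraction %||% 0.01)
    write_tsv(scan_res$scores, file.path(out_dir, "ehh_scores.tsv"))
    regions <- scan_res$regions
    if (length(pops) == 3 && !is.null(model) &&
        (sc$calibrate %||% TRUE) && nrow(regions)) {
      neutral <- lapply(seq_len(sc$n_neutral %||% 12), function(i)
        wf_simulate(model, n_per_pop = cfg$simulate$n_per_pop %||% 20,
                    seed = seed + 1000 + i)$panels[[1]])
      thr <- lapply(pops, function(p)
        calibrate_pbs_threshold(neutral, p, fpr = sc$fpr %||% 0.01,
                                pops = pops,
                                min_snps = sc$calib_min_snps %||% 1e4))
      write_tsv(data.frame(population = pops,
                           threshold = vapply(thr, `[[`, numeric(1),
                                              "threshold"),
                           n_snps = vapply(thr, `[[`, numeric(1),
                                           "n_snps")),
                file.path(out_dir, "pbs_thresholds.tsv"))
      pbs_df <- do.call(rbind, lapply(panels, function(p) {
        d <- pbs_per_snp(p, pops)
        cbind(scaffold_id = p$scaffold_id, d)
      }))
      regions <- pbs_overlap(regions, pbs_df, thr)
    }
    write_bed(regions, file.path(out_dir, "sweep_regions.bed"))
    results$regions <- regions
  }

  if (!is.null(cfg$enrich) && !is.null(cfg$enrich$genes) &&
      !is.null(results$regions) && nrow(results$regions)) {
    genes <- read_genes(cfg$enrich$genes)
    go_map <- read_go_map(cfg$enrich$go_map)
    grid50 <- make_windows(lens, cfg$scan$window_size %||% 5e4)
    enr <- region_enrichment(results$regions, grid50, genes, go_map,
                             p_cut = cfg$enrich$p_cut %||% 0.005)
    write_tsv(enr, file.path(out_dir, "region_enrichment.tsv"))
    results$enrichment <- enr
  }

  if (!is.null(cfg$kmer) && !is.null(cfg$kmer$reads)) {
    k <- cfg$kmer$k %||% 21
    prof <- lapply(cfg$kmer$reads, count_kmers, k = k)
    names(prof) <- names(cfg$kmer$reads) %||%
      basename(unlist(cfg$kmer$reads))
    dm <- d2s_matrix(prof)
    write_tsv(data.frame(sample = rownames(dm), dm, check.names = FALSE),
              file.path(out_dir, "d2s_matrix.tsv"))
    mds <- classical_mds(dm, dims = cfg$kmer$dims %||% 2)
    write_tsv(data.frame(sample = rownames(mds), mds, check.names = FALSE),
              file.path(out_dir, "d2s_mds.tsv"))
    results$d2s <- dm
  }

  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# sweep regions as BED6+: chrom, start, end, name=pop, score=1000*max_prop,
# strand=".", then stats, pbs columns
write_bed <- function(regions, path) {
  if (!nrow(regions)) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  bed <- data.frame(chrom = regions$scaffold_id,
                    start = format(regions$start, scientific = FALSE,
                                   trim = TRUE),
                    end = format(regions$end, scientific = FALSE,
                                 trim = TRUE),
                    name = regions$pop,
                    score = round(1000 * regions$max_prop),
                    strand = ".",
                    stats = regions$stats)
  if (!is.null(regions$pbs_overlap)) {
    bed$pbs_overlap <- regions$pbs_overlap
    bed$pbs_max <- regions$pbs_max
  }
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read back a sweep-region BED written by the pipeline
#'
#' @param path BED path.
#' @return data frame with the standard sweep-region columns.
#' @export
read_sweep_bed <- function(path) {
  if (file.size(path) == 0)
    return(data.frame(scaffold_id = character(0), start = numeric(0),
                      end = numeric(0), pop = character(0),
                      stats = character(0)))
  d <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  names(d)[1:7] <- c("scaffold_id", "start", "end", "pop", "score",
                     "strand", "stats")
  if (ncol(d) >= 9) names(d)[8:9] <- c("pbs_overlap", "pbs_max")
  d
}
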