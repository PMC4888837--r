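#' Run the full DamID analysis pipeline
#'
#' Orchestrates index building, per-library signal extraction, peak calling
#' per factor against the Dam-GFP control, factor co-occupancy and promoter
#' annotation, TSS metaprofiles, and (when DE tables are present) the
#' knockdown expression-concordance analysis — from one configuration.
#'
#' The configuration is a list (or the path to a YAML file) with either a
#' `simulate` block (fields of [sim_config()]) or an `inputs` block with
#' `genome` (FASTA), `genes` (BED6), `samples` (named SAM paths, one per
#' factor), `control` (SAM) and optionally `de_tables` (`a`, `b` TSV
#' paths); plus an optional `params` block with `filter`, `peaks`,
#' `promoter`, `tss` (`window`, `bin_width`) and `concordance` (`alpha`,
#' `alpha_adj`) overrides, and a `seed`.
#'
#' All stage outputs (counts TSVs, bedGraphs, peak BED/TSVs, Venn summary,
#' profile TSVs, concordance tables) are written under `out_dir`, along
#' with `manifest.json` summarizing parameters, read accounting and
#' results. An existing manifest is returned as-is unless `force` is set.
#'
#' @param config Configuration list or YAML path.
#' @param out_dir Output directory.
#' @param force Re-run even if `out_dir` already contains a manifest.
#' @param verbose Log stage progress. Default `TRUE`.
#' @return The run manifest (class `damid_manifest`), invisibly a list.
#' @export
run_damid_pipeline <- function(config, out_dir, force = FALSE,
                               verbose = TRUE) {
  if (is.character(config) && length(config) == 1L) {
    .stop_if(!file.exists(config), sprintf("config file '%s' not found", config))
    config <- yaml::read_yaml(config)
  }
  .stop_if(!is.list(config), "config must be a list or a YAML file path")
  .stop_if(is.null(config$simulate) && is.null(config$inputs),
           "malformed config: need a 'simulate' or 'inputs' block")
  if (!is.null(config$inputs)) {
    .stop_if(is.null(config$inputs$control),
             "control required for DamID peak calling")
    for (p in unlist(config$inputs)) {
      .stop_if(!file.exists(p), sprintf("input file '%s' not found", p))
    }
  }

  manifest_path <- file.path(out_dir, "manifest.json")
  if (file.exists(manifest_path) && !force) {
    .msg(verbose, "run_damid_pipeline: up-to-date manifest found, skipping (use force = TRUE to re-run)")
    man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
    class(man) <- "damid_manifest"
    return(invisible(man))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  seed <- config$seed %||% 1L
  pr <- config$params %||% list()
  fpar <- do.call(filter_params, pr$filter %||% list())
  ppar <- do.call(peak_params, pr$peaks %||% list())
  prom <- do.call(promoter_params, pr$promoter %||% list())
  tssp <- pr$tss %||% list()
  conc <- pr$concordance %||% list()
  alpha <- conc$alpha %||% 0.01
  alpha_adj <- conc$alpha_adj %||% 0.05

  # --- stage: inputs -------------------------------------------------------
  de_tables <- NULL
  if (!is.null(config$simulate)) {
    .msg(verbose, "stage simulate: generating synthetic study")
    scfg <- do.call(sim_config, c(config$simulate,
                                  if (is.null(config$simulate$seed))
                                    list(seed = seed)))
    sim <- simulate_damid_experiment(scfg, dir = file.path(out_dir, "inputs"))
    index <- sim$index
    genes <- sim$genome$genes
    libs <- sim$reads
    de_tables <- sim$de
  } else {
    .msg(verbose, "stage inputs: loading genome, genes and libraries")
    index <- gatc_index(config$inputs$genome)
    genes <- read_genes(config$inputs$genes)
    libs <- lapply(config$inputs$samples, read_sam_reads, verbose = verbose)
    libs$control <- read_sam_reads(config$inputs$control, verbose = verbose)
    if (!is.null(config$inputs$de_tables)) {
      de_tables <- list(a = load_de_table(config$inputs$de_tables$a),
                        b = load_de_table(config$inputs$de_tables$b))
    }
  }
  write_gatc_index(index, file.path(out_dir, "gatc_index.tsv"))

  # --- stage: signal -------------------------------------------------------
  accounting <- list()
  tracks <- list()
  for (f in names(libs)) {
    .msg(verbose, sprintf("stage signal: library '%s'", f))
    retained <- filter_reads(libs[[f]], index, fpar, verbose = verbose)
    counts <- count_sites(retained, index)
    tracks[[f]] <- normalize_counts(counts)
    accounting[[f]] <- list(input_total = attr(counts, "input_total"),
                            retained_total = attr(counts, "retained_total"))
    utils::write.table(
      data.frame(chrom = counts$chrom, cut_site = counts$cut_site,
                 raw_count = counts$count),
      file.path(out_dir, sprintf("counts_%s.tsv", f)),
      sep = "\t", quote = FALSE, row.names = FALSE)
    write_bedgraph(make_bedgraph(retained, index$chrom_lengths),
                   file.path(out_dir, sprintf("coverage_%s.bedgraph", f)))
  }

  # --- stage: peaks --------------------------------------------------------
  factors <- setdiff(names(libs), "control")
  peaksets <- list()
  for (f in factors) {
    .msg(verbose, sprintf("stage peaks: factor '%s'", f))
    cand <- candidate_regions(tracks[[f]], ppar, control = tracks$control)
    peaksets[[f]] <- score_and_filter(cand, tracks[[f]], tracks$control,
                                      ppar, label = f)
    write_peaks(peaksets[[f]], file.path(out_dir, sprintf("peaks_%s", f)))
  }

  # --- stage: co-occupancy and annotation ----------------------------------
  venn <- cobound <- delta <- NULL
  if (length(factors) >= 2L) {
    a <- factors[1L]; b <- factors[2L]
    .msg(verbose, sprintf("stage overlap: %s vs %s", a, b))
    venn <- overlap_peaksets(peaksets[[a]], peaksets[[b]])
    cobound <- cobound_promoter_count(venn, genes, prom)
    venn_tab <- data.frame(
      category = c(sprintf("%s_only", a), "shared", sprintf("%s_only", b),
                   "cobound_promoters"),
      count = c(venn$n_a_only, venn$n_shared, venn$n_b_only,
                as.integer(cobound)))
    utils::write.table(venn_tab, file.path(out_dir, "venn.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if ("deltaCTD" %in% factors && venn$n_shared > 0L &&
        nrow(peaksets$deltaCTD) > 0L) {
      delta <- fraction_overlap(venn, peaksets$deltaCTD)
    }
  }
  profiles <- lapply(peaksets, function(ps) {
    tss_profile(ps, genes, window = tssp$window %||% 10000L,
                bin_width = tssp$bin_width %||% 250L)
  })
  for (f in names(profiles)) {
    write_tss_profile(profiles[[f]],
                      file.path(out_dir, sprintf("tss_profile_%s.tsv", f)))
  }

  # --- stage: concordance --------------------------------------------------
  concordance <- NULL
  if (!is.null(de_tables)) {
    .msg(verbose, "stage concordance: knockdown DE tables")
    ov <- overlap_misregulated(de_tables$a, de_tables$b, alpha = alpha)
    dc <- direction_concordance(de_tables$a, de_tables$b,
                                alpha_adj = alpha_adj)
    utils::write.table(dc$pairs, file.path(out_dir, "paired_log2fc.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    concordance <- list(n_sig_a = ov$n_sig_a, n_sig_b = ov$n_sig_b,
                        n_overlap = ov$n_overlap,
                        hypergeom_p = ov$hypergeom_p,
                        universe_size = ov$universe_size,
                        frac_same_direction = dc$frac_same_direction,
                        n_compared = dc$n_compared)
  }

  man <- list(
    out_dir = out_dir,
    seed = seed,
    parameters = list(filter = unclass(fpar), peaks = unclass(ppar),
                      promoter = unclass(prom),
                      tss = list(window = tssp$window %||% 10000L,
                                 bin_width = tssp$bin_width %||% 250L),
                      concordance = list(alpha = alpha,
                                         alpha_adj = alpha_adj)),
    libraries = accounting,
    peak_counts = lapply(peaksets, nrow),
    venn = if (!is.null(venn)) list(a_only = venn$n_a_only,
                                    shared = venn$n_shared,
                                    b_only = venn$n_b_only,
                                    cobound_promoters = as.integer(cobound)),
    delta_ctd = if (!is.null(delta)) list(percent = delta$percent,
                                          n_base = delta$n_base,
                                          n_hit = delta$n_hit),
    concordance = concordance
  )
  jsonlite::write_json(man, manifest_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  class(man) <- "damid_manifest"
  invisible(man)
}

#' @export
print.damid_manifest <- function(x, ...) {
  cat("DamID pipeline run\n")
  cat(sprintf("  output: %s (seed %s)\n", x$out_dir, x$seed))
  for (f in names(x$libraries)) {
    cat(sprintf("  library %s: %s/%s reads retained\n", f,
                x$libraries[[f]]$retained_total,
                x$libraries[[f]]$input_total))
  }
  for (f in names(x$peak_counts)) {
    cat(sprintf("  peaks %s: %s\n", f, x$peak_counts[[f]]))
  }
  if (!is.null(x$venn)) {
    cat(sprintf("  venn: %s only / %s shared / %s only; cobound promoters %s\n",
                x$venn$a_only, x$venn$shared, x$venn$b_only,
                x$venn$cobound_promoters))
  }
  if (!is.null(x$delta_ctd)) {
    cat(sprintf("  deltaCTD overlap: %s of %s shared clusters (%s%%)\n",
                x$delta_ctd$n_hit, x$delta_ctd$n_base, x$delta_ctd$percent))
  }
  if (!is.null(x$concordance)) {
    cat(sprintf("  concordance: frac same direction %.3f (%s genes)\n",
                x$concordance$frac_same_direction, x$concordance$n_compared))
  }
  invisible(x)
}
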