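#' Configuration for a full pipeline run
#'
#' @param world A [world_config()] (synthetic mode) or `NULL` with `paths`
#'   naming input files (user-data mode; same formats as [write_world()]).
#' @param paths Named list of input paths (`metadata`, `expression`, `tss`,
#'   `snps`, `deg`, `markers`, `class_map`, `publications`, `peaks_dir`);
#'   ignored in synthetic mode.
#' @param level Inventory/cover level, `"class"` (default) or
#'   `"cell_type"`.
#' @param flank Promoter flank in bp (default 500).
#' @param match_threshold Name-matching acceptance threshold.
#' @param deg_threshold Hidden-gem DEG threshold (strict, default 1000).
#' @param n_reps Shuffled acquisition orders (default 100).
#' @param n_subsamples Subsamples per order/fraction in the Welch
#'   comparison (default 50).
#' @param n_compare Top/bottom AUC orders entered into the comparison
#'   (default 3 each).
#' @param seed Master seed for simulation stages.
#' @param outdir Output directory for stage TSVs and the run manifest.
#' @return `pipeline_config` list.
#' @export
pipeline_config <- function(world = world_config(), paths = NULL,
                            level = "class", flank = 500,
                            match_threshold = 0.9, deg_threshold = 1000,
                            n_reps = 100, n_subsamples = 50, n_compare = 3,
                            seed = 1, outdir = tempfile("tfcoverage_run_")) {
  cfg <- list(world = world, paths = paths, level = level, flank = flank,
              match_threshold = match_threshold,
              deg_threshold = deg_threshold, n_reps = n_reps,
              n_subsamples = n_subsamples, n_compare = n_compare,
              seed = as.integer(seed), outdir = outdir)
  class(cfg) <- "pipeline_config"
  cfg
}

.load_world_from_paths <- function(paths) {
  peak_files <- list.files(paths$peaks_dir, pattern = "\\.bed$",
                           full.names = TRUE)
  peaks <- lapply(peak_files, read_bed)
  names(peaks) <- sub("\\.bed$", "", basename(peak_files))
  pubs_df <- utils::read.delim(paths$publications, stringsAsFactors = FALSE)
  list(metadata = read_experiment_table(paths$metadata),
       expression = read_expression_matrix(paths$expression),
       tss = utils::read.delim(paths$tss, stringsAsFactors = FALSE),
       snps = read_snp_table(paths$snps),
       deg = read_deg_table(paths$deg),
       markers = read_marker_table(paths$markers),
       class_map = read_class_map(paths$class_map),
       publications = stats::setNames(pubs_df$publications, pubs_df$tf),
       peaks = peaks, ground_truth = NULL)
}

#' Run the full coverage-audit pipeline
#'
#' Executes the stages in dependency order: expression thresholding,
#' cell-line name matching, coverage inventory, inequality summaries,
#' annual cover ratios, acquisition-order simulation, and prioritization.
#' Every stage writes a tidy TSV into `config$outdir`; the run manifest
#' records the seed, a hash of the configuration, and the MD5 of every
#' output, so a re-run with the same configuration is byte-identical.
#' If the marker table is absent (user-data mode) the prioritization stage
#' is skipped with a warning; the other stages still complete.
#'
#' @param config A [pipeline_config()].
#' @return List of in-memory stage results (`world`, `calls`, `matches`,
#'   `inventory`, `inequality`, `cover`, `simulation`, `welch`,
#'   `prioritization`, `manifest`), invisibly also written to
#'   `config$outdir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out_file <- function(name) file.path(config$outdir, name)
  write_tsv <- function(df, name) {
    utils::write.table(df, out_file(name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    name
  }
  written <- character()

  world <- if (!is.null(config$world)) generate_world(config$world)
           else .load_world_from_paths(config$paths)
  log_stage <- function(stage, msg)
    message(sprintf("[%s] %s", stage, msg))

  # 1. expression thresholding ------------------------------------------
  calls <- call_expression(world$expression)
  written <- c(written, write_tsv(calls$fits, "step_fits.tsv"))
  log_stage("threshold", sprintf("%d TFs fit, %d skipped",
                                 nrow(calls$fits), length(calls$skipped)))

  # 2. cell-line name matching ------------------------------------------
  matches <- match_cell_lines(colnames(world$expression),
                              unique(world$metadata$cell_type),
                              threshold = config$match_threshold)
  accepted <- matches[matches$accepted, , drop = FALSE]
  written <- c(written, write_tsv(matches, "name_matches.tsv"))
  log_stage("match", sprintf("%d/%d expression cell lines matched",
                             nrow(accepted), ncol(world$expression)))

  # 3. coverage inventory ------------------------------------------------
  expressed_ct <- {
    idx <- which(calls$calls == TRUE, arr.ind = TRUE)
    data.frame(tf = rownames(calls$calls)[idx[, 1]],
               sample = colnames(calls$calls)[idx[, 2]],
               stringsAsFactors = FALSE)
  }
  if (config$level == "class") {
    expr_cls <- aggregate_to_class(calls$calls, world$class_map)
    expressed <- data.frame(tf = expr_cls$tf,
                            sample = expr_cls$cell_type_class,
                            stringsAsFactors = FALSE)
    sample_universe <- sort(unique(world$class_map$cell_type_class))
  } else {
    expressed <- expressed_ct
    sample_universe <- sort(unique(world$class_map$cell_type))
  }
  measured <- measured_pairs(world$metadata, level = config$level,
                             mapping = world$class_map)
  inventory <- build_inventory(expressed, measured,
                               tf_universe = sort(rownames(world$expression)),
                               sample_universe = sample_universe,
                               level = config$level)
  written <- c(written, write_tsv(inventory, "inventory.tsv"))
  written <- c(written, write_tsv(unmeasured_fraction(inventory, "sample"),
                                  "unmeasured_fraction.tsv"))
  log_stage("inventory", sprintf("%d measured / %d unmeasured / %d not expressed",
                                 sum(inventory$status == "measured"),
                                 sum(inventory$status == "unmeasured"),
                                 sum(inventory$status == "not_expressed")))

  # 4. inequality and attention -----------------------------------------
  tf_counts <- table(factor(world$metadata$antigen,
                            levels = sort(rownames(world$expression))))
  ct_counts <- table(factor(world$metadata$cell_type,
                            levels = sort(unique(world$class_map$cell_type))))
  split_year <- floor(mean(range(as.integer(
    format(as.Date(world$metadata$deposit_date), "%Y")))))
  att <- attention_correlations(
    stats::setNames(as.numeric(tf_counts), names(tf_counts)),
    world$publications, world$metadata, split_year)
  inequality <- list(
    gini_tf = gini(as.numeric(tf_counts)),
    gini_cell_type = gini(as.numeric(ct_counts)),
    gini_tf_counterfactual = counterfactual_gini(
      data.frame(tf = expressed_ct$tf, sample = expressed_ct$sample)),
    lorenz_tf = lorenz_curve(as.numeric(tf_counts)),
    lorenz_cell_type = lorenz_curve(as.numeric(ct_counts)),
    attention = att, split_year = split_year)
  written <- c(written, write_tsv(
    data.frame(quantity = c("gini_tf", "gini_cell_type",
                            "gini_tf_counterfactual",
                            "spearman_publications_vs_experiments",
                            "spearman_early_vs_late"),
               value = c(inequality$gini_tf, inequality$gini_cell_type,
                         inequality$gini_tf_counterfactual,
                         att$publications_vs_experiments,
                         att$early_vs_late)),
    "inequality.tsv"))
  written <- c(written, write_tsv(inequality$lorenz_tf, "lorenz_tf.tsv"))
  log_stage("inequality", sprintf("gini TF %.3f, cell type %.3f, counterfactual %.3f",
                                  inequality$gini_tf,
                                  inequality$gini_cell_type,
                                  inequality$gini_tf_counterfactual))

  # 5. annual cover ratios ----------------------------------------------
  yr <- as.integer(format(as.Date(world$metadata$deposit_date), "%Y"))
  years <- seq(min(yr), max(yr))
  top_lines <- names(sort(table(world$metadata$cell_type),
                          decreasing = TRUE))
  top_lines <- utils::head(intersect(top_lines, colnames(world$expression)),
                           3L)
  reg_series <- do.call(rbind, lapply(top_lines, function(cl) {
    annual_series("reg_tf", cl, years, world$metadata, world$peaks,
                  expression_vector = world$expression[, cl],
                  tss = world$tss, flank = config$flank)
  }))
  classes <- sort(unique(world$class_map$cell_type_class))
  hits <- snp_hits_by_experiment(world$snps, world$peaks)
  exp_year <- stats::setNames(yr, world$metadata$experiment_id)
  exp_class <- world$class_map$cell_type_class[
    match(world$metadata$cell_type, world$class_map$cell_type)]
  gwas_series <- do.call(rbind, lapply(classes, function(cl) {
    ids <- world$metadata$experiment_id[exp_class == cl]
    s <- gwas_series_from_hits(hits, exp_year, years,
                               n_snps = nrow(world$snps),
                               experiment_ids = ids)
    cbind(entity = cl, statistic = "gwas_snp", s)
  }))
  cover <- list(reg_tf = reg_series, gwas_snp = gwas_series)
  written <- c(written, write_tsv(reg_series, "cover_reg_tf.tsv"))
  written <- c(written, write_tsv(gwas_series, "cover_gwas_snp.tsv"))
  log_stage("cover", sprintf("%d reg-TF and %d GWAS series points",
                             nrow(reg_series), nrow(gwas_series)))

  # 6. acquisition-order simulation -------------------------------------
  busiest_class <- names(which.max(table(exp_class)))
  sim <- run_order_simulation(world$metadata, world$snps, world$peaks,
                              entity = busiest_class, level = "class",
                              mapping = world$class_map, years = years,
                              n_reps = config$n_reps, seed = config$seed)
  written <- c(written, write_tsv(sim$results, "order_simulation.tsv"))
  shuffled <- sim$results[sim$results$order != "real", , drop = FALSE]
  ranked <- shuffled$order[order(shuffled$auc, decreasing = TRUE)]
  chosen <- unique(c(utils::head(ranked, config$n_compare),
                     utils::tail(ranked, config$n_compare)))
  welch <- subsample_compare(sim, chosen, fractions = c(0.9, 0.5),
                             n_subsamples = config$n_subsamples,
                             seed = config$seed + 1L)
  written <- c(written, write_tsv(welch, "order_welch.tsv"))
  log_stage("simulate", sprintf("entity %s: real AUC %.4f, shuffled %.4f-%.4f",
                                busiest_class,
                                sim$results$auc[sim$results$order == "real"],
                                min(shuffled$auc), max(shuffled$auc)))

  # 7. prioritization ----------------------------------------------------
  prioritization <- NULL
  if (is.null(world$markers) || length(world$markers) == 0L) {
    warning("marker table absent: prioritization stage skipped")
    log_stage("prioritize", "skipped (no marker table)")
  } else {
    gems <- hidden_gems(inventory, world$deg, world$markers,
                        deg_threshold = config$deg_threshold)
    cmp_marker <- compare_deg_groups(world$deg,
                                     grouping = "marker_vs_nonmarker")
    cmp_measured <- tryCatch(
      compare_deg_groups(world$deg, inventory,
                         grouping = "measured_vs_unmeasured"),
      error = function(e) NULL)
    prioritization <- list(gems = gems, marker_test = cmp_marker,
                           measured_test = cmp_measured)
    written <- c(written, write_tsv(gems, "gem_audit.tsv"))
    log_stage("prioritize", sprintf("%d hidden gems", sum(gems$gem)))
  }

  # manifest --------------------------------------------------------------
  cfg_yaml <- yaml::as.yaml(config[setdiff(names(config), "outdir")])
  cfg_file <- out_file("config.yaml")
  writeLines(cfg_yaml, cfg_file)
  manifest <- list(run_id = unname(tools::md5sum(cfg_file)),
                   seed = config$seed,
                   outputs = as.list(
                     stats::setNames(unname(tools::md5sum(
                       vapply(written, out_file, character(1)))), written)))
  yaml::write_yaml(manifest, out_file("manifest.yaml"))
  invisible(list(world = world, calls = calls, matches = matches,
                 inventory = inventory, inequality = inequality,
                 cover = cover, simulation = sim, welch = welch,
                 prioritization = prioritization, manifest = manifest,
                 outdir = config$outdir))
}
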