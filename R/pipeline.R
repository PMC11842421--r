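# End-to-end pipeline: simulate -> qc -> classify -> adjust -> plsda ->
# associate -> annotate -> enrich, plus an optparse-based command-line
# entry point (see inst/scripts/mwas).

#' Default pipeline configuration
#'
#' All module thresholds at their published defaults: QC filters 0.30 /
#' 0.30 / 0.70 with kNN k = 10, hydroxycotinine top 14%, VIP cutoff 2.0,
#' annotation tolerances 5 ppm + 15 s (level 1) and 10 ppm (level 4),
#' 2 PLS components, 100 permutations, alpha 0.05, minimum pathway overlap 3.
#'
#' @param seed Seed for simulation and permutation resampling.
#' @return list of pipeline parameters.
#' @export
default_config <- function(seed = 1L) {
  list(seed = as.integer(seed),
       max_missing_frac = 0.30, max_median_cv = 0.30,
       min_median_pearson = 0.70, knn_k = 10L,
       hydroxycotinine_top_frac = 0.14, biomarker_tol_ppm = 5,
       vip_cutoff = 2.0, components = 2L,
       level1_tol_ppm = 5, level1_tol_rt_s = 15, level4_tol_ppm = 10,
       pathway_tol_ppm = 10, permutations = 100L, min_overlap = 3L,
       alpha = 0.05)
}

#' Run the analysis for one chromatography mode
#'
#' QC, replicate summarization, transformation, imputation, covariate
#' residualization, PLS-DA/VIP selection, fold changes, logistic
#' association with FDR, annotation and pathway enrichment. Biomarker
#' features (by m/z) are excluded from discovery.
#'
#' @param table A `feature_table` for the mode.
#' @param samples Covariate data.frame (rows aligned by sample_id).
#' @param smoker Logical exposure vector aligned to the table's samples.
#' @param config Pipeline configuration (see [default_config]).
#' @param library_df Reference library for level-1 annotation.
#' @param pdb Pathway database for enrichment.
#' @return list of per-stage outputs (qc report, matrices, model,
#'   selection, association, annotation, enrichment, counts).
#' @export
run_mode <- function(table, samples, smoker, config = default_config(),
                     library_df = read_reference_library(
                       default_reference_library_path()),
                     pdb = read_pathway_db(default_pathway_db_path())) {
  sids <- table_samples(table)
  stopifnot(identical(sids, samples$sample_id))
  thr <- qc_thresholds(config$max_missing_frac, config$max_median_cv,
                       config$min_median_pearson, config$knn_k)
  qc <- apply_qc(table, thr)
  sm <- summarize_replicates(qc$table)
  tr <- log2_batch_center_autoscale(sm)

  # biomarker channels never enter discovery
  rule <- exposure_rule(mz_tol_ppm = config$biomarker_tol_ppm,
                        hydroxycotinine_top_frac =
                          config$hydroxycotinine_top_frac)
  bio_mz <- c(rule$cotinine_mz, rule$hydroxycotinine_mz)
  feats <- tr$scaled$features
  is_bio <- vapply(feats$mz, function(m) {
    any(abs(ppm_error(m, bio_mz)) <= config$biomarker_tol_ppm)
  }, TRUE)
  bio_ids <- feats$feature_id[is_bio]

  scaled <- knn_impute(tr$scaled$intensities, k = config$knn_k)
  log2_back <- scaled * tr$scale + tr$center  # imputed, pre-scaling scale
  design <- design_matrix(samples)
  adj_scaled <- residualize(scaled, design, exclude = bio_ids)$residuals
  adj_log2 <- residualize(log2_back, design, exclude = bio_ids)$residuals

  disc_ids <- feats$feature_id[!is_bio]
  X <- t(adj_scaled[disc_ids, , drop = FALSE])
  model <- fit_plsda(X, as.numeric(smoker), A = config$components)
  selection <- select_features(model, adj_log2[disc_ids, , drop = FALSE],
                               smoker, vip_cutoff = config$vip_cutoff)
  sel_ids <- selection$feature_id[selection$selected]
  association <- if (length(sel_ids)) {
    associate_features(adj_scaled, smoker, feats, sel_ids)
  } else NULL
  sel_feats <- feats[feats$feature_id %in% sel_ids, , drop = FALSE]
  disc_feats <- feats[!is_bio, , drop = FALSE]
  annotation <- list(
    level1 = match_level1(sel_feats, library_df,
                          config$level1_tol_ppm, config$level1_tol_rt_s),
    level4 = match_level4(sel_feats, library_df, config$level4_tol_ppm))
  enrichment <- enrich(sel_feats, disc_feats, pdb,
                       tol_ppm = config$pathway_tol_ppm,
                       P = config$permutations,
                       min_overlap = config$min_overlap,
                       alpha = config$alpha)
  list(qc_report = qc$report, transformed = tr, scaled_imputed = scaled,
       adjusted_scaled = adj_scaled, adjusted_log2 = adj_log2,
       model = model, selection = selection, association = association,
       annotation = annotation, enrichment = enrichment,
       counts = c(input = nrow(table$features),
                  post_qc = sum(qc$report$pass),
                  post_transform = nrow(feats),
                  discoverable = length(disc_ids),
                  selected = length(sel_ids)))
}

#' Run the full pipeline on simulated data
#'
#' Simulates a study, classifies exposure from the HILIC biomarker
#' channels of the raw (pre-QC) summarized table, runs both modes through
#' discovery, and writes all stage outputs plus a provenance manifest to
#' `outdir` when given.
#'
#' @param cfg A [sim_config]; its seed drives every stochastic stage.
#' @param config Pipeline configuration.
#' @param outdir Optional output directory.
#' @return list: `sim`, `calls`, `summary`, `modes` (per-mode results),
#'   `manifest`.
#' @export
run_all <- function(cfg = sim_config(), config = default_config(cfg$seed),
                    outdir = NULL) {
  sim <- simulate_mwas(cfg)
  rule <- exposure_rule(mz_tol_ppm = config$biomarker_tol_ppm,
                        hydroxycotinine_top_frac =
                          config$hydroxycotinine_top_frac)
  sm_raw <- summarize_replicates(sim$hilic)
  cot <- extract_biomarker(sm_raw, rule$cotinine_mz, rule$mz_tol_ppm)
  hyd <- extract_biomarker(sm_raw, rule$hydroxycotinine_mz,
                           rule$mz_tol_ppm)
  calls <- classify_exposure(sim$samples, cot$intensity, hyd$intensity,
                             rule)
  summary <- cohort_summary(calls, sim$samples)
  modes <- list(
    HILIC_pos = run_mode(sim$hilic, sim$samples, calls$smoker, config),
    C18_neg = run_mode(sim$c18, sim$samples, calls$smoker, config))
  manifest <- list(seed = cfg$seed, config = config,
                   n_samples = nrow(sim$samples),
                   n_smokers = sum(calls$smoker),
                   stage_counts = lapply(modes,
                                         function(m) as.list(m$counts)))
  out <- list(sim = sim, calls = calls, summary = summary, modes = modes,
              manifest = manifest)
  if (!is.null(outdir)) write_run(out, outdir)
  out
}

write_run <- function(run, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_feature_table(run$sim$hilic, file.path(outdir, "hilic.tsv"),
                      file.path(outdir, "hilic_batches.tsv"))
  write_feature_table(run$sim$c18, file.path(outdir, "c18.tsv"),
                      file.path(outdir, "c18_batches.tsv"))
  write_samples(run$sim$samples, file.path(outdir, "samples.tsv"))
  utils::write.table(run$calls, file.path(outdir, "exposure_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (mode in names(run$modes)) {
    r <- run$modes[[mode]]
    pre <- file.path(outdir, tolower(mode))
    utils::write.table(r$qc_report, paste0(pre, "_qc_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(r$selection, paste0(pre, "_selection.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(r$association)) {
      utils::write.table(r$association, paste0(pre, "_association.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(manhattan_export(r$association),
                         paste0(pre, "_manhattan.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    utils::write.table(r$enrichment, paste0(pre, "_enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(run$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(outdir)
}

# matrix TSV helpers for staged CLI outputs: first column feature_id,
# then one column per sample
write_matrix_tsv <- function(x, path) {
  df <- data.frame(feature_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$feature_id
  m
}

# staged file names inside a run directory, per mode
stage_paths <- function(outdir, mode) {
  pre <- file.path(outdir, tolower(mode))
  list(table = file.path(outdir, if (mode == "HILIC_pos") "hilic.tsv"
                         else "c18.tsv"),
       batches = file.path(outdir, if (mode == "HILIC_pos")
         "hilic_batches.tsv" else "c18_batches.tsv"),
       qc_table = paste0(pre, "_qc.tsv"),
       qc_batches = paste0(pre, "_qc_batches.tsv"),
       qc_report = paste0(pre, "_qc_report.tsv"),
       adjusted = paste0(pre, "_adjusted.tsv"),
       adjusted_log2 = paste0(pre, "_adjusted_log2.tsv"),
       selection = paste0(pre, "_selection.tsv"),
       scores = paste0(pre, "_scores.tsv"),
       association = paste0(pre, "_association.tsv"),
       manhattan = paste0(pre, "_manhattan.tsv"),
       level1 = paste0(pre, "_level1.tsv"),
       level4 = paste0(pre, "_level4.tsv"),
       enrichment = paste0(pre, "_enrichment.tsv"))
}

cli_modes <- function(outdir) {
  Filter(function(m) file.exists(stage_paths(outdir, m)$table),
         FEATURE_MODES)
}

require_file <- function(path, stage) {
  if (!file.exists(path)) {
    stop("missing input for '", stage, "': ", path,
         " (run the earlier stages first)")
  }
  path
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

read_calls <- function(outdir) {
  p <- require_file(file.path(outdir, "exposure_calls.tsv"), "classify")
  df <- utils::read.delim(p, stringsAsFactors = FALSE)
  for (cl in c("smoker", "by_report", "by_cotinine",
               "by_hydroxycotinine")) df[[cl]] <- as.logical(df[[cl]])
  df
}

#' Command-line interface
#'
#' Subcommands chain through a shared run directory (`--outdir`):
#' `simulate`, `qc`, `classify`, `adjust`, `plsda`, `associate`,
#' `annotate`, `enrich`, and `run-all` (everything at once). Each stage
#' reads the previous stage's TSV outputs and writes its own. Used by the
#' installed `inst/scripts/mwas` wrapper.
#'
#' @param args Character vector of command-line arguments.
#' @return Invisibly, the output directory.
#' @export
mwas_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  cmds <- c("simulate", "qc", "classify", "adjust", "plsda", "associate",
            "annotate", "enrich", "run-all")
  if (!length(args)) {
    stop("usage: mwas <", paste(cmds, collapse = "|"),
         "> [--seed N] [--outdir DIR]")
  }
  cmd <- args[1]
  if (!cmd %in% cmds) stop("unknown subcommand: ", cmd)
  opts <- optparse::parse_args(
    optparse::OptionParser(option_list = list(
      optparse::make_option("--seed", type = "integer", default = 1L),
      optparse::make_option("--outdir", type = "character",
                            default = "mwas_out"),
      optparse::make_option("--n-samples", type = "integer",
                            default = 900L, dest = "n_samples"),
      optparse::make_option("--n-features", type = "integer",
                            default = 2000L, dest = "n_features"),
      optparse::make_option("--n-planted", type = "integer",
                            default = 60L, dest = "n_planted"),
      optparse::make_option("--max-missing", type = "double",
                            default = 0.30, dest = "max_missing"),
      optparse::make_option("--max-cv", type = "double", default = 0.30,
                            dest = "max_cv"),
      optparse::make_option("--min-pearson", type = "double",
                            default = 0.70, dest = "min_pearson"),
      optparse::make_option("--knn-k", type = "integer", default = 10L,
                            dest = "knn_k"),
      optparse::make_option("--components", type = "integer",
                            default = 2L),
      optparse::make_option("--vip-cutoff", type = "double",
                            default = 2.0, dest = "vip_cutoff"),
      optparse::make_option("--min-overlap", type = "integer",
                            default = 3L, dest = "min_overlap"),
      optparse::make_option("--alpha", type = "double", default = 0.05),
      optparse::make_option("--permutations", type = "integer",
                            default = 100L))),
    args = args[-1])
  outdir <- opts$outdir
  config <- default_config(opts$seed)
  config$max_missing_frac <- opts$max_missing
  config$max_median_cv <- opts$max_cv
  config$min_median_pearson <- opts$min_pearson
  config$knn_k <- opts$knn_k
  config$components <- opts$components
  config$vip_cutoff <- opts$vip_cutoff
  config$min_overlap <- opts$min_overlap
  config$alpha <- opts$alpha
  config$permutations <- opts$permutations
  switch(cmd,
         "simulate" = cli_simulate(opts, outdir),
         "qc" = cli_qc(config, outdir),
         "classify" = cli_classify(config, outdir),
         "adjust" = cli_adjust(config, outdir),
         "plsda" = cli_plsda(config, outdir),
         "associate" = cli_associate(config, outdir),
         "annotate" = cli_annotate(config, outdir),
         "enrich" = cli_enrich(config, outdir),
         "run-all" = {
           cfg <- sim_config(seed = opts$seed,
                             n_samples = opts$n_samples,
                             n_features = opts$n_features,
                             n_planted = min(opts$n_planted,
                                             opts$n_features %/% 4L))
           run_all(cfg, config, outdir = outdir)
         })
  invisible(outdir)
}

cli_simulate <- function(opts, outdir) {
  cfg <- sim_config(seed = opts$seed, n_samples = opts$n_samples,
                    n_features = opts$n_features,
                    n_planted = min(opts$n_planted,
                                    opts$n_features %/% 4L))
  sim <- simulate_mwas(cfg)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_feature_table(sim$hilic, file.path(outdir, "hilic.tsv"),
                      file.path(outdir, "hilic_batches.tsv"))
  write_feature_table(sim$c18, file.path(outdir, "c18.tsv"),
                      file.path(outdir, "c18_batches.tsv"))
  write_samples(sim$samples, file.path(outdir, "samples.tsv"))
  jsonlite::write_json(sim$truth, file.path(outdir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
}

cli_read_table <- function(outdir, mode, stage, filtered = FALSE) {
  p <- stage_paths(outdir, mode)
  if (filtered) {
    read_feature_table(require_file(p$qc_table, stage), mode,
                       p$qc_batches)
  } else {
    read_feature_table(require_file(p$table, stage), mode, p$batches)
  }
}

cli_qc <- function(config, outdir) {
  thr <- qc_thresholds(config$max_missing_frac, config$max_median_cv,
                       config$min_median_pearson, config$knn_k)
  for (mode in cli_modes(outdir)) {
    p <- stage_paths(outdir, mode)
    out <- apply_qc(cli_read_table(outdir, mode, "qc"), thr)
    write_tsv(out$report, p$qc_report)
    write_feature_table(out$table, p$qc_table, p$qc_batches)
  }
}

cli_classify <- function(config, outdir) {
  samples <- read_samples(require_file(file.path(outdir, "samples.tsv"),
                                       "classify"))
  rule <- exposure_rule(mz_tol_ppm = config$biomarker_tol_ppm,
                        hydroxycotinine_top_frac =
                          config$hydroxycotinine_top_frac)
  sm <- summarize_replicates(cli_read_table(outdir, "HILIC_pos",
                                            "classify"))
  calls <- classify_exposure(
    samples, extract_biomarker(sm, rule$cotinine_mz,
                               rule$mz_tol_ppm)$intensity,
    extract_biomarker(sm, rule$hydroxycotinine_mz,
                      rule$mz_tol_ppm)$intensity, rule)
  write_tsv(calls, file.path(outdir, "exposure_calls.tsv"))
  s <- cohort_summary(calls, samples)
  write_tsv(s$prevalence, file.path(outdir, "summary_prevalence.tsv"))
  write_tsv(s$indicators, file.path(outdir, "summary_indicators.tsv"))
  write_tsv(s$strata, file.path(outdir, "summary_strata.tsv"))
}

# shared by adjust and downstream recomputing stages
cli_transform <- function(config, outdir, mode) {
  tab <- cli_read_table(outdir, mode, "adjust", filtered = TRUE)
  tr <- log2_batch_center_autoscale(summarize_replicates(tab))
  scaled <- knn_impute(tr$scaled$intensities, k = config$knn_k)
  list(tr = tr, scaled = scaled,
       log2_back = scaled * tr$scale + tr$center)
}

cli_bio_ids <- function(feats, config) {
  rule <- exposure_rule()
  bio_mz <- c(rule$cotinine_mz, rule$hydroxycotinine_mz)
  feats$feature_id[vapply(feats$mz, function(m) {
    any(abs(ppm_error(m, bio_mz)) <= config$biomarker_tol_ppm)
  }, TRUE)]
}

cli_adjust <- function(config, outdir) {
  samples <- read_samples(require_file(file.path(outdir, "samples.tsv"),
                                       "adjust"))
  design <- design_matrix(samples)
  for (mode in cli_modes(outdir)) {
    p <- stage_paths(outdir, mode)
    tx <- cli_transform(config, outdir, mode)
    bio <- cli_bio_ids(tx$tr$scaled$features, config)
    write_matrix_tsv(residualize(tx$scaled, design,
                                 exclude = bio)$residuals, p$adjusted)
    write_matrix_tsv(residualize(tx$log2_back, design,
                                 exclude = bio)$residuals,
                     p$adjusted_log2)
  }
}

cli_plsda <- function(config, outdir) {
  calls <- read_calls(outdir)
  for (mode in cli_modes(outdir)) {
    p <- stage_paths(outdir, mode)
    adj <- read_matrix_tsv(require_file(p$adjusted, "plsda"))
    adj_log2 <- read_matrix_tsv(require_file(p$adjusted_log2, "plsda"))
    feats <- cli_read_table(outdir, mode, "plsda",
                            filtered = TRUE)$features
    disc <- setdiff(rownames(adj), cli_bio_ids(feats, config))
    model <- fit_plsda(t(adj[disc, , drop = FALSE]),
                       as.numeric(calls$smoker), A = config$components)
    sel <- select_features(model, adj_log2[disc, , drop = FALSE],
                           calls$smoker, config$vip_cutoff)
    write_tsv(sel, p$selection)
    write_tsv(export_scores(model, calls$smoker)$scores, p$scores)
  }
}

cli_selected <- function(outdir, mode) {
  p <- stage_paths(outdir, mode)
  sel <- utils::read.delim(require_file(p$selection, "associate"),
                           stringsAsFactors = FALSE)
  sel$selected <- as.logical(sel$selected)
  sel
}

cli_associate <- function(config, outdir) {
  calls <- read_calls(outdir)
  for (mode in cli_modes(outdir)) {
    p <- stage_paths(outdir, mode)
    adj <- read_matrix_tsv(require_file(p$adjusted, "associate"))
    feats <- cli_read_table(outdir, mode, "associate",
                            filtered = TRUE)$features
    sel <- cli_selected(outdir, mode)
    ids <- sel$feature_id[sel$selected]
    if (!length(ids)) next
    rows <- associate_features(adj, calls$smoker, feats, ids)
    write_tsv(rows, p$association)
    write_tsv(manhattan_export(rows), p$manhattan)
  }
}

cli_annotate <- function(config, outdir) {
  lib <- read_reference_library(default_reference_library_path())
  for (mode in cli_modes(outdir)) {
    p <- stage_paths(outdir, mode)
    feats <- cli_read_table(outdir, mode, "annotate",
                            filtered = TRUE)$features
    sel <- cli_selected(outdir, mode)
    sf <- feats[feats$feature_id %in% sel$feature_id[sel$selected], ]
    write_tsv(match_level1(sf, lib, config$level1_tol_ppm,
                           config$level1_tol_rt_s), p$level1)
    write_tsv(match_level4(sf, lib, config$level4_tol_ppm), p$level4)
  }
}

cli_enrich <- function(config, outdir) {
  pdb <- read_pathway_db(default_pathway_db_path())
  set.seed(config$seed)
  for (mode in cli_modes(outdir)) {
    p <- stage_paths(outdir, mode)
    feats <- cli_read_table(outdir, mode, "enrich",
                            filtered = TRUE)$features
    sel <- cli_selected(outdir, mode)
    bio <- cli_bio_ids(feats, config)
    disc <- feats[!feats$feature_id %in% bio, ]
    sf <- feats[feats$feature_id %in% sel$feature_id[sel$selected], ]
    write_tsv(enrich(sf, disc, pdb, tol_ppm = config$pathway_tol_ppm,
                     P = config$permutations,
                     min_overlap = config$min_overlap,
                     alpha = config$alpha), p$enrichment)
  }
}
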