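#' Pipeline configuration
#'
#' Collects every stage's settings with defaults mirroring the study
#' protocol: rarefaction depth 6000 reads/sample, doubleton removal, 999
#' PERMANOVA permutations, 1000 permutations for indicator-value, distance
#' and CCA tests, core prevalence threshold 0.5, CCA on 4 components per
#' side, Shannon log base 2. Inputs come either from a [synth_config()]
#' generator (`synth`) or from TSV paths.
#'
#' @param synth a [synth_config()], or NULL to read from paths.
#' @param table_path,meta_path,expr_path TSV inputs when `synth` is NULL
#'   (`expr_path` optional; the CCA and expression stages are skipped
#'   without it).
#' @param seed master seed; per-stage seeds are derived from it.
#' @param depth rarefaction depth.
#' @param log_base Shannon logarithm base.
#' @param formula PERMANOVA model formula.
#' @param n_perm_permanova,n_perm_indval,n_perm_contrast,n_perm_cca
#'   permutation counts per stage.
#' @param core_threshold core prevalence threshold.
#' @param core_mode `"either"` or `"both"` (see [find_core()]).
#' @param k_cca components per side for the CCA stage.
#' @param detect_threshold expression presence cutoff.
#' @param indval_group metadata column for the indicator analysis.
#' @return `pipeline_config` list.
#' @export
pipeline_config <- function(synth = synth_config(),
                            table_path = NULL, meta_path = NULL,
                            expr_path = NULL,
                            seed = 1L,
                            depth = 6000,
                            log_base = 2,
                            formula = ~ tolerance + temperature + family +
                              part + tolerance:temperature,
                            n_perm_permanova = 999,
                            n_perm_indval = 1000,
                            n_perm_contrast = 1000,
                            n_perm_cca = 1000,
                            core_threshold = 0.5,
                            core_mode = "either",
                            k_cca = 4,
                            detect_threshold = 0,
                            indval_group = "tolerance") {
  cfg <- as.list(environment())
  if (is.null(synth) && (is.null(table_path) || is.null(meta_path)))
    stop("either a synth config or table_path + meta_path is required")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes generate/ingest, doubleton filtering, rarefaction,
#' alpha-diversity with the mixed-effects stage, Bray-Curtis distances with
#' ordination and Monte-Carlo contrasts, PERMANOVA, indicator-value
#' analysis, core-microbiome resilience, and (when expression data exist)
#' the expression fold-change contrast and the CCA redundancy permutation
#' test. Identical config and seed give an identical report.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, tables are written as TSV
#'   and the summary as JSON.
#' @return `run_report` list of per-stage outputs plus the config echo.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  log_stage <- function(name, ...) message(sprintf("[%s] %s", name,
                                                   sprintf(...)))
  report <- list(config = cfg[setdiff(names(cfg), "formula")],
                 formula = deparse(cfg$formula))

  # -- ingest ----------------------------------------------------------------
  if (!is.null(cfg$synth)) {
    sim <- generate_microbiome(cfg$synth)
    table <- sim$table; meta <- sim$meta
    expr <- generate_expression(cfg$synth, sim$truth)
    report$truth_core <- sim$truth$core_taxa
  } else {
    table <- read_feature_table(cfg$table_path)
    meta <- read_metadata(cfg$meta_path)
    expr <- if (!is.null(cfg$expr_path)) read_expression(cfg$expr_path)
  }
  al <- align_tables(table, meta)
  table <- al$table; meta <- al$meta
  log_stage("ingest", "%d samples x %d features", nrow(table), ncol(table))

  # -- filtering + rarefaction ----------------------------------------------
  table <- filter_doubletons(table)
  table <- rarefy(table, depth = cfg$depth,
                  seed = stream_seed(cfg$seed, "rarefy"))
  al <- align_tables(table, meta)
  table <- al$table; meta <- al$meta
  log_stage("rarefy", "depth %d, %d samples retained", cfg$depth,
            nrow(table))

  # -- alpha diversity + LMM -------------------------------------------------
  alpha <- alpha_diversity(table, log_base = cfg$log_base)
  report$alpha <- alpha
  report$lmm <- list(
    richness = fit_diversity_lmm(alpha$richness, meta),
    shannon = fit_diversity_lmm(alpha$shannon, meta))
  log_stage("diversity", "temperature F(richness) = %.2f",
            report$lmm$richness$fixed$F[
              report$lmm$richness$fixed$term == "temperature"])

  # -- beta diversity --------------------------------------------------------
  dm <- bray_curtis(table)
  report$pcoa <- pcoa(dm, k = 2)
  contrast_seed <- stream_seed(cfg$seed, "contrast")
  report$contrast_shift <- distance_contrast(
    dm, meta,
    pair_selector("temperature", "between",
                  stratum = list(tolerance = "resistant")),
    pair_selector("temperature", "between",
                  stratum = list(tolerance = "sensitive")),
    n_perm = cfg$n_perm_contrast, seed = contrast_seed, n_comparisons = 2)
  report$contrast_warm <- distance_contrast(
    dm, meta,
    pair_selector("tolerance", "within", level = "resistant",
                  stratum = list(temperature = "warm24")),
    pair_selector("tolerance", "within", level = "sensitive",
                  stratum = list(temperature = "warm24")),
    n_perm = cfg$n_perm_contrast, seed = contrast_seed + 1L,
    n_comparisons = 2)
  log_stage("distances", "warm->cold shift t = %.2f, p = %.4g",
            report$contrast_shift$t, report$contrast_shift$p)

  # -- permanova -------------------------------------------------------------
  report$permanova <- adonis_dm(dm, meta, cfg$formula,
                                n_perm = cfg$n_perm_permanova,
                                seed = stream_seed(cfg$seed, "permutation"))
  log_stage("permanova", "%d terms, %d permutations",
            nrow(report$permanova) - 2, cfg$n_perm_permanova)

  # -- indicator value -------------------------------------------------------
  report$indval <- indval(table, cfg$indval_group, meta = meta,
                          n_perm = cfg$n_perm_indval,
                          seed = stream_seed(cfg$seed, "indval"))

  # -- core resilience -------------------------------------------------------
  core <- find_core(table, meta, prevalence_threshold = cfg$core_threshold,
                    mode = cfg$core_mode)
  report$core <- core
  if (length(core)) {
    profile <- renormalize_core(table, core)
    report$resilience <- resilience_contrast(profile, meta)
    log_stage("core", "%d core features, Wilcoxon p = %.4g", length(core),
              report$resilience$wilcoxon$p)
  } else {
    warning("no core features at threshold ", cfg$core_threshold)
  }

  # -- omics linkage ---------------------------------------------------------
  if (!is.null(expr)) {
    ale <- align_tables(expr, meta)
    report$expression_fc <- expression_fold_change(ale$table, ale$meta)
    shared <- intersect(rownames(table), rownames(ale$table))
    A <- component_scores(table[shared, , drop = FALSE],
                          method = "pcoa_braycurtis", k = cfg$k_cca)
    B <- component_scores(ale$table[shared, , drop = FALSE],
                          method = "pca_log", k = cfg$k_cca)
    report$cca <- cca_permutation_test(A, B, n_perm = cfg$n_perm_cca,
                                       seed = stream_seed(cfg$seed, "cca"))
    log_stage("cca", "variance explained = %.3f, p = %.4g",
              report$cca$variance_explained, report$cca$p)
  } else {
    warning("no expression matrix; CCA stage skipped")
  }

  class(report) <- "run_report"
  if (!is.null(out_dir)) write_report(report, table, meta, out_dir)
  report
}

write_report <- function(report, table, meta, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_feature_table(table, file.path(out_dir, "analysis_table.tsv"))
  write_metadata(meta, file.path(out_dir, "metadata.tsv"))
  utils::write.table(as.data.frame(report$permanova),
                     file.path(out_dir, "permanova.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$indval$records,
                     file.path(out_dir, "indval.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summary <- list(
    formula = report$formula,
    seed = report$config$seed,
    lmm = lapply(report$lmm, function(l) l[c("fixed", "varcomp")]),
    contrast_shift = report$contrast_shift[c("t", "p", "p_corrected")],
    contrast_warm = report$contrast_warm[c("t", "p", "p_corrected")],
    core = report$core,
    resilience = if (!is.null(report$resilience))
      list(median_abs_log2fc = as.list(report$resilience$median_abs_log2fc),
           wilcoxon = report$resilience$wilcoxon),
    cca = if (!is.null(report$cca))
      report$cca[c("variance_explained", "p", "n_perm", "k")])
  jsonlite::write_json(summary, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("thermogut pipeline report\n")
  cat("  formula:", x$formula, "\n")
  cat(sprintf("  warm->cold distance shift: t = %.3f, corrected p = %.4g\n",
              x$contrast_shift$t, x$contrast_shift$p_corrected))
  if (!is.null(x$resilience))
    cat(sprintf("  core resilience Wilcoxon p = %.4g\n",
                x$resilience$wilcoxon$p))
  if (!is.null(x$cca))
    cat(sprintf("  CCA variance explained = %.4f, p = %.4g\n",
                x$cca$variance_explained, x$cca$p))
  print(x$permanova)
  invisible(x)
}
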