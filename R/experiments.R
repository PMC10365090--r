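# The four prediction experiments, driven from a spec object and emitting
# reports shaped like the published performance tables: one row per
# (selector, classifier) pair with the metric panel for the training split,
# the internal hold-out validation and (radiomics-only experiment) the
# external cohort.

experiment_names <- c("pfs_radiomics", "pfs_multiomics", "hotcold_radiomics",
                      "pfs_radiomics_hotcold")

default_n_select <- c(pfs_radiomics = 30L, pfs_multiomics = 20L,
                      hotcold_radiomics = 15L, pfs_radiomics_hotcold = 15L)

#' Experiment specification
#'
#' The radiomics-only PFS experiment runs the 2 x 2 grid
#' {relieff, t_test} x {mlp, svm_linear} with external validation; the three
#' radiogenomic experiments run {t_test, wilcoxon, auroc, relieff} x
#' {tree_ensemble, svm_linear} with internal hold-out only. Default
#' selection sizes are 30 / 20 / 15 / 15 features. For
#' `pfs_radiomics_hotcold` the HOT/COLD status is appended as feature 343
#' and always kept in the selection.
#'
#' @param name one of `"pfs_radiomics"`, `"pfs_multiomics"`,
#'   `"hotcold_radiomics"`, `"pfs_radiomics_hotcold"`
#' @param cohort_config a [synthetic_cohort_config()] for the (training)
#'   cohort, or `NULL` to pass pre-built tables in `run_experiment()`
#' @param external_config config for the external cohort
#'   (`pfs_radiomics` only; defaults to the training config with a shifted
#'   seed and the 85-subject external cohort size)
#' @param selectors selector grid override
#' @param classifiers classifier grid override
#' @param n_select selection size override
#' @param extraction an [extraction_config()]
#' @param seed master seed for split/model randomness
#' @export
experiment_spec <- function(name, cohort_config = synthetic_cohort_config(),
                            external_config = NULL, selectors = NULL,
                            classifiers = NULL, n_select = NULL,
                            extraction = extraction_config(), seed = 42L) {
  name <- match.arg(name, experiment_names)
  if (is.null(selectors))
    selectors <- if (name == "pfs_radiomics") c("relieff", "t_test")
                 else c("t_test", "wilcoxon", "auroc", "relieff")
  if (is.null(classifiers))
    classifiers <- if (name == "pfs_radiomics") c("mlp", "svm_linear")
                   else c("tree_ensemble", "svm_linear")
  if (is.null(n_select)) n_select <- default_n_select[[name]]
  if (name == "pfs_radiomics" && is.null(external_config) &&
      !is.null(cohort_config)) {
    external_config <- cohort_config
    external_config$n_subjects <- max(8L,
      as.integer(round(cohort_config$n_subjects * 85 / 110)))
    external_config$seed <- cohort_config$seed + 10000L
  }
  structure(list(name = name, cohort_config = cohort_config,
                 external_config = external_config,
                 selectors = selectors, classifiers = classifiers,
                 n_select = as.integer(n_select), extraction = extraction,
                 seed = as.integer(seed)),
            class = "experiment_spec")
}

selector_cfg <- function(selector, n_select, force_include = character(0)) {
  if (selector == "relieff")
    selection_config(method = "relieff", n_select = n_select,
                     force_include = force_include)
  else
    selection_config(method = "statistical", z_statistic = selector,
                     n_select = n_select, force_include = force_include)
}

experiment_table <- function(spec, cohort = NULL, verbose = FALSE) {
  if (is.null(cohort)) cohort <- generate_cohort(spec$cohort_config)
  ft <- cohort_feature_table(cohort, spec$extraction, verbose = verbose)
  if (spec$name == "pfs_multiomics") {
    expr <- do.call(rbind, lapply(cohort, `[[`, "expression"))
    rownames(expr) <- rownames(ft$x)
    ft <- merge_omics(ft, expr)
  } else if (spec$name == "pfs_radiomics_hotcold") {
    hc <- setNames(vapply(cohort, `[[`, integer(1), "hotcold_label"),
                   rownames(ft$x))
    ft <- merge_omics(ft, hc)
  }
  ft
}

#' Run one experiment end-to-end
#'
#' Generates (or accepts) the cohort, extracts features, merges omics as the
#' experiment requires, and evaluates every (selector, classifier) pair with
#' selection refit inside the training partition. Fully reproducible from
#' (spec, seed).
#'
#' @param spec an [experiment_spec()]
#' @param table optional pre-built unnormalized [feature_table()] with
#'   label columns `dc` and `hotcold` (skips synthesis/extraction)
#' @param external_table optional pre-built external [feature_table()]
#' @param verbose print stage progress
#' @return an `experiment_report`: data.frame, one row per grid cell, with
#'   train / internal-CV / external metric panels and run metadata
#'   attributes
#' @export
run_experiment <- function(spec, table = NULL, external_table = NULL,
                           verbose = FALSE) {
  stopifnot(inherits(spec, "experiment_spec"))
  needs_omics <- spec$name %in% c("pfs_multiomics", "hotcold_radiomics",
                                  "pfs_radiomics_hotcold")
  if (!is.null(table) && needs_omics) {
    has_hc <- !is.null(table$labels) && "hotcold" %in% colnames(table$labels)
    has_genes <- any(table$provenance == "gene")
    if (spec$name == "pfs_multiomics" && !has_genes)
      stopf("experiment '%s' needs gene expression columns", spec$name)
    if (spec$name != "pfs_multiomics" && !has_hc &&
        !any(table$provenance == "hotcold"))
      stopf("experiment '%s' needs HOT/COLD status", spec$name)
  }
  if (is.null(table)) {
    if (verbose) message("generating cohort and extracting features...")
    table <- experiment_table(spec, verbose = verbose)
  }
  labels <- if (spec$name == "hotcold_radiomics") table$labels$hotcold
            else table$labels$dc
  force_inc <- if (spec$name == "pfs_radiomics_hotcold") "hotcold"
               else character(0)
  if (spec$name == "pfs_radiomics" && is.null(external_table) &&
      !is.null(spec$external_config)) {
    if (verbose) message("generating external cohort...")
    ext_cohort <- generate_cohort(spec$external_config)
    external_table <- cohort_feature_table(ext_cohort, spec$extraction,
                                           verbose = verbose)
  }
  rows <- list()
  for (sel in spec$selectors) for (clf in spec$classifiers) {
    if (verbose) message(sprintf("  %s x %s", sel, clf))
    mcfg <- model_config(classifier = clf, cv_seed = spec$seed,
                         mlp_seed = spec$seed + 1L,
                         tree_seed = spec$seed + 2L)
    scfg <- selector_cfg(sel, spec$n_select, force_inc)
    cv <- holdout_cv(table, labels, mcfg, scfg)
    row <- data.frame(reduction_method = sel, learning_method = clf)
    panel <- function(rep, prefix) {
      p <- rep[, c("auroc", "accuracy", "sensitivity", "specificity",
                   "misclassification_rate", "n_misclassified", "n")]
      names(p) <- paste0(prefix, names(p))
      p
    }
    row <- cbind(row, panel(cv$train_report, "train_"),
                 panel(cv$validation_report, "cv_"))
    if (!is.null(external_table)) {
      ext <- external_validate(cv$model, external_table,
                               external_table$labels$dc)
      row <- cbind(row, panel(ext, "ext_"))
    }
    rows[[length(rows) + 1]] <- row
  }
  report <- do.call(rbind, rows)
  attr(report, "experiment") <- spec$name
  attr(report, "seed") <- spec$seed
  attr(report, "config_hash") <- object_md5(unclass(spec))
  attr(report, "package_version") <- as.character(packageVersion("radiomix"))
  class(report) <- c("experiment_report", "data.frame")
  report
}

#' Write an experiment report as TSV (metadata in a JSON sidecar)
#' @param report an `experiment_report`
#' @param path output `.tsv` path
#' @export
write_experiment_report <- function(report, path) {
  write.table(as.data.frame(report), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  meta <- list(experiment = attr(report, "experiment"),
               seed = attr(report, "seed"),
               config_hash = attr(report, "config_hash"),
               package_version = attr(report, "package_version"))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
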