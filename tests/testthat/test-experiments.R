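# Experiment-level tests run on small synthetic cohorts (image sizes scaled
# down for runtime; the grids, selection sizes and report shapes are the
# published ones).

local_cached_tables <- local({
  cache <- new.env()
  function() {
    if (is.null(cache$ft)) {
      cfg <- test_cohort_config(91, n = 16, effect = "strong")
      cohort <- generate_cohort(cfg)
      cache$cohort <- cohort
      cache$ft <- cohort_feature_table(cohort)
      expr <- do.call(rbind, lapply(cohort, `[[`, "expression"))
      rownames(expr) <- rownames(cache$ft$x)
      cache$ft_genes <- merge_omics(cache$ft, expr)
      hc <- setNames(vapply(cohort, `[[`, integer(1), "hotcold_label"),
                     rownames(cache$ft$x))
      cache$ft_hc <- merge_omics(cache$ft, hc)
    }
    cache
  }
})

test_that("pfs_radiomics runs the published 2x2 grid with external
           validation", {
  cache <- local_cached_tables()
  spec <- experiment_spec("pfs_radiomics",
                          cohort_config = test_cohort_config(91, n = 16,
                                                             effect = "strong"),
                          n_select = 10, seed = 7)
  ext_cfg <- test_cohort_config(191, n = 12, effect = "strong")
  ext <- cohort_feature_table(generate_cohort(ext_cfg))
  report <- suppressWarnings(
    run_experiment(spec, table = cache$ft, external_table = ext))
  expect_equal(nrow(report), 4)
  expect_setequal(report$reduction_method, c("relieff", "t_test"))
  expect_setequal(report$learning_method, c("mlp", "svm_linear"))
  expect_true(all(c("train_auroc", "cv_auroc", "ext_auroc",
                    "ext_misclassification_rate") %in% colnames(report)))
  expect_true(all(is.finite(report$ext_auroc)))

  report2 <- suppressWarnings(
    run_experiment(spec, table = cache$ft, external_table = ext))
  expect_identical(as.data.frame(report), as.data.frame(report2))
})

test_that("the three radiogenomic experiments run the 4x2 grid", {
  cache <- local_cached_tables()
  for (case in list(
    list(name = "pfs_multiomics", tbl = cache$ft_genes),
    list(name = "hotcold_radiomics", tbl = cache$ft),
    list(name = "pfs_radiomics_hotcold", tbl = cache$ft_hc))) {
    spec <- experiment_spec(case$name, cohort_config = NULL, n_select = 8,
                            seed = 11)
    report <- suppressWarnings(run_experiment(spec, table = case$tbl))
    expect_equal(nrow(report), 8)
    expect_setequal(report$reduction_method,
                    c("t_test", "wilcoxon", "auroc", "relieff"))
    expect_setequal(report$learning_method, c("tree_ensemble", "svm_linear"))
    expect_false(any(c("ext_auroc") %in% colnames(report)))
  }
})

test_that("default selection sizes follow the published 30/20/15/15", {
  for (nm in names(radiomix:::default_n_select)) {
    spec <- experiment_spec(nm, cohort_config = NULL)
    expect_equal(spec$n_select,
                 unname(radiomix:::default_n_select[[nm]]), info = nm)
  }
  expect_equal(experiment_spec("pfs_radiomics",
                               cohort_config = NULL)$n_select, 30)
})

test_that("the hybrid experiment keeps the HOT/COLD column in the model", {
  cache <- local_cached_tables()
  spec <- experiment_spec("pfs_radiomics_hotcold", cohort_config = NULL,
                          n_select = 6, seed = 13,
                          selectors = "t_test", classifiers = "svm_linear")
  report <- run_experiment(spec, table = cache$ft_hc)
  expect_equal(nrow(report), 1)
  # refit by hand to inspect the selection
  cv <- holdout_cv(cache$ft_hc, cache$ft_hc$labels$dc,
                   model_config("svm_linear", cv_seed = 13),
                   selection_config(n_select = 6,
                                    force_include = "hotcold"))
  expect_true("hotcold" %in% select_top(cv$selection, 6))
  expect_true("hotcold" %in% cv$model$features)
})

test_that("experiments needing omics fail fast without omics", {
  cache <- local_cached_tables()
  spec <- experiment_spec("pfs_multiomics", cohort_config = NULL)
  expect_error(run_experiment(spec, table = cache$ft), "gene expression")
})

test_that("experiment report writes TSV + metadata sidecar", {
  cache <- local_cached_tables()
  spec <- experiment_spec("hotcold_radiomics", cohort_config = NULL,
                          n_select = 5, seed = 3,
                          selectors = "auroc", classifiers = "tree_ensemble")
  report <- run_experiment(spec, table = cache$ft)
  p <- tempfile(fileext = ".tsv")
  write_experiment_report(report, p)
  back <- read.table(p, sep = "\t", header = TRUE)
  expect_equal(nrow(back), 1)
  meta <- jsonlite::read_json(paste0(p, ".meta.json"))
  expect_equal(meta$experiment, "hotcold_radiomics")
  unlink(c(p, paste0(p, ".meta.json")))
})

test_that("CLI: simulate + extract produce one 342-value row; errors exit
           non-zero", {
  out <- tempfile()
  cfg_json <- tempfile(fileext = ".json")
  jsonlite::write_json(list(n_subjects = 2, image_shape = c(20, 20, 14),
                            voxel_spacing_mm = c(1, 1, 1),
                            tumor_radius_mm_by_class = list(c(4, 6), c(4, 6))),
                       cfg_json, auto_unbox = TRUE)
  expect_equal(radiomix_cli(c("simulate", "--config", cfg_json,
                              "--seed", "5", "--out", out)), 0)
  expect_true(file.exists(file.path(out, "subj_001_ct.nii.gz")))
  expect_true(file.exists(file.path(out, "labels.tsv")))

  feat_out <- tempfile(fileext = ".tsv")
  expect_equal(radiomix_cli(c("extract",
                              "--volume", file.path(out, "subj_001_ct.nii.gz"),
                              "--mask", file.path(out, "subj_001_mask.nii.gz"),
                              "--out", feat_out)), 0)
  row <- read_feature_table(feat_out)
  expect_equal(dim(row$x), c(1, 342))

  expect_equal(radiomix_cli(c("extract",
                              "--volume", file.path(out, "subj_001_ct.nii.gz"),
                              "--mask", "/nonexistent/mask.nii.gz")), 1)
  expect_equal(radiomix_cli("frobnicate"), 1)
  unlink(c(out, cfg_json, feat_out, paste0(feat_out, ".manifest.json")),
         recursive = TRUE)
})
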