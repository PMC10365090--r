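# Synthetic imaging + transcriptomic cohorts with the statistical structure
# the analysis assumes: two outcome classes whose lesions differ in size and
# texture homogeneity, a log-scale expression matrix carrying a bimodal
# 27-gene HOT/COLD signature, and binary disease-control labels correlated
# with both. Each subject owns an RNG stream derived from (seed, index), so
# cohorts are extensible without reshuffling earlier subjects.

#' Synthetic cohort configuration
#'
#' Class 1 parameters describe progressive disease (PD), class 2 disease
#' control (DC): responders are modelled as slightly smaller, smoother and
#' less noisy lesions (the homogeneous-responder observation). Defaults:
#' 60 subjects at DC prevalence 60/110, 48x48x36 voxel grids at
#' 1x1x1.5 mm, tumor radii 10-16 mm (PD) vs 8-14 mm (DC), texture
#' correlation lengths 1 vs 2 voxels, intra-lesion white-noise SD 35 vs
#' 15 HU, 2,559 genes with a 27-gene signature shifted +2 log-units in HOT
#' tumors, and a +1.5 shift in the log-odds of HOT given DC.
#'
#' @param n_subjects cohort size
#' @param prevalence_dc P(disease control), in (0, 1)
#' @param image_shape voxel grid, length 3
#' @param voxel_spacing_mm positive spacing, length 3
#' @param tumor_radius_mm_by_class list of two ranges `c(lo, hi)` (PD, DC)
#' @param texture_corr_length_by_class smoothing SD in voxels (PD, DC)
#' @param noise_sd_by_class white-noise SD in HU (PD, DC)
#' @param texture_amplitude_hu amplitude of the smoothed field (both classes)
#' @param n_genes genes in the expression panel (default 2559)
#' @param n_signature_genes HOT/COLD signature size (default 27)
#' @param signature_shift mean log-expression offset of signature genes in
#'   HOT tumors
#' @param hotcold_response_log_odds shift of the HOT log-odds under DC
#' @param seed integer master seed
#' @export
synthetic_cohort_config <- function(n_subjects = 60L,
                                    prevalence_dc = 60 / 110,
                                    image_shape = c(48L, 48L, 36L),
                                    voxel_spacing_mm = c(1, 1, 1.5),
                                    tumor_radius_mm_by_class =
                                      list(c(10, 16), c(8, 14)),
                                    texture_corr_length_by_class = c(1, 2),
                                    noise_sd_by_class = c(35, 15),
                                    texture_amplitude_hu = 30,
                                    n_genes = 2559L,
                                    n_signature_genes = 27L,
                                    signature_shift = 2,
                                    hotcold_response_log_odds = 1.5,
                                    seed = 1L) {
  if (n_subjects < 1) stopf("n_subjects must be positive")
  if (prevalence_dc <= 0 || prevalence_dc >= 1)
    stopf("prevalence_dc must lie in (0, 1)")
  if (any(voxel_spacing_mm <= 0) || length(voxel_spacing_mm) != 3)
    stopf("voxel spacing must be three positive numbers")
  if (any(image_shape < 8)) stopf("image_shape too small")
  for (r in tumor_radius_mm_by_class)
    if (any(r <= 0) || r[2] < r[1]) stopf("tumor radius ranges must be positive")
  if (any(texture_corr_length_by_class <= 0))
    stopf("texture correlation lengths must be positive")
  if (any(noise_sd_by_class < 0)) stopf("noise SDs must be non-negative")
  if (n_signature_genes > n_genes)
    stopf("n_signature_genes (%d) exceeds n_genes (%d)", n_signature_genes,
          n_genes)
  structure(list(n_subjects = as.integer(n_subjects),
                 prevalence_dc = prevalence_dc,
                 image_shape = as.integer(image_shape),
                 voxel_spacing_mm = as.numeric(voxel_spacing_mm),
                 tumor_radius_mm_by_class = tumor_radius_mm_by_class,
                 texture_corr_length_by_class = texture_corr_length_by_class,
                 noise_sd_by_class = noise_sd_by_class,
                 texture_amplitude_hu = texture_amplitude_hu,
                 n_genes = as.integer(n_genes),
                 n_signature_genes = as.integer(n_signature_genes),
                 signature_shift = signature_shift,
                 hotcold_response_log_odds = hotcold_response_log_odds,
                 seed = as.integer(seed)),
            class = "synthetic_cohort_config")
}

#' Names of the genes in the synthetic panel
#' @param config a [synthetic_cohort_config()]
#' @return character vector; the signature genes come first (`immsig_*`)
#' @export
synthetic_gene_names <- function(config) {
  c(sprintf("immsig_%02d", seq_len(config$n_signature_genes)),
    sprintf("gene_%04d", seq_len(config$n_genes - config$n_signature_genes)))
}

simulate_lesion <- function(config, class_idx, rng_seed) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(rng_seed)
  d <- config$image_shape
  sp <- config$voxel_spacing_mm
  rng <- config$tumor_radius_mm_by_class[[class_idx]]
  base_r <- runif(1, rng[1], rng[2])
  radii <- base_r * runif(3, 0.8, 1.2)   # per-axis +-20% jitter
  center <- (d - 1) / 2 * sp + runif(3, -2, 2)
  coords <- lapply(1:3, function(a) (seq_len(d[a]) - 1) * sp[a])
  dist2 <- outer(outer((coords[[1]] - center[1])^2 / radii[1]^2,
                       (coords[[2]] - center[2])^2 / radii[2]^2, `+`),
                 (coords[[3]] - center[3])^2 / radii[3]^2, `+`)
  fg <- dist2 <= 1
  vol <- array(rnorm(prod(d), -800, 10), d)   # lung background
  field <- smooth_gaussian_3d(array(rnorm(prod(d)), d),
                              config$texture_corr_length_by_class[class_idx])
  fsd <- sd(field)
  if (fsd > 0) field <- field / fsd
  lesion <- 40 + config$texture_amplitude_hu * field +
    rnorm(prod(d), 0, config$noise_sd_by_class[class_idx])
  vol[fg] <- lesion[fg]
  list(volume = ct_volume(vol, sp), fg = fg)
}

#' Generate a synthetic cohort
#'
#' Each subject carries a CT volume with an ellipsoid lesion (soft-tissue
#' baseline 40 HU over -800 HU lung background), its segmentation mask, a
#' gene log-expression profile, the disease-control label and the HOT/COLD
#' label. Identical (config, seed) yields a bit-identical cohort.
#'
#' @param config a [synthetic_cohort_config()]
#' @return list of subjects (class `synthetic_subject`)
#' @export
generate_cohort <- function(config = synthetic_cohort_config()) {
  stopifnot(inherits(config, "synthetic_cohort_config"))
  dc <- vapply(seq_len(config$n_subjects), function(i) {
    old <- get_rng_state(); on.exit(restore_rng_state(old))
    set.seed(subject_stream_seed(config$seed, i, 1L))
    as.integer(runif(1) < config$prevalence_dc)
  }, integer(1))
  omics <- generate_transcriptome(config, dc)
  lapply(seq_len(config$n_subjects), function(i) {
    les <- simulate_lesion(config, dc[i] + 1L,
                           subject_stream_seed(config$seed, i, 2L))
    structure(list(subject_id = sprintf("subj_%03d", i),
                   volume = les$volume,
                   mask = segmentation_mask(les$fg, les$volume),
                   expression = omics$expression[i, ],
                   dc_label = dc[i],
                   hotcold_label = omics$hotcold[i]),
              class = "synthetic_subject")
  })
}

#' Generate the synthetic transcriptome and HOT/COLD labels
#'
#' Log-normal background expression (gene means drawn once from N(5, 1),
#' i.i.d. unit-SD noise per subject); the signature genes get a
#' `+signature_shift` mean offset in HOT subjects. HOT assignment is
#' Bernoulli with log-odds `logit(31/54) + log_odds * (dc - 1/2)`, so the
#' marginal HOT fraction stays near the 31/54 observed in the radiogenomic
#' subgroup while HOT correlates with disease control as configured.
#'
#' @param config a [synthetic_cohort_config()]
#' @param dc_labels binary vector of length `n_subjects`
#' @return list: `expression` (subjects x genes matrix),
#'   `hotcold` (binary vector), `signature_genes` (names)
#' @export
generate_transcriptome <- function(config, dc_labels) {
  if (length(dc_labels) != config$n_subjects)
    stopf("dc_labels length (%d) must equal n_subjects (%d)",
          length(dc_labels), config$n_subjects)
  genes <- synthetic_gene_names(config)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(subject_stream_seed(config$seed, 0L, 3L))
  gene_means <- rnorm(config$n_genes, 5, 1)
  base_logit <- qlogis(31 / 54)
  expr <- matrix(0, config$n_subjects, config$n_genes,
                 dimnames = list(sprintf("subj_%03d",
                                         seq_len(config$n_subjects)), genes))
  hot <- integer(config$n_subjects)
  for (i in seq_len(config$n_subjects)) {
    set.seed(subject_stream_seed(config$seed, i, 4L))
    p_hot <- plogis(base_logit +
                      config$hotcold_response_log_odds * (dc_labels[i] - 0.5))
    hot[i] <- as.integer(runif(1) < p_hot)
    e <- gene_means + rnorm(config$n_genes, 0, 1)
    if (hot[i] == 1)
      e[seq_len(config$n_signature_genes)] <-
        e[seq_len(config$n_signature_genes)] + config$signature_shift
    expr[i, ] <- e
  }
  list(expression = expr, hotcold = hot,
       signature_genes = genes[seq_len(config$n_signature_genes)])
}

#' Reference HOT/COLD dichotomizer from a signature
#'
#' A subject is HOT iff the mean of its Z-scored (per gene, across
#' subjects) signature expression exceeds 0.
#'
#' @param expression subjects x genes matrix with gene column names
#' @param signature_genes character vector of signature gene names
#' @return binary vector (1 = HOT), named by subject
#' @export
hotcold_from_signature <- function(expression, signature_genes) {
  missing <- setdiff(signature_genes, colnames(expression))
  if (length(missing) > 0)
    stopf("signature genes absent from expression table: %s",
          paste(missing, collapse = ", "))
  sig <- expression[, signature_genes, drop = FALSE]
  z <- apply(sig, 2, function(col) {
    s <- sd(col)
    if (!is.finite(s) || s == 0) rep(0, length(col))
    else (col - mean(col)) / s
  })
  score <- rowMeans(matrix(z, nrow = nrow(sig)))
  setNames(as.integer(score > 0), rownames(expression))
}

#' Serialize a cohort to disk (NIfTI or DICOM imaging + TSV tables)
#'
#' Writes `<id>_ct.nii.gz` (or a DICOM directory) and `<id>_mask.nii.gz`
#' per subject, `expression.tsv`, `labels.tsv` and `manifest.json`.
#'
#' @param cohort output of [generate_cohort()]
#' @param dir output directory
#' @param config the generating [synthetic_cohort_config()] (echoed into
#'   the manifest)
#' @param imaging_format `"nifti"` or `"dicom"`
#' @export
write_cohort <- function(cohort, dir, config = NULL,
                         imaging_format = c("nifti", "dicom")) {
  imaging_format <- match.arg(imaging_format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in cohort) {
    if (imaging_format == "nifti") {
      write_ct_volume(s$volume, file.path(dir, paste0(s$subject_id,
                                                      "_ct.nii.gz")))
    } else {
      write_dicom_series(s$volume, file.path(dir, paste0(s$subject_id,
                                                         "_ct")))
    }
    write_mask(s$mask, file.path(dir, paste0(s$subject_id, "_mask.nii.gz")))
  }
  expr <- do.call(rbind, lapply(cohort, `[[`, "expression"))
  rownames(expr) <- vapply(cohort, `[[`, character(1), "subject_id")
  write.table(data.frame(subject_id = rownames(expr), expr,
                         check.names = FALSE),
              file.path(dir, "expression.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  labels <- data.frame(
    subject_id = rownames(expr),
    dc = vapply(cohort, `[[`, integer(1), "dc_label"),
    hotcold = vapply(cohort, `[[`, integer(1), "hotcold_label"))
  write.table(labels, file.path(dir, "labels.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  manifest <- list(n_subjects = length(cohort),
                   imaging_format = imaging_format,
                   config = if (!is.null(config)) unclass(config) else NULL,
                   package_version = as.character(packageVersion("radiomix")))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
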