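# Fixtures are built in code; nothing is stored on disk.

# md5 of the shipped registry (names, families, G-levels); adding, removing
# or renaming a feature is a breaking change and must update this constant
FROZEN_REGISTRY_HASH <- "46cae8213469047f2f45ae2ebad95d58"

mask_from_array <- function(fg, spacing = c(1, 1, 1)) {
  structure(list(labels = fg, spacing_mm = rep(spacing, length.out = 3),
                 origin_mm = c(0, 0, 0)),
            class = "segmentation_mask")
}

roi_from_array <- function(intens, fg = array(TRUE, dim(intens)),
                           spacing = 1) {
  isotropic_roi(intens, fg, spacing)
}

ball_array <- function(radius, dims = rep(2 * ceiling(radius) + 9, 3),
                       spacing = c(1, 1, 1), center = NULL) {
  if (is.null(center)) center <- (dims + 1) / 2 * spacing
  g <- lapply(1:3, function(a) (seq_len(dims[a])) * spacing[a])
  outer(outer((g[[1]] - center[1])^2, (g[[2]] - center[2])^2, `+`),
        (g[[3]] - center[3])^2, `+`) <= radius^2
}

ellipsoid_array <- function(radii, dims = 2 * ceiling(radii) + 9,
                            spacing = c(1, 1, 1)) {
  ctr <- (dims + 1) / 2 * spacing
  g <- lapply(1:3, function(a) (seq_len(dims[a])) * spacing[a])
  outer(outer((g[[1]] - ctr[1])^2 / radii[1]^2,
              (g[[2]] - ctr[2])^2 / radii[2]^2, `+`),
        (g[[3]] - ctr[3])^2 / radii[3]^2, `+`) <= 1
}

# irregular blobby slice for moment-invariance properties
random_blob_slice <- function(seed, dim = c(41, 41)) {
  set.seed(seed)
  ctr <- (dim + 1) / 2
  sl <- matrix(FALSE, dim[1], dim[2])
  for (k in 1:4) {
    a <- runif(1, 4, 13); b <- runif(1, 4, 13)
    cx <- runif(1, -5, 5); cy <- runif(1, -5, 5)
    sl <- sl | outer((seq_len(dim[1]) - ctr[1] - cx)^2 / a^2,
                     (seq_len(dim[2]) - ctr[2] - cy)^2 / b^2, `+`) <= 1
  }
  sl
}

slice_mask <- function(sl, pad_z = 3) {
  fg <- array(FALSE, c(dim(sl), pad_z))
  fg[, , ceiling(pad_z / 2)] <- sl
  mask_from_array(fg)
}

random_quantized_roi <- function(seed, dims = c(6, 6, 6), G = 8,
                                 mask_frac = 0.85) {
  set.seed(seed)
  intens <- array(rnorm(prod(dims), 0, 50), dims)
  fg <- array(runif(prod(dims)) < mask_frac, dims)
  if (!any(fg)) fg[1] <- TRUE
  quantize_equal_probability(roi_from_array(intens, fg), G)
}

# small, fast synthetic-cohort configs used by end-to-end tests; image sizes
# are scaled down for runtime, class-effect parameters are the stated world
test_cohort_config <- function(seed, n = 40, effect = c("moderate", "strong",
                                                        "null")) {
  effect <- match.arg(effect)
  base <- list(n_subjects = n, image_shape = c(28L, 28L, 20L),
               voxel_spacing_mm = c(1, 1, 1.2), seed = seed)
  pars <- switch(effect,
    strong = list(tumor_radius_mm_by_class = list(c(6, 9), c(4, 7)),
                  texture_corr_length_by_class = c(0.8, 2.5),
                  noise_sd_by_class = c(60, 5),
                  signature_shift = 3, hotcold_response_log_odds = 6),
    moderate = list(tumor_radius_mm_by_class = list(c(5, 8), c(4, 7)),
                    texture_corr_length_by_class = c(1, 2),
                    noise_sd_by_class = c(35, 15)),
    null = list(tumor_radius_mm_by_class = list(c(5, 8), c(5, 8)),
                texture_corr_length_by_class = c(1.5, 1.5),
                noise_sd_by_class = c(25, 25),
                signature_shift = 0, hotcold_response_log_odds = 0))
  do.call(synthetic_cohort_config, c(base, pars))
}
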