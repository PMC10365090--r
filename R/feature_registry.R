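# The pinned 342-feature registry. The published pipeline reports "342
# radiomic features" but never enumerates them, so this manifest is the
# package's source of truth: it totals exactly 342, respects every family
# count reported for the selected-feature tables as a lower bound, and
# allocates the texture-matrix features across the 7 gray-level counts.
# Provenance tags distinguish features the source names explicitly
# ("paper-named"), community-standard definitions ("standard"), and
# families that are named but never defined, for which this package's
# concrete definitions stand in ("artifact-defined").

registry_row <- function(name, family, G = NA_integer_, provenance,
                         offset_invariant, paper_name = NA_character_) {
  data.frame(name = name, family = family, G = G, provenance = provenance,
             offset_invariant = offset_invariant, paper_name = paper_name,
             stringsAsFactors = FALSE)
}

#' The canonical 342-feature registry
#'
#' @return data.frame with columns `name` (unique), `family`, `G`
#'   (gray-level count, NA for non-quantized features), `provenance`,
#'   `offset_invariant` (is the feature unchanged by adding a constant HU
#'   offset), `paper_name` (the display name used in the source's tables,
#'   where one exists)
#' @export
feature_registry <- function() {
  rows <- list()
  add <- function(...) rows[[length(rows) + 1]] <<- registry_row(...)

  size_names <- c("shape_volume_mm3", "shape_surface_mm2", "shape_sphericity",
                  "shape_compactness", "shape_max_diameter_mm")
  for (nm in size_names) add(nm, "size", provenance = "standard",
                             offset_invariant = TRUE)
  for (i in 1:8) add(sprintf("hu_%d", i), "hu_moments",
                     provenance = "paper-named", offset_invariant = TRUE)
  for (i in 1:6) add(sprintf("affine_%d", i), "affine_moments",
                     provenance = "paper-named", offset_invariant = TRUE)
  for (p in zernike_pairs(4))
    add(sprintf("zernike_%d_%d", p[1], p[2]), "zernike",
        provenance = "paper-named", offset_invariant = TRUE)
  for (nm in c("skel_n_branch_points", "skel_n_endpoints", "skel_length_mm",
               "skel_mean_branch_length_mm"))
    add(nm, "skeleton", provenance = "artifact-defined",
        offset_invariant = TRUE)
  for (nm in c("dist_mean_mm", "dist_sd_mm", "dist_max_min_ratio",
               "dist_entropy"))
    add(nm, "dist", provenance = "artifact-defined", offset_invariant = TRUE)
  add("lacunarity", "lacunarity", provenance = "paper-named",
      offset_invariant = TRUE)
  fo <- c("fo_mean", "fo_variance", "fo_skewness", "fo_kurtosis", "fo_energy",
          "fo_entropy", "fo_p10", "fo_p25", "fo_median", "fo_p75", "fo_p90",
          "fo_iqr", "fo_range", "fo_mad")
  for (nm in fo) add(nm, "first_order", provenance = "standard",
                     offset_invariant = FALSE)

  glcm <- c("energy", "contrast", "correlation", "homogeneity", "entropy",
            "dissimilarity", "cluster_shade", "cluster_prominence")
  glrlm <- c("SRE", "LRE", "GLN", "RLN", "RP", "LGRE", "HGRE", "SRLGE",
             "SRHGE", "LRLGE", "LRHGE")
  glszm <- c("SZE", "LZE", "GLN", "ZSN", "ZP", "LGZE", "HGZE", "SZLGE",
             "SZHGE", "LZLGE", "LZHGE")
  ngtdm <- c("coarseness", "contrast", "busyness", "complexity", "strength")
  paper_names <- c(glrlm_GLN = "Gray Level Non-Uniformity",
                   glrlm_LRHGE = "Long Run High Gray Level Emphasis",
                   glszm_GLN = "Gray Level Non-Uniformity",
                   glszm_LZE = "Large Zone Size Emphasis",
                   glszm_ZSN = "Zone Size Non-Uniformity",
                   ngtdm_contrast = "NGTDM contrast")
  pn <- function(key)
    if (key %in% names(paper_names)) unname(paper_names[[key]])
    else NA_character_
  for (G in default_gray_levels()) {
    for (fam in c("glcm", "glrlm", "glszm", "ngtdm")) {
      feats <- switch(fam, glcm = glcm, glrlm = glrlm, glszm = glszm,
                      ngtdm = ngtdm)
      for (f in feats) {
        key <- paste0(fam, "_", f)
        add(sprintf("%s_G%d", key, G), fam, G,
            if (key %in% names(paper_names)) "paper-named" else "standard",
            TRUE, pn(key))
      }
    }
  }

  for (o in 1:6) for (s in 1:5)
    add(sprintf("gabor_energy_s%d_o%d", s, o), "gabor",
        provenance = "paper-named", offset_invariant = TRUE)
  for (i in 1:6) add(sprintf("fourier_ring%d", i), "fourier",
                     provenance = "artifact-defined",
                     offset_invariant = FALSE)
  add("fourier_spectral_entropy", "fourier", provenance = "artifact-defined",
      offset_invariant = FALSE)
  add("surf_keypoint_density", "surf", provenance = "artifact-defined",
      offset_invariant = TRUE)
  add("harris_response", "harris", provenance = "artifact-defined",
      offset_invariant = TRUE)
  for (nm in c("grad_mean", "grad_sd", "grad_entropy"))
    add(nm, "grad", provenance = "artifact-defined", offset_invariant = TRUE)
  for (nm in c("losib_mean_0", "losib_mean_45", "losib_mean_90",
               "losib_mean_135"))
    add(nm, "losib", provenance = "artifact-defined", offset_invariant = TRUE)

  reg <- do.call(rbind, rows)
  rownames(reg) <- NULL
  reg
}

#' Stable hash of the shipped registry (breaking-change sentinel)
#' @return md5 string
#' @export
feature_registry_hash <- function() {
  reg <- feature_registry()
  object_md5(list(reg$name, reg$family, reg$G))
}
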