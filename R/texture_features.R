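# First-order statistics and the four texture-matrix families, at the
# parameterization used throughout the pipeline: GLCM and GLRLM over the four
# in-plane directions (0, 45, 90, 135 degrees) at offset one voxel, swept
# through the full 3-D ROI; GLSZM zones and NGTDM neighborhoods with
# 26-connectivity. Feature formulas follow the IBSI reference definitions.

texture_directions <- function() {
  list(c(1L, 0L, 0L), c(1L, 1L, 0L), c(0L, 1L, 0L), c(-1L, 1L, 0L))
}

#' First-order (histogram) intensity features
#'
#' Statistics of the in-mask HU distribution; entropy and energy
#' (uniformity) come from a 256-bin equal-width histogram spanning the
#' in-mask range. A constant ROI has zero variance, entropy, skewness and
#' kurtosis by convention.
#'
#' @param roi an [isotropic_roi()]
#' @return named numeric vector of 14 features
#' @export
first_order <- function(roi) {
  v <- roi$intensities[roi$mask]
  n <- length(v)
  mu <- mean(v)
  vr <- if (n > 1) sum((v - mu)^2) / n else 0
  if (vr > 0) {
    sk <- sum((v - mu)^3) / n / vr^1.5
    ku <- sum((v - mu)^4) / n / vr^2 - 3
  } else {
    sk <- 0; ku <- 0
  }
  rng <- range(v)
  if (diff(rng) > 0) {
    h <- tabulate(pmin(floor((v - rng[1]) / diff(rng) * 256) + 1, 256),
                  nbins = 256)
    p <- h / n
  } else {
    p <- c(1, rep(0, 255))
  }
  q <- quantile(v, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE, type = 7)
  c(fo_mean = mu, fo_variance = vr, fo_skewness = sk, fo_kurtosis = ku,
    fo_energy = sum(p^2), fo_entropy = shannon_entropy_bits(p),
    fo_p10 = q[1], fo_p25 = q[2], fo_median = q[3], fo_p75 = q[4],
    fo_p90 = q[5], fo_iqr = q[4] - q[2], fo_range = diff(rng),
    fo_mad = mean(abs(v - mu)))
}

glcm_single <- function(P) {
  G <- nrow(P)
  i <- row(P); j <- col(P)
  pi_ <- rowSums(P)
  mu_i <- sum(seq_len(G) * pi_)
  sd_i <- sqrt(sum((seq_len(G) - mu_i)^2 * pi_))
  corr <- if (sd_i > 0)
    sum((i - mu_i) * (j - mu_i) * P) / sd_i^2 else 1
  c(energy = sum(P^2),
    contrast = sum((i - j)^2 * P),
    correlation = corr,
    homogeneity = sum(P / (1 + abs(i - j))),
    entropy = shannon_entropy_bits(P),
    dissimilarity = sum(abs(i - j) * P),
    cluster_shade = sum((i + j - 2 * mu_i)^3 * P),
    cluster_prominence = sum((i + j - 2 * mu_i)^4 * P))
}

#' Gray-level co-occurrence features
#'
#' One symmetric, normalized G x G matrix per direction; the 8 features are
#' computed per direction then averaged. Directions with no valid voxel pair
#' are skipped from the average.
#'
#' @param q a [quantize_equal_probability()] result
#' @return named numeric vector `glcm_*`
#' @export
glcm_features <- function(q) {
  vals <- NULL
  for (off in texture_directions()) {
    M <- cpp_glcm(as.integer(q$levels), as.integer(dim(q$levels)), q$G, off)
    if (sum(M) == 0) next
    vals <- rbind(vals, glcm_single(M / sum(M)))
  }
  if (is.null(vals))
    vals <- rbind(c(energy = 1, contrast = 0, correlation = 1,
                    homogeneity = 1, entropy = 0, dissimilarity = 0,
                    cluster_shade = 0, cluster_prominence = 0))
  setNames(colMeans(vals), paste0("glcm_", colnames(vals)))
}

glrlm_single <- function(M, n_voxels) {
  g <- row(M); r <- col(M)
  Nr <- sum(M)
  c(SRE = sum(M / r^2) / Nr,
    LRE = sum(M * r^2) / Nr,
    GLN = sum(rowSums(M)^2) / Nr,
    RLN = sum(colSums(M)^2) / Nr,
    RP = Nr / n_voxels,
    LGRE = sum(M / g^2) / Nr,
    HGRE = sum(M * g^2) / Nr,
    SRLGE = sum(M / (g^2 * r^2)) / Nr,
    SRHGE = sum(M * g^2 / r^2) / Nr,
    LRLGE = sum(M * r^2 / g^2) / Nr,
    LRHGE = sum(M * g^2 * r^2) / Nr)
}

#' Gray-level run-length features
#'
#' Per-direction run-length matrices averaged over the four in-plane
#' directions. Includes Gray Level Non-Uniformity (GLN) and Long Run High
#' Gray Level Emphasis (LRHGE) under their usual abbreviations.
#'
#' @inheritParams glcm_features
#' @return named numeric vector `glrlm_*`
#' @export
glrlm_features <- function(q) {
  nv <- sum(q$mask)
  vals <- NULL
  for (off in texture_directions()) {
    M <- cpp_glrlm(as.integer(q$levels), as.integer(dim(q$levels)), q$G, off)
    keep <- seq_len(max(which(colSums(M) > 0)))
    vals <- rbind(vals, glrlm_single(M[, keep, drop = FALSE], nv))
  }
  setNames(colMeans(vals), paste0("glrlm_", colnames(vals)))
}

#' Raw run-length matrix for one direction (exposed for identity checks)
#' @inheritParams glcm_features
#' @param direction integer offset, length 3
#' @return numeric matrix G x Rmax of run counts
#' @export
run_length_matrix <- function(q, direction) {
  M <- cpp_glrlm(as.integer(q$levels), as.integer(dim(q$levels)), q$G,
                 as.integer(direction))
  M[, seq_len(max(which(colSums(M) > 0))), drop = FALSE]
}

#' Size-zone matrix: zones are 26-connected components of constant level
#' @inheritParams glcm_features
#' @return numeric matrix G x Smax of zone counts
#' @export
size_zone_matrix <- function(q) {
  lab <- cpp_label_zones(as.integer(q$levels), as.integer(dim(q$levels)),
                         TRUE)
  inz <- lab > 0
  sizes <- tabulate(lab[inz])
  lev <- integer(length(sizes))
  lev[lab[inz]] <- q$levels[inz]
  M <- matrix(0, q$G, max(sizes))
  for (z in seq_along(sizes)) M[lev[z], sizes[z]] <- M[lev[z], sizes[z]] + 1
  M
}

#' Gray-level size-zone features
#'
#' Zones are 26-connected components of equal level. Includes Large Zone
#' Size Emphasis (LZE), Zone Size Non-Uniformity (ZSN) and Gray Level
#' Non-Uniformity (GLN).
#'
#' @inheritParams glcm_features
#' @return named numeric vector `glszm_*`
#' @export
glszm_features <- function(q) {
  M <- size_zone_matrix(q)
  g <- row(M); s <- col(M)
  Nz <- sum(M)
  nv <- sum(q$mask)
  out <- c(SZE = sum(M / s^2) / Nz,
           LZE = sum(M * s^2) / Nz,
           GLN = sum(rowSums(M)^2) / Nz,
           ZSN = sum(colSums(M)^2) / Nz,
           ZP = Nz / nv,
           LGZE = sum(M / g^2) / Nz,
           HGZE = sum(M * g^2) / Nz,
           SZLGE = sum(M / (g^2 * s^2)) / Nz,
           SZHGE = sum(M * g^2 / s^2) / Nz,
           LZLGE = sum(M * s^2 / g^2) / Nz,
           LZHGE = sum(M * g^2 * s^2) / Nz)
  setNames(out, paste0("glszm_", names(out)))
}

#' Neighborhood gray-tone difference table (n_g, s_g)
#' @inheritParams glcm_features
#' @return matrix with columns `n` and `s`, one row per level
#' @export
ngtdm_table <- function(q) {
  out <- cpp_ngtdm(as.integer(q$levels), as.integer(dim(q$levels)), q$G)
  colnames(out) <- c("n", "s")
  out
}

#' NGTDM features (Amadasun & King)
#'
#' Coarseness, contrast, busyness, complexity and strength over
#' 26-neighborhoods restricted to in-mask neighbors.
#'
#' @inheritParams glcm_features
#' @return named numeric vector `ngtdm_*`
#' @export
ngtdm_features <- function(q) {
  tab <- ngtdm_table(q)
  n_g <- tab[, "n"]; s_g <- tab[, "s"]
  n <- sum(n_g)
  p <- n_g / n
  act <- which(p > 0)
  lev <- seq_along(p)
  eps <- 1e-12
  coarseness <- min(1 / (eps + sum(p * s_g)), 1e6)
  if (length(act) > 1) {
    pij <- outer(p[act], p[act])
    dij <- outer(lev[act], lev[act], `-`)
    contrast <- sum(pij * dij^2) / (length(act) * (length(act) - 1)) *
      sum(s_g) / n
    busy_den <- sum(abs(outer(lev[act] * p[act], lev[act] * p[act], `-`)))
    busyness <- if (busy_den > 0) sum(p * s_g) / busy_den else 0
    psij <- outer(p[act] * s_g[act], p[act] * s_g[act], `+`)
    complexity <- sum(abs(dij) * psij / outer(p[act], p[act], `+`)) / n
    strength <- sum(outer(p[act], p[act], `+`) * dij^2) / (eps + sum(s_g))
  } else {
    contrast <- 0; busyness <- 0; complexity <- 0; strength <- 0
  }
  c(ngtdm_coarseness = coarseness, ngtdm_contrast = contrast,
    ngtdm_busyness = busyness, ngtdm_complexity = complexity,
    ngtdm_strength = strength)
}

#' Gliding-box lacunarity of the binary mask
#'
#' `Lambda(r) = E(M^2) / E(M)^2` over all boxes of side r fully inside the
#' mask bounding box, for r on a fixed ladder (2, 4, 8 voxels, clamped to
#' the bounding box). The scalar registry feature is the least-squares slope
#' of log Lambda against log r (0 if only one box size fits).
#'
#' @param mask a [segmentation_mask()] (or anything with `$labels`)
#' @return list with `box_sizes`, `lacunarity` (per box size) and `slope`
#' @export
lacunarity <- function(mask) {
  fg <- mask$labels
  w <- which(fg, arr.ind = TRUE)
  lo <- apply(w, 2, min); hi <- apply(w, 2, max)
  crop <- fg[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  d <- dim(crop)
  ladder <- c(2L, 4L, 8L)
  ladder <- ladder[ladder <= min(d)]
  if (length(ladder) == 0) ladder <- 1L
  # 3-D summed-area table
  sat <- apply(apply(apply(crop * 1, c(2, 3), cumsum), c(1, 3), cumsum),
               c(1, 2), cumsum)
  sat <- aperm(sat, c(2, 3, 1))
  pad <- array(0, d + 1)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- sat
  box_sum <- function(r) {
    xs <- 1:(d[1] - r + 1); ys <- 1:(d[2] - r + 1); zs <- 1:(d[3] - r + 1)
    s <- pad[xs + r, ys + r, zs + r, drop = FALSE] -
      pad[xs, ys + r, zs + r, drop = FALSE] -
      pad[xs + r, ys, zs + r, drop = FALSE] -
      pad[xs + r, ys + r, zs, drop = FALSE] +
      pad[xs, ys, zs + r, drop = FALSE] +
      pad[xs, ys + r, zs, drop = FALSE] +
      pad[xs + r, ys, zs, drop = FALSE] -
      pad[xs, ys, zs, drop = FALSE]
    as.numeric(s)
  }
  lam <- vapply(ladder, function(r) {
    m <- box_sum(r)
    if (mean(m) == 0) return(1)
    mean(m^2) / mean(m)^2
  }, numeric(1))
  slope <- if (length(ladder) > 1)
    unname(stats::coef(stats::lm(log(lam) ~ log(ladder)))[2]) else 0
  list(box_sizes = ladder, lacunarity = lam, slope = slope)
}
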