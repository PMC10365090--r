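# Frequency-domain and descriptor features: Gabor bank, Fourier rings,
# blob/corner keypoints, gradient statistics, local oriented intensity
# differences (LOSIB). All operators are 2-D per axial slice with
# mask-weighted aggregation, the plane in which their classical definitions
# live; every descriptor is invariant to a constant HU offset.

#' Gabor filter bank configuration
#'
#' Wavelengths grow geometrically with ratio sqrt(2) from the minimum; the
#' orientations are evenly spaced over `[0, pi)`.
#'
#' @param n_scales number of wavelengths (default 5)
#' @param n_orientations number of orientations (default 6)
#' @param min_wavelength shortest wavelength in voxels (default 3)
#' @param scale_ratio multiplicative wavelength step (default `sqrt(2)`)
#' @export
gabor_bank_config <- function(n_scales = 5L, n_orientations = 6L,
                              min_wavelength = 3, scale_ratio = sqrt(2)) {
  stopifnot(n_scales >= 1, n_orientations >= 1, min_wavelength > 0,
            scale_ratio > 1)
  structure(list(n_scales = as.integer(n_scales),
                 n_orientations = as.integer(n_orientations),
                 min_wavelength = min_wavelength,
                 scale_ratio = scale_ratio),
            class = "gabor_bank_config")
}

gabor_kernel_pair <- function(wavelength, theta, bandwidth_sigma = 0.56) {
  sigma <- bandwidth_sigma * wavelength
  radius <- max(2L, ceiling(2 * sigma))
  g <- seq(-radius, radius)
  X <- outer(g, rep(1, length(g)))
  Y <- outer(rep(1, length(g)), g)
  xr <- X * cos(theta) + Y * sin(theta)
  yr <- -X * sin(theta) + Y * cos(theta)
  env <- exp(-(xr^2 + yr^2) / (2 * sigma^2))
  # DC response of the even part removed so constant images map to zero
  even <- env * cos(2 * pi * xr / wavelength)
  even <- even - env * sum(even) / sum(env)
  odd <- env * sin(2 * pi * xr / wavelength)
  norm <- sqrt(sum(even^2) + sum(odd^2))
  list(even = even / norm, odd = odd / norm)
}

roi_slices_with_mask <- function(roi, min_pixels = 1) {
  zs <- which(apply(roi$mask, 3, sum) >= min_pixels)
  lapply(zs, function(z) list(img = roi$intensities[, , z],
                              mask = roi$mask[, , z]))
}

#' Gabor bank features
#'
#' Each of the `n_scales * n_orientations` quadrature filters is applied to
#' every axial slice; the in-mask response energy (mean squared magnitude)
#' and mean absolute magnitude are aggregated over slices by mask-weighted
#' mean. The pinned feature registry keeps the 30 energies.
#'
#' @param roi an [isotropic_roi()]
#' @param cfg a [gabor_bank_config()]
#' @return named numeric vector `gabor_energy_s*_o*`, `gabor_meanabs_s*_o*`
#' @export
gabor_features <- function(roi, cfg = gabor_bank_config()) {
  slices <- roi_slices_with_mask(roi)
  wavelengths <- cfg$min_wavelength * cfg$scale_ratio^(seq_len(cfg$n_scales) - 1)
  thetas <- (seq_len(cfg$n_orientations) - 1) * pi / cfg$n_orientations
  kernels <- lapply(seq_len(cfg$n_scales), function(si)
    lapply(seq_len(cfg$n_orientations), function(oi)
      gabor_kernel_pair(wavelengths[si], thetas[oi])))
  energy <- matrix(0, cfg$n_scales, cfg$n_orientations)
  meanabs <- matrix(0, cfg$n_scales, cfg$n_orientations)
  wsum <- 0
  for (sl in slices) {
    wt <- sum(sl$mask)
    wsum <- wsum + wt
    for (si in seq_len(cfg$n_scales))
      for (oi in seq_len(cfg$n_orientations)) {
        k <- kernels[[si]][[oi]]
        eo <- cpp_filter2_masked(sl$img, k$even, k$odd, sl$mask)
        mag2 <- eo[, 1]^2 + eo[, 2]^2
        energy[si, oi] <- energy[si, oi] + wt * mean(mag2)
        meanabs[si, oi] <- meanabs[si, oi] + wt * mean(sqrt(mag2))
      }
  }
  energy <- energy / wsum
  meanabs <- meanabs / wsum
  nm <- function(stat) as.vector(outer(seq_len(cfg$n_scales),
                                       seq_len(cfg$n_orientations),
                                       function(s, o)
                                         sprintf("gabor_%s_s%d_o%d", stat, s, o)))
  c(setNames(as.vector(energy), nm("energy")),
    setNames(as.vector(meanabs), nm("meanabs")))
}

#' Fourier spectrum features
#'
#' Power spectrum of the mask-windowed ROI (3-D FFT). Features are the
#' energy fractions in 6 equal-width radial-frequency rings plus the
#' spectral entropy of the normalized power distribution.
#'
#' @param roi an [isotropic_roi()]
#' @param n_rings number of radial rings (default 6)
#' @return named numeric vector `fourier_ring1..n`, `fourier_spectral_entropy`
#' @export
fourier_features <- function(roi, n_rings = 6L) {
  arr <- roi$intensities * roi$mask
  d <- dim(arr)
  pw <- Mod(fft(arr))^2
  fr <- lapply(d, function(n) {
    k <- 0:(n - 1)
    pmin(k, n - k) / n
  })
  r <- sqrt(outer(outer(fr[[1]]^2, fr[[2]]^2, `+`), fr[[3]]^2, `+`))
  rmax <- sqrt(3) / 2
  ring <- pmin(floor(r / rmax * n_rings) + 1, n_rings)
  tot <- sum(pw)
  frac <- if (tot > 0)
    vapply(seq_len(n_rings), function(b) sum(pw[ring == b]) / tot,
           numeric(1))
  else c(1, rep(0, n_rings - 1))
  p <- as.vector(pw) / max(tot, .Machine$double.xmin)
  c(setNames(frac, paste0("fourier_ring", seq_len(n_rings))),
    fourier_spectral_entropy = shannon_entropy_bits(p))
}

gaussian_kernel_1d_deriv <- function(sigma, order) {
  radius <- max(2L, ceiling(3 * sigma))
  g <- seq(-radius, radius)
  g0 <- exp(-g^2 / (2 * sigma^2)); g0 <- g0 / sum(g0)
  switch(order + 1,
         g0,
         -g / sigma^2 * exp(-g^2 / (2 * sigma^2)),
         {
           # exact zero sum so constant offsets give exactly zero response
           k <- (g^2 / sigma^4 - 1 / sigma^2) * exp(-g^2 / (2 * sigma^2))
           k - mean(k)
         })
}

# separable Gaussian(-derivative) filtering: kernel = outer(kx, ky)
filter2_gauss <- function(img, sigma, deriv = c(0, 0)) {
  kx <- gaussian_kernel_1d_deriv(sigma, deriv[1])
  ky <- gaussian_kernel_1d_deriv(sigma, deriv[2])
  cpp_filter2(cpp_filter2(img, matrix(kx, ncol = 1)), matrix(ky, nrow = 1))
}

sobel_gradients <- function(img) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3) / 8
  list(gx = cpp_filter2(img, kx), gy = cpp_filter2(img, t(kx)))
}

#' Keypoint, corner, gradient and LOSIB descriptor features
#'
#' Per axial slice within the mask: determinant-of-Hessian blob keypoint
#' density over a three-scale ladder (a fixed-threshold stand-in for the
#' fast-Hessian detector), structure-tensor corner response, Sobel
#' gradient-magnitude statistics, and the mean absolute oriented intensity
#' difference at offset one voxel for four orientations (LOSIB). Aggregated
#' over slices by mask-weighted mean. Slices need at least 9 in-plane mask
#' pixels; if no slice qualifies all features are zero with a warning.
#'
#' @param roi an [isotropic_roi()]
#' @param doh_threshold determinant-of-Hessian keypoint threshold (HU^2)
#' @return named numeric vector: `surf_keypoint_density`, `harris_response`,
#'   `grad_mean`, `grad_sd`, `grad_entropy`, `losib_mean_0/45/90/135`
#' @export
keypoint_gradient_features <- function(roi, doh_threshold = 50) {
  zero <- c(surf_keypoint_density = 0, harris_response = 0,
            grad_mean = 0, grad_sd = 0, grad_entropy = 0,
            losib_mean_0 = 0, losib_mean_45 = 0, losib_mean_90 = 0,
            losib_mean_135 = 0)
  slices <- roi_slices_with_mask(roi, min_pixels = 9)
  if (length(slices) == 0) {
    warning("no slice has 9 or more in-mask pixels; descriptor features set to 0",
            call. = FALSE)
    return(zero)
  }
  acc <- zero
  wsum <- 0
  n_kp <- 0
  area_mm2 <- 0
  for (sl in slices) {
    wt <- sum(sl$mask)
    wsum <- wsum + wt
    gr <- sobel_gradients(sl$img)
    gmag <- sqrt(gr$gx^2 + gr$gy^2)[sl$mask]
    h <- tabulate(cut(gmag, breaks = seq(0, max(gmag) + 1e-9,
                                         length.out = 17),
                      labels = FALSE), nbins = 16)
    acc["grad_mean"] <- acc["grad_mean"] + wt * mean(gmag)
    acc["grad_sd"] <- acc["grad_sd"] + wt * (if (length(gmag) > 1) sd(gmag) else 0)
    acc["grad_entropy"] <- acc["grad_entropy"] +
      wt * shannon_entropy_bits(h / sum(h))
    # structure tensor (Harris) with Gaussian integration sigma 1
    Axx <- filter2_gauss(gr$gx^2, 1); Ayy <- filter2_gauss(gr$gy^2, 1)
    Axy <- filter2_gauss(gr$gx * gr$gy, 1)
    R <- (Axx * Ayy - Axy^2) - 0.05 * (Axx + Ayy)^2
    acc["harris_response"] <- acc["harris_response"] +
      wt * mean(pmax(R[sl$mask], 0))
    # determinant-of-Hessian blob ladder
    for (sg in c(1.2, 2.4, 4.8)) {
      Lxx <- filter2_gauss(sl$img, sg, c(2, 0)) * sg^2
      Lyy <- filter2_gauss(sl$img, sg, c(0, 2)) * sg^2
      Lxy <- filter2_gauss(sl$img, sg, c(1, 1)) * sg^2
      doh <- Lxx * Lyy - (0.9 * Lxy)^2
      n_kp <- n_kp + count_local_maxima(doh, sl$mask, doh_threshold)
    }
    area_mm2 <- area_mm2 + wt * roi$spacing_mm^2
    for (i in seq_along(losib_offsets)) {
      off <- losib_offsets[[i]]
      acc[5 + i] <- acc[5 + i] + wt * oriented_mean_diff(sl$img, sl$mask, off)
    }
  }
  out <- acc / wsum
  out["surf_keypoint_density"] <- n_kp / area_mm2
  out
}

losib_offsets <- list(c(1L, 0L), c(1L, 1L), c(0L, 1L), c(-1L, 1L))

oriented_mean_diff <- function(img, mask, off) {
  d <- dim(img)
  xs <- seq_len(d[1]); ys <- seq_len(d[2])
  x2 <- xs + off[1]; y2 <- ys + off[2]
  okx <- x2 >= 1 & x2 <= d[1]; oky <- y2 >= 1 & y2 <= d[2]
  a <- img[xs[okx], ys[oky], drop = FALSE]
  b <- img[x2[okx], y2[oky], drop = FALSE]
  m <- mask[xs[okx], ys[oky], drop = FALSE] & mask[x2[okx], y2[oky], drop = FALSE]
  if (!any(m)) return(0)
  mean(abs(a - b)[m])
}

count_local_maxima <- function(resp, mask, threshold) {
  d <- dim(resp)
  if (any(d < 3)) return(0L)
  ctr <- resp[2:(d[1] - 1), 2:(d[2] - 1)]
  is_max <- ctr > threshold & mask[2:(d[1] - 1), 2:(d[2] - 1)]
  for (dx in -1:1) for (dy in -1:1) {
    if (dx == 0 && dy == 0) next
    nb <- resp[2:(d[1] - 1) + dx, 2:(d[2] - 1) + dy]
    is_max <- is_max & ctr >= nb
  }
  sum(is_max)
}
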