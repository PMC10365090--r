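# Morphology of the binary lesion mask: size, planar moment invariants,
# skeleton and radial-distance descriptors. The 2-D moment families (Hu,
# affine, Zernike) are computed on the largest-area axial slice — the
# classical planar definitions, consistent with the in-plane angle
# conventions used for the texture matrices.

mask_boundary_voxels <- function(fg) {
  d <- dim(fg)
  pad <- array(FALSE, d + 2)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- fg
  core <- pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
  exposed <- core & !(pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] &
                      pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] &
                      pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] &
                      pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] &
                      pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] &
                      pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)])
  which(exposed, arr.ind = TRUE)
}

exposed_face_flags <- function(fg, axis) {
  d <- dim(fg)
  pad_dim <- d; pad_dim[axis] <- d[axis] + 2
  pad <- array(FALSE, pad_dim)
  idx <- lapply(seq_len(3), function(a)
    if (a == axis) 2:(d[a] + 1) else seq_len(d[a]))
  pad[idx[[1]], idx[[2]], idx[[3]]] <- fg
  lo <- idx; lo[[axis]] <- 1:d[axis]
  hi <- idx; hi[[axis]] <- 3:(d[axis] + 2)
  (fg & !pad[lo[[1]], lo[[2]], lo[[3]]]) +
    (fg & !pad[hi[[1]], hi[[2]], hi[[3]]])
}

# Digital surface area from the 0.5 iso-surface of the lightly smoothed
# (sigma 1 voxel) mask indicator, meshed by marching tetrahedra with linear
# edge interpolation. Plain face counting overestimates oblique surfaces
# (x1.5 for spheres); the smoothed iso-mesh converges to the true area for
# smooth digital shapes. Very small masks whose smoothed field never
# reaches 0.5 fall back to exact face counting.
digital_surface_mesh <- function(fg, sp) {
  sm <- smooth_gaussian_3d(fg * 1, 1)
  out <- cpp_mesh_area_volume(as.numeric(sm), as.integer(dim(fg)),
                              as.numeric(sp), 0.5)
  if (out[1] > 0) return(list(area = out[1], volume = out[2]))
  face_area <- c(sp[2] * sp[3], sp[1] * sp[3], sp[1] * sp[2])
  area <- sum(vapply(1:3, function(a)
    sum(exposed_face_flags(fg, a)) * face_area[a], numeric(1)))
  list(area = area, volume = sum(fg) * prod(sp))
}

#' Size and global shape features of a lesion mask
#'
#' Volume is voxel count times voxel volume. Surface is the area of the 0.5
#' iso-surface mesh of the lightly smoothed mask (marching tetrahedra);
#' sphericity `pi^(1/3) * (6V)^(2/3) / A` and compactness
#' `V / (sqrt(pi) * A^(3/2))` use the mesh's own enclosed volume so the
#' isoperimetric bound (sphericity <= 1) holds by construction. The maximum
#' 3-D diameter is the largest pairwise distance between boundary voxel
#' centers.
#'
#' @param mask a [segmentation_mask()]
#' @param spacing_mm optional spacing override (defaults to the mask's)
#' @return named numeric vector of 5 features
#' @export
size_shape <- function(mask, spacing_mm = mask$spacing_mm) {
  fg <- mask$labels
  sp <- rep(spacing_mm, length.out = 3)
  nvox <- sum(fg)
  volume <- nvox * prod(sp)
  mesh <- digital_surface_mesh(fg, sp)
  bd <- mask_boundary_voxels(fg)
  maxdiam <- if (nrow(bd) < 2) 0 else
    cpp_max_pairwise(sweep(bd, 2, sp, `*`))
  c(shape_volume_mm3 = volume,
    shape_surface_mm2 = mesh$area,
    shape_sphericity = pi^(1 / 3) * (6 * mesh$volume)^(2 / 3) / mesh$area,
    shape_compactness = mesh$volume / (sqrt(pi) * mesh$area^1.5),
    shape_max_diameter_mm = maxdiam)
}

largest_axial_slice <- function(fg) {
  areas <- apply(fg, 3, sum)
  fg[, , which.max(areas)]
}

# Exact geometric central moments of the pixel region (each pixel treated
# as a unit square, monomials integrated in closed form). With region
# moments, integer pixel replication is an exact affine image of the shape,
# so the affine invariants are invariant to floating-point precision.
central_moments_2d <- function(slice, max_order = 4) {
  w <- which(slice, arr.ind = TRUE)
  x <- w[, 1]; y <- w[, 2]
  xc <- mean(x); yc <- mean(y)
  seg <- function(c, p) ((c + 0.5)^(p + 1) - (c - 0.5)^(p + 1)) / (p + 1)
  mu <- matrix(0, max_order + 1, max_order + 1)
  for (p in 0:max_order)
    for (q in 0:max_order)
      if (p + q <= max_order)
        mu[p + 1, q + 1] <- sum(seg(x - xc, p) * seg(y - yc, q))
  mu
}

#' Moment-invariant shape features
#'
#' Computed on the largest-area axial slice of the mask: the 7 classical Hu
#' invariants plus the 8th skew invariant; the first 6 affine moment
#' invariants (orders up to 4); and the magnitudes of the Zernike moments of
#' order 0-4 on the centroid-centred unit disk (rotation invariant).
#'
#' @param mask a [segmentation_mask()]
#' @return named numeric vector: `hu_1..hu_8`, `affine_1..affine_6`,
#'   `zernike_n_m` for the 9 (n, m) pairs with n <= 4
#' @export
moment_invariants <- function(mask) {
  slice <- largest_axial_slice(mask$labels)
  mu <- central_moments_2d(slice)
  m <- function(p, q) mu[p + 1, q + 1]
  m00 <- m(0, 0)
  eta <- function(p, q) m(p, q) / m00^(1 + (p + q) / 2)
  n20 <- eta(2, 0); n02 <- eta(0, 2); n11 <- eta(1, 1)
  n30 <- eta(3, 0); n03 <- eta(0, 3); n21 <- eta(2, 1); n12 <- eta(1, 2)
  hu <- c(
    n20 + n02,
    (n20 - n02)^2 + 4 * n11^2,
    (n30 - 3 * n12)^2 + (3 * n21 - n03)^2,
    (n30 + n12)^2 + (n21 + n03)^2,
    (n30 - 3 * n12) * (n30 + n12) *
      ((n30 + n12)^2 - 3 * (n21 + n03)^2) +
      (3 * n21 - n03) * (n21 + n03) *
      (3 * (n30 + n12)^2 - (n21 + n03)^2),
    (n20 - n02) * ((n30 + n12)^2 - (n21 + n03)^2) +
      4 * n11 * (n30 + n12) * (n21 + n03),
    (3 * n21 - n03) * (n30 + n12) *
      ((n30 + n12)^2 - 3 * (n21 + n03)^2) -
      (n30 - 3 * n12) * (n21 + n03) *
      (3 * (n30 + n12)^2 - (n21 + n03)^2),
    n11 * ((n30 + n12)^2 - (n03 + n21)^2) -
      (n20 - n02) * (n30 + n12) * (n03 + n21)
  )
  names(hu) <- paste0("hu_", 1:8)
  u <- function(p, q) m(p, q)
  aff <- c(
    (u(2, 0) * u(0, 2) - u(1, 1)^2) / m00^4,
    (-u(3, 0)^2 * u(0, 3)^2 + 6 * u(3, 0) * u(2, 1) * u(1, 2) * u(0, 3) -
       4 * u(3, 0) * u(1, 2)^3 - 4 * u(2, 1)^3 * u(0, 3) +
       3 * u(2, 1)^2 * u(1, 2)^2) / m00^10,
    (u(2, 0) * (u(2, 1) * u(0, 3) - u(1, 2)^2) -
       u(1, 1) * (u(3, 0) * u(0, 3) - u(2, 1) * u(1, 2)) +
       u(0, 2) * (u(3, 0) * u(1, 2) - u(2, 1)^2)) / m00^7,
    (u(2, 0)^3 * u(0, 3)^2 -
       6 * u(2, 0)^2 * u(1, 1) * u(1, 2) * u(0, 3) -
       6 * u(2, 0)^2 * u(0, 2) * u(2, 1) * u(0, 3) +
       9 * u(2, 0)^2 * u(0, 2) * u(1, 2)^2 +
       12 * u(2, 0) * u(1, 1)^2 * u(2, 1) * u(0, 3) +
       6 * u(2, 0) * u(1, 1) * u(0, 2) * u(3, 0) * u(0, 3) -
       18 * u(2, 0) * u(1, 1) * u(0, 2) * u(2, 1) * u(1, 2) -
       8 * u(1, 1)^3 * u(3, 0) * u(0, 3) -
       6 * u(2, 0) * u(0, 2)^2 * u(3, 0) * u(1, 2) +
       9 * u(2, 0) * u(0, 2)^2 * u(2, 1)^2 +
       12 * u(1, 1)^2 * u(0, 2) * u(3, 0) * u(1, 2) -
       6 * u(1, 1) * u(0, 2)^2 * u(3, 0) * u(2, 1) +
       u(0, 2)^3 * u(3, 0)^2) / m00^11,
    (u(4, 0) * u(0, 4) - 4 * u(3, 1) * u(1, 3) + 3 * u(2, 2)^2) / m00^6,
    (u(4, 0) * u(2, 2) * u(0, 4) - u(4, 0) * u(1, 3)^2 -
       u(3, 1)^2 * u(0, 4) + 2 * u(3, 1) * u(2, 2) * u(1, 3) -
       u(2, 2)^3) / m00^9
  )
  names(aff) <- paste0("affine_", 1:6)
  c(hu, aff, zernike_magnitudes(slice))
}

zernike_radial <- function(n, m, r) {
  out <- 0
  for (s in 0:((n - m) / 2)) {
    out <- out + (-1)^s * factorial(n - s) /
      (factorial(s) * factorial((n + m) / 2 - s) *
         factorial((n - m) / 2 - s)) * r^(n - 2 * s)
  }
  out
}

zernike_pairs <- function(max_order = 4) {
  pairs <- list()
  for (n in 0:max_order)
    for (m in seq(n %% 2, n, by = 2))
      pairs[[length(pairs) + 1]] <- c(n, m)
  pairs
}

zernike_magnitudes <- function(slice, max_order = 4) {
  w <- which(slice, arr.ind = TRUE)
  x <- w[, 1] - mean(w[, 1]); y <- w[, 2] - mean(w[, 2])
  rmax <- max(sqrt(x^2 + y^2))
  if (rmax == 0) { x <- x; y <- y; rmax <- 1 }
  r <- sqrt(x^2 + y^2) / rmax
  th <- atan2(y, x)
  out <- numeric(0)
  for (p in zernike_pairs(max_order)) {
    n <- p[1]; m <- p[2]
    rad <- zernike_radial(n, m, r)
    a <- (n + 1) / pi * mean(rad * cos(m * th))
    b <- (n + 1) / pi * mean(rad * sin(m * th))
    out <- c(out, setNames(sqrt(a^2 + b^2), sprintf("zernike_%d_%d", n, m)))
  }
  out
}

#' Skeleton features of the lesion mask
#'
#' The mask is reduced to a curve skeleton by sequential 3-D thinning
#' (simple-point removal with endpoint preservation). Endpoints are skeleton
#' voxels with at most one 26-neighbor, branch points those with three or
#' more; total length is the weight of a minimum spanning forest over the
#' 26-adjacency graph of skeleton voxels (physical distances).
#'
#' @param mask a [segmentation_mask()]
#' @param spacing_mm optional spacing override
#' @return named numeric vector: `skel_n_branch_points`, `skel_n_endpoints`,
#'   `skel_length_mm`, `skel_mean_branch_length_mm`
#' @export
skeleton_features <- function(mask, spacing_mm = mask$spacing_mm) {
  sp <- rep(spacing_mm, length.out = 3)
  zero <- c(skel_n_branch_points = 0, skel_n_endpoints = 0,
            skel_length_mm = 0, skel_mean_branch_length_mm = 0)
  skel <- cpp_skeletonize(mask$labels, as.integer(dim(mask$labels)))
  w <- which(array(skel, dim(mask$labels)), arr.ind = TRUE)
  if (nrow(w) <= 1) return(zero)
  pts <- sweep(w, 2, sp, `*`)
  dmat <- as.matrix(stats::dist(pts))
  adj <- dmat <= sqrt(sum(sp^2)) + 1e-9 & dmat > 0
  deg <- rowSums(adj)
  edges <- which(adj & upper.tri(adj), arr.ind = TRUE)
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges[, 1], to = edges[, 2],
               weight = dmat[edges]),
    directed = FALSE,
    vertices = data.frame(name = seq_len(nrow(w))))
  forest <- igraph::mst(g)
  total_len <- sum(igraph::E(forest)$weight)
  n_branch <- sum(deg >= 3)
  c(skel_n_branch_points = n_branch,
    skel_n_endpoints = sum(deg <= 1),
    skel_length_mm = total_len,
    skel_mean_branch_length_mm = total_len / (n_branch + 1))
}

#' Radial-distance features
#'
#' Distances from the mask centroid to every boundary voxel (physical units):
#' mean, SD, max/min ratio, and the entropy of the 16-bin distance histogram.
#' All four are translation invariant by construction.
#'
#' @param mask a [segmentation_mask()]
#' @param spacing_mm optional spacing override
#' @return named numeric vector of 4 features
#' @export
radial_distance_features <- function(mask, spacing_mm = mask$spacing_mm) {
  sp <- rep(spacing_mm, length.out = 3)
  w <- which(mask$labels, arr.ind = TRUE)
  ctr <- colMeans(sweep(w, 2, sp, `*`))
  bd <- sweep(mask_boundary_voxels(mask$labels), 2, sp, `*`)
  d <- sqrt(rowSums(sweep(bd, 2, ctr, `-`)^2))
  rng <- range(d)
  p <- tabulate(cut(d, breaks = seq(rng[1] - 1e-9, rng[2] + 1e-9,
                                    length.out = 17),
                    labels = FALSE), nbins = 16)
  p <- p / sum(p)
  c(dist_mean_mm = mean(d),
    dist_sd_mm = if (length(d) > 1) sd(d) else 0,
    dist_max_min_ratio = if (rng[1] > 0) rng[2] / rng[1] else 0,
    dist_entropy = shannon_entropy_bits(p))
}
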