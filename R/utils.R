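"%||%" <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ..., class = NULL) {
  msg <- sprintf(fmt, ...)
  cnd <- structure(class = c(class, "radiomix_error", "error", "condition"),
                   list(message = msg, call = sys.call(-1)))
  stop(cnd)
}

gaussian_kernel_1d <- function(sigma, radius = max(1L, ceiling(3 * sigma))) {
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

#' Separable Gaussian smoothing of a 3-D array
#'
#' @param arr numeric 3-D array
#' @param sigma smoothing SD in voxels, scalar or length-3
#' @return smoothed array of the same shape
#' @keywords internal
smooth_gaussian_3d <- function(arr, sigma) {
  sigma <- rep(sigma, length.out = 3)
  d <- dim(arr)
  out <- arr
  for (ax in 0:2) {
    if (sigma[ax + 1] <= 0) next
    out <- cpp_smooth_axis(as.numeric(out), as.integer(d), ax,
                           gaussian_kernel_1d(sigma[ax + 1]))
  }
  array(out, d)
}

# Deterministic per-subject stream seed, extensible in the subject index.
# `stream` separates imaging from omics draws. Kept below 2^31.
subject_stream_seed <- function(seed, index, stream = 0L) {
  as.integer((abs(as.numeric(seed)) %% 65536) * 32749 +
               index * 251 + stream * 17 + 1) %% 2147483629L
}

shannon_entropy_bits <- function(p) {
  p <- p[p > 0]
  if (length(p) == 0) return(0)
  -sum(p * log2(p))
}

# md5 of an R object via its serialization (used for config/registry hashes;
# version fixed so hashes are stable across sessions)
object_md5 <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(x, con, version = 2)
  close(con)
  unname(tools::md5sum(f))
}
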