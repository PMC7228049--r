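# Internal helpers: typed conditions and small numerics shared across modules.

stop_dwim <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "dwimarkers_error"), call = call))
}

stop_validation <- function(msg) stop_dwim(msg, "dwimarkers_validation_error")
stop_io <- function(msg) stop_dwim(msg, "dwimarkers_io_error")

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_validation(sprintf("'%s' must be a single finite number", name))
  if (positive && x <= 0)
    stop_validation(sprintf("'%s' must be positive", name))
  invisible(x)
}

gaussian_kernel_1d <- function(fwhm_vox) {
  sigma <- fwhm_vox / (2 * sqrt(2 * log(2)))
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  w <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  w / sum(w)
}

smooth_along_first <- function(m, w) {
  r <- (length(w) - 1L) %/% 2L
  n <- nrow(m)
  acc <- matrix(0, n, ncol(m))
  nrm <- numeric(n)
  for (j in seq(-r, r)) {
    wi <- w[j + r + 1L]
    lo <- max(1L, 1L - j); hi <- min(n, n - j)
    if (lo > hi) next
    i_out <- seq.int(lo, hi)
    acc[i_out, ] <- acc[i_out, ] + wi * m[i_out + j, , drop = FALSE]
    nrm[i_out] <- nrm[i_out] + wi
  }
  acc / nrm
}

#' Separable 3-D Gaussian smoothing
#'
#' Isotropic Gaussian filter applied axis by axis, with the kernel
#' renormalised over the in-bounds support at array edges (no padding bias).
#' Used by the voxel-stability filter before temporal statistics are taken.
#'
#' @param arr 3-D numeric array.
#' @param fwhm_vox kernel full width at half maximum, in voxels. `0` disables
#'   smoothing and returns `arr` unchanged.
#' @return array of the same dimensions.
#' @export
gaussian_smooth_3d <- function(arr, fwhm_vox) {
  if (length(dim(arr)) != 3L) stop_validation("gaussian_smooth_3d expects a 3-D array")
  if (fwhm_vox < 0) stop_validation("'fwhm_vox' must be non-negative")
  if (fwhm_vox == 0) return(arr)
  w <- gaussian_kernel_1d(fwhm_vox)
  d <- dim(arr)
  arr <- array(smooth_along_first(matrix(arr, d[1], d[2] * d[3]), w), d)
  a2 <- aperm(arr, c(2, 1, 3))
  a2 <- array(smooth_along_first(matrix(a2, d[2], d[1] * d[3]), w), c(d[2], d[1], d[3]))
  arr <- aperm(a2, c(2, 1, 3))
  a3 <- aperm(arr, c(3, 1, 2))
  a3 <- array(smooth_along_first(matrix(a3, d[3], d[1] * d[2]), w), c(d[3], d[1], d[2]))
  aperm(a3, c(2, 3, 1))
}

# Deterministic sub-seed derivation; keeps results in 32-bit integer range.
derive_seed <- function(master_seed, index) {
  as.integer((as.double(master_seed) + 104729 * as.double(index)) %% 2147483647)
}

# Welch two-sample p-value with explicit degenerate handling: zero variance
# in both samples yields p = 1 when the means agree (no evidence of a
# difference) and NA otherwise (not computable).
welch_p <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2L || length(y) < 2L) return(NA_real_)
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else NA_real_)
  }
  stats::t.test(x, y, var.equal = FALSE)$p.value
}

# Paired two-sided p-value with the same degenerate conventions.
paired_p <- function(pre, post) {
  ok <- is.finite(pre) & is.finite(post)
  pre <- pre[ok]; post <- post[ok]
  if (length(pre) < 2L) return(NA_real_)
  d <- post - pre
  if (stats::sd(d) == 0) return(if (all(d == 0)) 1 else NA_real_)
  stats::t.test(post, pre, paired = TRUE)$p.value
}
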