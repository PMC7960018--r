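#' Volume quality metrics: RMSE and (M)SSIM
#'
#' `rmse()` is the root mean squared voxel difference.  `ssim_window()`
#' evaluates the structural similarity index on a pair of windows with the
#' standard stabilizers `c1 = (k1 L)^2`, `c2 = (k2 L)^2` (`k1 = 0.01`,
#' `k2 = 0.03`, `L` the dynamic range).  `mssim()` averages SSIM over all
#' fully-contained cubic windows at stride 1.
#'
#' @param z reconstructed volume (3D array or [recon_volume()]).
#' @param g ground-truth volume, same shape.
#' @return `rmse` returns a non-negative scalar.
#' @examples
#' rmse(array(0, c(2, 1, 1)), array(c(3, 4), c(2, 1, 1)))  # sqrt(12.5)
#' @export
rmse <- function(z, g) {
  z <- as_voxels(z); g <- as_voxels(g)
  if (!identical(dim(z), dim(g))) stop("volume shapes differ")
  sqrt(mean((z - g)^2))
}

as_voxels <- function(x) if (inherits(x, "recon_volume")) x$voxels else x

#' @rdname rmse
#' @param z_win,g_win equally shaped windows (any dimension).
#' @param L dynamic range of the reference.
#' @param k1,k2 SSIM stabilizer constants.
#' @export
ssim_window <- function(z_win, g_win, L, k1 = 0.01, k2 = 0.03) {
  if (!identical(dim(z_win), dim(g_win)) ||
      length(z_win) != length(g_win)) stop("window shapes differ")
  c1 <- (k1 * L)^2; c2 <- (k2 * L)^2
  n <- length(z_win)
  mz <- mean(z_win); mg <- mean(g_win)
  vz <- mean(z_win^2) - mz^2; vg <- mean(g_win^2) - mg^2
  cv <- mean(z_win * g_win) - mz * mg
  ((2 * mz * mg + c1) * (2 * cv + c2)) /
    ((mz^2 + mg^2 + c1) * (vz + vg + c2))
}

#' @rdname rmse
#' @param window cubic window side (voxels).
#' @return `mssim` returns the mean SSIM with attributes `M` (number of
#'   windows) and `window`.
#' @export
mssim <- function(z, g, window = 7, L = NULL) {
  z <- as_voxels(z); g <- as_voxels(g)
  if (!identical(dim(z), dim(g))) stop("volume shapes differ")
  if (any(window > dim(z))) stop("window larger than volume")
  if (is.null(L)) L <- diff(range(g))
  out <- cpp_mssim(z, g, as.integer(window), L, 0.01, 0.03)
  structure(out$mssim, M = out$M, window = window)
}

#' Relative RMSE improvement, in percent
#'
#' `100 * (before - after) / before`: the headline quality-improvement
#' number when an ablation's RMSE drops to the full method's.
#'
#' @param before,after RMSE values (before > 0).
#' @return Percent improvement.
#' @examples
#' rmse_improvement(126.47, 78.89)  # 37.62
#' @export
rmse_improvement <- function(before, after) {
  stopifnot(before > 0)
  100 * (before - after) / before
}

#' Full metric report for a reconstruction
#'
#' @param recon,truth volumes of identical shape.
#' @param window SSIM window size.
#' @return A data.frame with `rmse`, `mssim`, `n_windows`, `window_size`,
#'   `dynamic_range`.
#' @export
metric_report <- function(recon, truth, window = 7) {
  ms <- mssim(recon, truth, window = window)
  data.frame(rmse = rmse(recon, truth), mssim = as.numeric(ms),
             n_windows = attr(ms, "M"), window_size = window,
             dynamic_range = diff(range(as_voxels(truth))))
}
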