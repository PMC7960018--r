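#' Stack data matrix for low-rank motion assessment
#'
#' Stacks the vectorized slices of one stack as columns of an `m x k` matrix
#' (column-major vec; invalid pixels enter as 0 so the matrix shape is fixed
#' across removal ratios).
#'
#' @param stack a [svr_stack()]; all slices must share one shape.
#' @param corrected apply [correct_slice()] first (default FALSE: raw
#'   intensities, as used before bias/scale are known).
#' @return Numeric matrix with one column per slice.
#' @export
build_data_matrix <- function(stack, corrected = FALSE) {
  sl <- stack$slices
  shp <- dim(sl[[1]]$pixels)
  if (!all(vapply(sl, function(s) identical(dim(s$pixels), shp), logical(1))))
    stop("all slices must have the same shape")
  vapply(sl, function(s) {
    if (corrected) s <- correct_slice(s)
    p <- s$pixels
    p[!s$valid_mask] <- 0
    as.numeric(p)                      # column-major vec
  }, numeric(prod(shp)))
}

#' Relative error of the best rank-r approximation
#'
#' `delta_r = ||D - D_r|| / ||D||` in the Frobenius norm, where `D_r` keeps
#' the first `r` singular values: `sqrt(sum_{i>r} s_i^2) / sqrt(sum s_i^2)`.
#'
#' @param D numeric matrix with `||D|| > 0`.
#' @param r target rank, `1 <= r <= ncol(D)`.
#' @return `delta_r` in [0, 1].
#' @export
rank_error <- function(D, r) {
  k <- min(dim(D))
  stopifnot(r >= 1, r <= ncol(D))
  s <- svd(D, nu = 0, nv = 0)$d
  tot <- sum(s^2)
  if (tot <= 0) stop("rank_error undefined for the zero matrix")
  if (r >= k) return(0)
  sqrt(sum(s[(r + 1):k]^2) / tot)
}

#' Low-rank surrogate for the amount of stack motion
#'
#' Computes `delta_r` for r = 1..k, the minimal rank `r*` with
#' `delta_r < beta` (k when none qualifies), and the motion surrogate
#' `mu = delta_{r*} * r*`.  Stacks with little motion are nearly low-rank,
#' so small `mu` indicates a good registration template.
#'
#' @param D data matrix from [build_data_matrix()].
#' @param beta relative-error threshold in (0, 1].
#' @return A list of class `motion_report`: `delta`, `r_star`, `mu`, `beta`.
#' @export
motion_surrogate <- function(D, beta = 0.1) {
  stopifnot(beta > 0, beta <= 1)
  k <- ncol(D)
  s <- svd(D, nu = 0, nv = 0)$d
  s <- c(s, rep(0, max(0, k - length(s))))
  tot <- sum(s^2)
  if (tot <= 0) stop("motion surrogate undefined for the zero matrix")
  tails <- rev(sqrt(pmax(cumsum(rev(c(s[-1]^2, 0))), 0) / tot))
  delta <- tails[seq_len(k)]
  r_star <- which(delta < beta)[1]
  if (is.na(r_star)) r_star <- k
  structure(list(delta = delta, r_star = r_star,
                 mu = delta[r_star] * r_star, beta = beta),
            class = "motion_report")
}

#' @export
print.motion_report <- function(x, ...) {
  cat(sprintf("<motion_report> r* = %d, mu = %.4g (beta = %g)\n",
              x$r_star, x$mu, x$beta))
  invisible(x)
}

#' Select the least-motion stack as registration template
#'
#' Scores each stack with [motion_surrogate()] and returns the index of the
#' stack with minimal `mu` (ties broken by lowest index).
#'
#' @param stacks list of [svr_stack()].
#' @param beta threshold passed to [motion_surrogate()].
#' @param corrected passed to [build_data_matrix()].
#' @return Integer stack index (1-based), with attribute `reports`.
#' @export
select_template <- function(stacks, beta = 0.1, corrected = FALSE) {
  if (length(stacks) == 0) stop("need at least one stack")
  reports <- lapply(stacks, function(st)
    motion_surrogate(build_data_matrix(st, corrected = corrected), beta))
  mu <- vapply(reports, `[[`, numeric(1), "mu")
  idx <- which.min(mu)                  # which.min takes the first minimum
  attr(idx, "reports") <- reports
  idx
}

#' Per-stack motion assessment table
#'
#' @param stacks list of [svr_stack()].
#' @param beta threshold in (0, 1].
#' @return A data.frame with one row per stack: `stack`, `orientation`,
#'   `r_star`, `mu`, `beta`.
#' @export
assess_stacks <- function(stacks, beta = 0.1) {
  reports <- lapply(stacks, function(st)
    motion_surrogate(build_data_matrix(st), beta))
  data.frame(stack = seq_along(stacks),
             orientation = vapply(stacks, `[[`, character(1),
                                  "orientation_tag"),
             r_star = vapply(reports, `[[`, numeric(1), "r_star"),
             mu = vapply(reports, `[[`, numeric(1), "mu"),
             beta = beta)
}
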