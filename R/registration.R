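#' Registration settings
#'
#' Controls of the derivative-free rigid optimizer: a Powell-style
#' coordinate descent over the 6 rigid parameters with step halving and
#' optional restarts, run coarse-to-fine over a Gaussian-pyramid schedule
#' for volume-to-volume registration.
#'
#' @param rot_step,trans_step initial search steps (radians, mm).
#' @param rot_min,trans_min terminal step sizes (radians, mm).
#' @param rot_limit,trans_limit trust region half-widths around the initial
#'   pose (radians, mm); rigid slice/stack motion is physiologically bounded
#'   and the NCC landscape has spurious distant minima.
#' @param max_sweeps coordinate-descent sweep cap per level.
#' @param restarts extra descent passes restarted from the current optimum.
#' @param pyramid_levels pyramid depth for volume-to-volume registration.
#' @return A list of class `reg_settings`.
#' @export
reg_settings <- function(rot_step = 2 * pi / 180, trans_step = 1,
                         rot_min = 2.5e-4, trans_min = 0.01,
                         rot_limit = 15 * pi / 180, trans_limit = 10,
                         max_sweeps = 60, restarts = 1,
                         pyramid_levels = 3, min_gain = 0.01) {
  structure(list(rot_step = rot_step, trans_step = trans_step,
                 rot_min = rot_min, trans_min = trans_min,
                 rot_limit = rot_limit, trans_limit = trans_limit,
                 max_sweeps = max_sweeps, restarts = restarts,
                 pyramid_levels = pyramid_levels, min_gain = min_gain),
            class = "reg_settings")
}

# Coordinate descent with step halving inside a box trust region; the
# translations (parameters 4:6) are swept before the rotations, which are
# better conditioned that way.  Only improvements are accepted, so the final
# value never exceeds the initial one.  Returns par, value, n_evals.
coord_descent <- function(f, par, step, min_step, lower, upper,
                          max_sweeps, restarts) {
  n_evals <- 0L
  eval_f <- function(p) { n_evals <<- n_evals + 1L; f(p) }
  best <- eval_f(par)
  order <- c(4:6, 1:3)
  run <- function(par, best, step) {
    for (sweep in seq_len(max_sweeps)) {
      moved <- FALSE
      for (i in order) {
        for (dir in c(1, -1)) {
          cand <- par
          cand[i] <- min(max(cand[i] + dir * step[i], lower[i]), upper[i])
          if (cand[i] == par[i]) next
          v <- eval_f(cand)
          improved <- FALSE
          while (v < best - 1e-14) {
            par <- cand; best <- v; moved <- TRUE; improved <- TRUE
            nxt <- min(max(cand[i] + dir * step[i], lower[i]), upper[i])
            if (nxt == cand[i]) break
            cand[i] <- nxt
            v <- eval_f(cand)
          }
          if (improved && dir == 1) break   # keep direction that worked
        }
      }
      if (!moved) {
        if (all(step <= min_step)) break
        step <- pmax(step / 2, min_step)
      }
    }
    list(par = par, value = best)
  }
  out <- run(par, best, step)
  for (r in seq_len(restarts)) {
    out2 <- run(out$par, out$value, step)
    if (out2$value < out$value) out <- out2
  }
  list(par = out$par, value = out$value, n_evals = n_evals)
}

# rigid transform from 6 parameters applied about a center point
params_to_transform <- function(par, center) {
  transform_about(rigid_transform(par[1:3], par[4:6]), center)
}

# 2x mean-pooled pyramid level (trims odd trailing voxels)
downsample_volume <- function(vol) {
  d <- dim(vol$voxels)
  d2 <- pmax(d %/% 2, 1)
  v <- vol$voxels[seq_len(d2[1] * 2), seq_len(d2[2] * 2),
                  seq_len(d2[3] * 2), drop = FALSE]
  pool <- function(a) {
    a <- (a[seq(1, dim(a)[1], 2), , , drop = FALSE] +
          a[seq(2, dim(a)[1], 2), , , drop = FALSE]) / 2
    a <- (a[, seq(1, dim(a)[2], 2), , drop = FALSE] +
          a[, seq(2, dim(a)[2], 2), , drop = FALSE]) / 2
    (a[, , seq(1, dim(a)[3], 2), drop = FALSE] +
     a[, , seq(2, dim(a)[3], 2), drop = FALSE]) / 2
  }
  shift <- diag(4); shift[1:3, 1:3] <- 2 * diag(3); shift[1:3, 4] <- 0.5
  sp <- if (length(vol$spacing) == 1) rep(vol$spacing, 3) else vol$spacing
  recon_volume(pool(v), spacing = sp * 2, world = vol$world %*% shift,
               weights = pool(vol$weights[seq_len(d2[1] * 2),
                                          seq_len(d2[2] * 2),
                                          seq_len(d2[3] * 2), drop = FALSE]))
}

#' Rigid volume-to-volume registration
#'
#' Minimizes the normalized-cross-correlation dissimilarity `1 - NCC` over
#' the 6 rigid parameters, coarse to fine over a Gaussian pyramid, with a
#' derivative-free coordinate-descent optimizer.  The returned transform
#' maps moving-volume world coordinates into fixed-volume world coordinates;
#' out-of-field samples are excluded from the metric.
#'
#' @param moving,fixed [recon_volume()]s with overlapping fields of view.
#' @param init initial [rigid_transform()] (default identity).
#' @param settings a [reg_settings()].
#' @return A list of class `registration_result`: `transform`,
#'   `final_metric`, `initial_metric`, `converged`, `n_evals`.
#' @export
register_volume_to_volume <- function(moving, fixed, init = rigid_identity(),
                                      settings = reg_settings()) {
  pyr_f <- list(fixed); pyr_m <- list(moving)
  for (l in seq_len(settings$pyramid_levels - 1)) {
    if (any(dim(pyr_f[[l]]$voxels) < 16) || any(dim(pyr_m[[l]]$voxels) < 16))
      break
    pyr_f[[l + 1]] <- downsample_volume(pyr_f[[l]])
    pyr_m[[l + 1]] <- downsample_volume(pyr_m[[l]])
  }
  d <- dim(fixed$voxels)
  center <- as.numeric(fixed$world %*% c((d - 1) / 2, 1))[1:3]
  metric_at <- function(fx, mv, par) {
    Tm <- params_to_transform(par, center)$matrix %*% init$matrix
    B <- solve(mv$world, solve(Tm, fx$world))
    r <- cpp_ncc_volume(fx$voxels, mv$voxels, B)
    list(value = 1 - r$ncc, overlap = r$n / r$n_total)
  }
  par <- rep(0, 6)
  n_evals <- 0L
  for (l in rev(seq_along(pyr_f))) {
    fx <- pyr_f[[l]]; mv <- pyr_m[[l]]
    scale <- 2^(l - 1)
    step <- c(rep(settings$rot_step, 3), rep(settings$trans_step * scale, 3))
    min_step <- c(rep(settings$rot_min * scale, 3),
                  rep(settings$trans_min * scale, 3))
    bound <- c(rep(settings$rot_limit, 3), rep(settings$trans_limit, 3))
    opt <- coord_descent(function(p) metric_at(fx, mv, p)$value,
                         par, step, min_step, -bound, bound,
                         settings$max_sweeps,
                         if (l == 1) settings$restarts else 0)
    par <- opt$par
    n_evals <- n_evals + opt$n_evals
  }
  fin <- metric_at(pyr_f[[1]], pyr_m[[1]], par)
  init_metric <- metric_at(pyr_f[[1]], pyr_m[[1]], rep(0, 6))$value
  converged <- fin$overlap >= 0.1
  if (!converged)
    warning("less than 10% overlap at the registration solution")
  structure(list(transform = rigid_from_matrix(
                   params_to_transform(par, center)$matrix %*% init$matrix),
                 final_metric = fin$value, initial_metric = init_metric,
                 converged = converged, n_evals = n_evals),
            class = "registration_result")
}

#' Rigid slice-to-volume registration
#'
#' Refines the local (slice motion) transform by minimizing `1 - NCC`
#' between the observed valid pixels and the slice simulated from the
#' volume at the candidate pose through the PSF.
#'
#' @param slice an observed [svr_slice()].
#' @param volume a gathered [recon_volume()].
#' @param t_global stack-level [rigid_transform()].
#' @param init initial local transform.
#' @param spec a [psf_spec()].
#' @param settings a [reg_settings()].
#' @return A `registration_result` whose `transform` is the refined local
#'   transform.  Slices with fewer than 32 valid pixels are skipped
#'   (`converged = FALSE`, transform unchanged).
#' @export
register_slice_to_volume <- function(slice, volume, t_global = rigid_identity(),
                                     init = rigid_identity(),
                                     spec, settings = reg_settings()) {
  corr <- correct_slice(slice)
  corr$valid_mask <- corr$valid_mask & is.finite(corr$pixels)
  corr$pixels[!is.finite(corr$pixels)] <- 0
  # metric pixel budget: NCC converges with ~1000 samples, so dense slices
  # are thinned on a regular lattice for the pose search (the slice data
  # scattered into the volume is never thinned)
  nv <- sum(corr$valid_mask)
  if (nv > 1200) {
    stride <- ceiling(sqrt(nv / 1200))
    keep <- matrix(FALSE, nrow(corr$pixels), ncol(corr$pixels))
    keep[seq(1, nrow(keep), by = stride), seq(1, ncol(keep), by = stride)] <- TRUE
    corr$valid_mask <- corr$valid_mask & keep
  }
  skip <- structure(list(transform = init, final_metric = NA_real_,
                         initial_metric = NA_real_, converged = FALSE,
                         n_evals = 0L),
                    class = "registration_result")
  if (sum(corr$valid_mask) < 32) return(skip)
  km <- known_mask(volume)
  # low-structure guard: NCC is meaningless on nearly empty slices and the
  # optimizer would chase noise correlations, so keep their current pose
  vol_range <- diff(range(volume$voxels[km > 0]))
  if (sd(corr$pixels[corr$valid_mask]) < 0.08 * vol_range) return(skip)
  ctr_idx <- c((nrow(corr$pixels) - 1) / 2, (ncol(corr$pixels) - 1) / 2, 0, 1)
  center <- as.numeric(init$matrix %*% corr$world %*% ctr_idx)[1:3]
  metric_at <- function(par, sg) {
    tl <- rigid_from_matrix(params_to_transform(par, center)$matrix %*%
                              init$matrix)
    mp <- slice_maps(corr, t_global, tl, volume)
    r <- cpp_ncc_slice(volume$voxels, km, corr$pixels, corr$valid_mask,
                       mp$A, mp$M, sg, spec$support_radius)
    if (r$n < 16) return(2)            # essentially no overlap
    1 - r$ncc
  }
  bound <- c(rep(settings$rot_limit, 3), rep(settings$trans_limit, 3))
  step <- c(rep(settings$rot_step, 3), rep(settings$trans_step, 3))
  min_step <- c(rep(settings$rot_min, 3), rep(settings$trans_min, 3))
  init_val <- metric_at(rep(0, 6), spec$sigma)
  # a pose update is only accepted when it gains at least min_gain, so a
  # slice already this well aligned cannot move: return immediately
  if (init_val < settings$min_gain) {
    return(structure(list(transform = init, final_metric = init_val,
                          initial_metric = init_val, converged = TRUE,
                          n_evals = 1L),
                     class = "registration_result"))
  }
  # coarse-to-fine in PSF width for badly aligned slices: a widened kernel
  # smooths the objective and enlarges the capture range; the true kernel
  # then refines the pose
  par0 <- rep(0, 6)
  n_coarse <- 0L
  if (init_val > 0.05) {
    opt1 <- coord_descent(function(p) metric_at(p, 2.5 * spec$sigma),
                          rep(0, 6), step, pmax(min_step, step / 8),
                          -bound, bound, settings$max_sweeps, 0)
    par0 <- opt1$par
    n_coarse <- opt1$n_evals
  }
  opt <- coord_descent(function(p) metric_at(p, spec$sigma),
                       par0, step, min_step, -bound, bound,
                       settings$max_sweeps, settings$restarts)
  if (opt$value > init_val) {          # smoothed stage led astray: redo
    opt2 <- coord_descent(function(p) metric_at(p, spec$sigma),
                          rep(0, 6), step, min_step, -bound, bound,
                          settings$max_sweeps, settings$restarts)
    opt2$n_evals <- opt2$n_evals + opt$n_evals
    if (opt2$value < opt$value) opt <- opt2
  }
  opt$n_evals <- opt$n_evals + n_coarse
  # overlap retention: a pose that slides a meaningful part of the slice out
  # of the reconstructed field is rejected in favor of the initial pose
  n_at <- function(par) {
    tl <- rigid_from_matrix(params_to_transform(par, center)$matrix %*%
                              init$matrix)
    mp <- slice_maps(corr, t_global, tl, volume)
    cpp_ncc_slice(volume$voxels, km, corr$pixels, corr$valid_mask,
                  mp$A, mp$M, spec$sigma, spec$support_radius)$n
  }
  if (n_at(opt$par) < 0.85 * n_at(rep(0, 6))) {
    skip$final_metric <- init_val
    skip$initial_metric <- init_val
    skip$n_evals <- opt$n_evals
    return(skip)
  }
  # pose-update damping: marginal NCC gains are discretization noise on an
  # imperfect consensus and would accumulate into a pose random walk over
  # the outer iterations, so they do not move the slice
  if (init_val - opt$value < settings$min_gain) {
    return(structure(list(transform = init, final_metric = init_val,
                          initial_metric = init_val, converged = TRUE,
                          n_evals = opt$n_evals),
                     class = "registration_result"))
  }
  structure(list(transform = rigid_from_matrix(
                   params_to_transform(opt$par, center)$matrix %*%
                     init$matrix),
                 final_metric = opt$value,
                 initial_metric = init_val,
                 converged = TRUE, n_evals = opt$n_evals),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("<registration_result> metric %.5f -> %.5f, %d evals, %s\n",
              x$initial_metric, x$final_metric, x$n_evals,
              if (isTRUE(x$converged)) "converged" else "not converged"))
  invisible(x)
}
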