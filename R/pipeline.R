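#' Pipeline configuration
#'
#' Settings of the full reconstruction: motion assessment threshold,
#' number of outer iterations (each runs PSF volume update, robust outlier
#' removal, steering kernel regression, residual-based combined update, and
#' slice-to-volume registration), the reconstruction grid spacing, nested
#' kernel-regression and registration settings, and the EM slice-exclusion
#' threshold.
#'
#' @param beta motion-assessment rank threshold in (0, 1].
#' @param outer_iterations outer loop count (>= 1).
#' @param recon_spacing isotropic reconstruction voxel size (mm); default:
#'   the template stack's in-plane spacing.
#' @param kr a [kr_config()].
#' @param em_threshold slice-exclusion probability threshold.
#' @param registration a [reg_settings()] (pipeline default trades a little
#'   optimizer polish for speed: no restart passes, 0.02 mm terminal step).
#' @param global_registration,slice_registration enable the stack-to-template
#'   and slice-to-volume stages.
#' @param use_steering enable the steering kernel regression update (turned
#'   off for the PSF-only ablation).
#' @param seed integer seed for any stochastic component.
#' @param verbose print per-iteration progress.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(beta = 0.1, outer_iterations = 3,
                            recon_spacing = NULL, kr = kr_config(),
                            em_threshold = 0.5,
                            registration = reg_settings(restarts = 0,
                                                        max_sweeps = 25,
                                                        trans_min = 0.05,
                                                        rot_min = 1e-3),
                            global_registration = TRUE,
                            slice_registration = TRUE,
                            use_steering = TRUE,
                            seed = 1L, verbose = FALSE) {
  stopifnot(outer_iterations >= 1)
  structure(list(beta = beta, outer_iterations = outer_iterations,
                 recon_spacing = recon_spacing, kr = kr,
                 em_threshold = em_threshold, registration = registration,
                 global_registration = global_registration,
                 slice_registration = slice_registration,
                 use_steering = use_steering, seed = as.integer(seed),
                 verbose = verbose),
            class = "pipeline_config")
}

# axis-aligned reconstruction grid covering a stack's world-space corners
recon_grid_for <- function(stack, spacing) {
  sl <- stack$slices
  n <- nrow(sl[[1]]$pixels); h <- ncol(sl[[1]]$pixels)
  corners <- NULL
  for (s in c(1, length(sl))) {
    W <- sl[[s]]$world
    for (i in c(0, n - 1)) for (j in c(0, h - 1))
      corners <- rbind(corners, as.numeric(W %*% c(i, j, 0, 1))[1:3])
  }
  lo <- apply(corners, 2, min); hi <- apply(corners, 2, max)
  d <- pmax(floor((hi - lo) / spacing) + 1, 8)
  world <- diag(c(rep(spacing, 3), 1))
  world[1:3, 4] <- lo
  recon_volume(array(0, d), spacing = spacing, world = world)
}

#' Full sparse slice-to-volume reconstruction
#'
#' Runs the complete algorithm: (1) low-rank motion assessment selects the
#' least-motion stack as template; (2) every other stack is rigidly
#' registered to it (global transforms); (3) the outer loop interleaves the
#' Gaussian-PSF volume update over included slices, EM robust outlier
#' classification of the slice residuals, the steering kernel regression
#' volume update, a residual-based robust correction (with simulated slices
#' refreshed after the steering update), and rigid slice-to-volume
#' registration refining each slice's local transform.
#'
#' @param stacks list of [svr_stack()]s (masks carried on the slices).
#' @param cfg a [pipeline_config()].
#' @return A list of class `svr_result`: `volume` (the reconstruction),
#'   `manifest` (per-iteration summaries and settings hash), `template`,
#'   `t_globals` (per stack), `t_locals` and `include` (per slice),
#'   `slice_stack` (stack id per slice).
#' @export
reconstruct <- function(stacks, cfg = pipeline_config()) {
  stopifnot(length(stacks) >= 1)
  t0 <- proc.time()[["elapsed"]]
  tmpl <- as.integer(select_template(stacks, beta = cfg$beta))
  tmpl_stack <- stacks[[tmpl]]
  spacing <- if (is.null(cfg$recon_spacing)) tmpl_stack$slices[[1]]$spacing
             else cfg$recon_spacing
  spec <- psf_spec(in_plane_fwhm = tmpl_stack$slices[[1]]$spacing,
                   through_plane_fwhm = tmpl_stack$slices[[1]]$thickness)
  grid <- recon_grid_for(tmpl_stack, spacing)

  t_globals <- vector("list", length(stacks))
  tmpl_vol <- stack_to_volume(tmpl_stack)
  for (s in seq_along(stacks)) {
    if (s == tmpl || !cfg$global_registration) {
      t_globals[[s]] <- rigid_identity()
    } else {
      rr <- register_volume_to_volume(stack_to_volume(stacks[[s]]), tmpl_vol,
                                      settings = cfg$registration)
      t_globals[[s]] <- rr$transform
      if (cfg$verbose)
        message(sprintf("stack %d -> template: metric %.4f (%d evals)",
                        s, rr$final_metric, rr$n_evals))
    }
  }

  slices <- list(); slice_tg <- list(); slice_stack <- integer(0)
  for (s in seq_along(stacks)) for (k in seq_along(stacks[[s]]$slices)) {
    slices[[length(slices) + 1]] <- stacks[[s]]$slices[[k]]
    slice_tg[[length(slice_tg) + 1]] <- t_globals[[s]]
    slice_stack <- c(slice_stack, s)
  }
  n_slices <- length(slices)
  t_locals <- replicate(n_slices, rigid_identity(), simplify = FALSE)
  include <- rep(TRUE, n_slices)
  em <- NULL
  iterations <- list()
  prev_vox <- NULL
  grow_streak <- 0L
  prev_change <- NULL
  vol <- grid

  for (it in seq_len(cfg$outer_iterations)) {
    # PSF-based volume update over included slices
    acc <- recon_volume(array(0, dim(grid$voxels)), grid$spacing, grid$world)
    acc <- scatter_slices(slices[include], slice_tg[include],
                          t_locals[include], acc, spec)
    vol_psf <- gather_volume(acc)

    # robust statistics on the residuals of all slices
    sims <- simulate_slices(vol_psf, slices, slice_tg, t_locals, spec)
    pooled <- unlist(lapply(sims$residuals, function(r) r[is.finite(r)]))
    em <- fit_em(pooled, init = em)
    post <- lapply(sims$residuals, function(r) {
      p <- r; fin <- is.finite(r)
      p[fin] <- e_step(r[fin], em$sigma, em$c, em$uniform_density)
      p
    })
    slice_probs <- vapply(post, function(p)
      slice_probability(p[is.finite(p)]), numeric(1))
    include <- tryCatch(
      exclude_outlier_slices(slice_probs, cfg$em_threshold),
      error = function(e)
        stop(sprintf("iteration %d: %s", it, conditionMessage(e))))

    # steering kernel regression volume update
    vol <- if (cfg$use_steering) steering_update_volume(vol_psf, cfg$kr)
           else vol_psf

    # slice-to-volume registration against the steered consensus (the
    # combined residual update below would re-anchor each slice at its
    # current pose, so poses are refined first)
    reg_evals <- 0L
    if (cfg$slice_registration) {
      for (j in seq_len(n_slices)) {
        rr <- register_slice_to_volume(slices[[j]], vol, slice_tg[[j]],
                                       init = t_locals[[j]], spec = spec,
                                       settings = cfg$registration)
        if (isTRUE(rr$converged)) t_locals[[j]] <- rr$transform
        reg_evals <- reg_evals + rr$n_evals
      }
    }

    # refresh residuals at the refined poses, then combined robust update
    sims2 <- simulate_slices(vol, slices, slice_tg, t_locals, spec)
    post2 <- lapply(sims2$residuals, function(r) {
      p <- r; fin <- is.finite(r)
      p[fin] <- e_step(r[fin], em$sigma, em$c, em$uniform_density)
      p
    })
    vol <- combined_update(vol, slices, slice_tg, t_locals, sims2$residuals,
                           post2, slice_probs, include, spec)

    change <- if (is.null(prev_vox)) NA_real_ else rmse(vol$voxels, prev_vox)
    if (!is.na(change) && !is.null(prev_change) && change > prev_change) {
      grow_streak <- grow_streak + 1L
      if (grow_streak >= 3L)
        stop(sprintf("iteration %d: reconstruction diverging (change grew 3 times in a row)", it))
    } else grow_streak <- 0L
    prev_change <- if (!is.na(change)) change else prev_change
    prev_vox <- vol$voxels

    iterations[[it]] <- list(
      iteration = it, sigma = em$sigma, c = em$c,
      n_excluded = sum(!include),
      excluded = which(!include),
      mean_abs_residual = mean(abs(pooled)),
      change_rmse = change, registration_evals = reg_evals,
      elapsed_s = proc.time()[["elapsed"]] - t0)
    if (cfg$verbose)
      message(sprintf(
        "iter %d: sigma=%.3f c=%.3f excluded=%d mean|e*|=%.3f",
        it, em$sigma, em$c, sum(!include), mean(abs(pooled))))
  }

  cfg_file <- tempfile()
  saveRDS(cfg[setdiff(names(cfg), "verbose")], cfg_file)
  manifest <- list(template = tmpl,
                   config_hash = unname(tools::md5sum(cfg_file)),
                   n_slices = n_slices,
                   iterations = iterations,
                   total_elapsed_s = proc.time()[["elapsed"]] - t0)
  unlink(cfg_file)
  structure(list(volume = vol, manifest = manifest, template = tmpl,
                 t_globals = t_globals, t_locals = t_locals,
                 include = include, slice_stack = slice_stack),
            class = "svr_result")
}

#' @export
print.svr_result <- function(x, ...) {
  cat(sprintf("<svr_result> template stack %d, %d slices (%d excluded), %s grid\n",
              x$template, x$manifest$n_slices,
              sum(!x$include), paste(dim(x$volume$voxels), collapse = "x")))
  invisible(x)
}

#' Resample a volume onto another volume's grid
#'
#' Trilinear resampling through the two world affines; points outside the
#' source grid become `fill`.
#'
#' @param src source [recon_volume()].
#' @param target [recon_volume()] defining the output grid.
#' @param fill value for out-of-field voxels.
#' @return A [recon_volume()] on the target grid.
#' @export
resample_volume <- function(src, target, fill = 0) {
  d <- dim(target$voxels)
  P <- solve(src$world, target$world)
  idx <- as.matrix(expand.grid(x = 0:(d[1] - 1), y = 0:(d[2] - 1),
                               z = 0:(d[3] - 1)))
  pts <- cbind(idx, 1) %*% t(P)
  v <- cpp_trilinear(src$voxels, pts[, 1:3, drop = FALSE])
  v[is.na(v)] <- fill
  recon_volume(array(v, d), target$spacing, target$world,
               weights = array(1, d))
}

#' Evaluate a reconstruction against ground truth
#'
#' Resamples the ground truth onto the reconstruction grid and reports RMSE
#' and MSSIM.
#'
#' @param recon reconstructed [recon_volume()] (or an `svr_result`).
#' @param truth ground-truth [recon_volume()].
#' @param window SSIM window size.
#' @return A one-row data.frame (see [metric_report()]).
#' @export
evaluate_reconstruction <- function(recon, truth, window = 7) {
  if (inherits(recon, "svr_result")) recon <- recon$volume
  g <- resample_volume(truth, recon)
  metric_report(recon, g, window = window)
}

#' Parameter ablation over the steering configuration
#'
#' Reconstructs one fixed scenario once per grid point and reports the
#' quality metrics, mirroring one-at-a-time parameter studies over
#' `w`, `alpha`, `lam`, `k_s`, `h_s`.
#'
#' @param stacks list of [svr_stack()]s.
#' @param truth ground-truth [recon_volume()].
#' @param grid data.frame whose columns are any subset of
#'   `w, alpha, lam, k_s, h_s`; one reconstruction per row.
#' @param cfg base [pipeline_config()].
#' @return `grid` with `rmse`, `mssim` and `steering_ops` columns appended.
#' @export
run_ablation <- function(stacks, truth, grid, cfg = pipeline_config()) {
  stopifnot(nrow(grid) >= 1)
  res <- grid
  res$rmse <- NA_real_; res$mssim <- NA_real_; res$steering_ops <- NA_real_
  for (r in seq_len(nrow(grid))) {
    kr <- cfg$kr
    for (nm in intersect(names(grid), c("w", "alpha", "lam", "k_s", "h_s")))
      kr[[nm]] <- grid[[nm]][r]
    cfg_r <- cfg; cfg_r$kr <- do.call(kr_config, kr[names(formals(kr_config))])
    out <- reconstruct(stacks, cfg_r)
    met <- evaluate_reconstruction(out, truth)
    res$rmse[r] <- met$rmse
    res$mssim[r] <- met$mssim
    res$steering_ops[r] <- sum(attr(out$volume, "ops"))
  }
  res
}
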