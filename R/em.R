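#' EM classification of residuals into inliers and outliers
#'
#' Registration/simulation residuals `e*` are modeled as a two-component
#' mixture: a zero-mean Gaussian (inliers, standard deviation `sigma`) and a
#' uniform density `U` over the residual range (outliers), mixed with
#' proportion `c` of inliers.  `e_step()` computes per-pixel posterior
#' probabilities of being an inlier; `m_step()` re-estimates `sigma` and `c`;
#' [fit_em()] alternates the two to convergence.
#'
#' @param residuals numeric vector of residuals (finite).
#' @param sigma inlier standard deviation (> 0).
#' @param c_mix mixing proportion of inliers in [0, 1].
#' @param U uniform outlier density (> 0).
#' @return `e_step` returns posterior probabilities in [0, 1].
#' @export
e_step <- function(residuals, sigma, c_mix, U) {
  stopifnot(sigma > 0, U > 0, c_mix >= 0, c_mix <= 1)
  if (length(residuals) == 0) return(numeric(0))
  num <- c_mix * dnorm(residuals, 0, sigma)
  num / (num + (1 - c_mix) * U)
}

#' @rdname e_step
#' @param posteriors posterior probabilities from [e_step()].
#' @return `m_step` returns `list(sigma, c)`: the posterior-weighted residual
#'   standard deviation and the mean posterior.
#' @export
m_step <- function(residuals, posteriors) {
  sp <- sum(posteriors)
  if (sp <= 0) stop("degenerate EM fit: all posteriors are zero")
  list(sigma = sqrt(sum(posteriors * residuals^2) / sp),
       c = sp / length(residuals))
}

#' @rdname e_step
#' @param init optional warm start, a list with `sigma` and `c`.
#' @param tol relative convergence tolerance on `sigma` and absolute on `c`.
#' @param max_iter iteration cap.
#' @return `fit_em` returns a list of class `em_state`: `sigma`, `c`,
#'   `uniform_density`, `posteriors`, `n_iter`, `loglik` (per-iteration
#'   observed-data log-likelihood).
#' @export
fit_em <- function(residuals, init = NULL, tol = 1e-4, max_iter = 50) {
  residuals <- residuals[is.finite(residuals)]
  if (length(residuals) < 16)
    stop("need at least 16 valid residuals for the EM fit")
  rng <- diff(range(residuals))
  if (rng <= 0) {
    # zero spread: everything is a perfect inlier
    return(structure(list(sigma = .Machine$double.eps, c = 1,
                          uniform_density = Inf,
                          posteriors = rep(1, length(residuals)),
                          n_iter = 0L, loglik = numeric(0)),
                     class = "em_state"))
  }
  U <- 1 / rng
  sigma <- if (is.null(init)) max(sd(residuals), 1e-8) else init$sigma
  c_mix <- if (is.null(init)) 0.9 else init$c
  loglik <- numeric(0)
  for (it in seq_len(max_iter)) {
    p <- e_step(residuals, sigma, c_mix, U)
    loglik <- c(loglik,
                sum(log(c_mix * dnorm(residuals, 0, sigma) +
                        (1 - c_mix) * U)))
    upd <- m_step(residuals, p)
    # guard against point-mass collapse: residuals that are exactly zero
    # (e.g. background pixels of noise-free data) must not shrink the
    # inlier component to a spike that outlaws every structured pixel
    new_sigma <- max(upd$sigma, 0.02 * sd(residuals), 1e-12)
    new_c <- min(max(upd$c, 0), 1)
    done <- abs(new_sigma - sigma) / sigma < tol && abs(new_c - c_mix) < tol
    sigma <- new_sigma; c_mix <- new_c
    if (done) break
  }
  structure(list(sigma = sigma, c = c_mix, uniform_density = U,
                 posteriors = e_step(residuals, sigma, c_mix, U),
                 n_iter = it, loglik = loglik),
            class = "em_state")
}

#' @export
print.em_state <- function(x, ...) {
  cat(sprintf("<em_state> sigma = %.4g, c = %.3f (%d iterations)\n",
              x$sigma, x$c, x$n_iter))
  invisible(x)
}

#' Slice inlier probability
#'
#' `p_slice = sum_i p_i^2 / N` over the slice's valid pixels: the mean of the
#' squared pixel posteriors.
#'
#' @param posteriors posterior probabilities of the slice's valid pixels.
#' @return The slice probability in [0, 1], or `NA` for an empty slice
#'   (marked excluded by the caller).
#' @export
slice_probability <- function(posteriors) {
  posteriors <- posteriors[is.finite(posteriors)]
  if (length(posteriors) == 0) return(NA_real_)
  mean(posteriors^2)
}

#' Exclude outlier slices
#'
#' A slice is included iff its probability is at least `threshold`; `NA`
#' probabilities (empty slices) are excluded.
#'
#' @param slice_probs vector of slice probabilities.
#' @param threshold inclusion threshold in [0, 1); default 0.5 (0 keeps
#'   every non-empty slice).
#' @return Logical inclusion flags.
#' @export
exclude_outlier_slices <- function(slice_probs, threshold = 0.5) {
  stopifnot(threshold >= 0, threshold < 1)
  incl <- !is.na(slice_probs) & slice_probs >= threshold
  if (!any(incl))
    stop("all slices classified as outliers; cannot continue")
  incl
}
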