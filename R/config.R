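#' Model configuration
#'
#' Central configuration for profile geometry, the intensity model and the
#' shape model. The observed profile has `k_prime` samples spaced
#' `spacing_mm` apart along the outward vertex normal; the reference profile
#' has `k = k_prime + delta` samples, and by default `delta = k_prime`, so a
#' 20-point observed profile gives a 40-point reference profile and a
#' displacement window of 10 samples inward and 10 outward.
#'
#' @param k_prime observed profile length (samples).
#' @param delta maximum integer displacement; default `k_prime`.
#' @param spacing_mm sample spacing along the normal, mm.
#' @param n_components mixture components per modality (`Nr`).
#' @param sigma_I smoothness of the intensity covariance kernel
#'   `G_ij = exp(-(i-j)^2 / (2 sigma_I))` (variance-like units).
#' @param n0 Normal-Wishart strength on the profile mean.
#' @param alpha0 Wishart degrees of freedom for the intensity precision;
#'   default `k + 2`.
#' @param dir_alpha Dirichlet concentration on the mixing weights.
#' @param delta_prior_sd prior SD (in samples) of the per-subject training
#'   displacement; default `delta / 4`.
#' @param shape_h shape-prior height (expected displacement SD, samples).
#' @param shape_w shape-prior width (edges).
#' @param shape_n0 shape Normal-Wishart strength.
#' @param shape_alpha shape Wishart dof; default `N + 2`, resolved when the
#'   mesh size is known.
#' @param shape_mode `"predictive"` (Student-t posterior predictive,
#'   default) or `"plugin"` (Gaussian at posterior point estimates) for
#'   fitting.
#' @param n_starts optimiser restarts for per-vertex training.
#' @param maxit optimiser iteration cap per start.
#' @return a `mist_config` list.
#' @export
mist_config <- function(k_prime = 20, delta = k_prime, spacing_mm = 0.5,
                        n_components = 3, sigma_I = 0.5,
                        n0 = 1, alpha0 = NULL, dir_alpha = 1.5,
                        delta_prior_sd = delta / 4,
                        shape_h = 2, shape_w = 2, shape_n0 = 1,
                        shape_alpha = NULL,
                        shape_mode = c("predictive", "plugin"),
                        n_starts = 3, maxit = 300) {
  if (k_prime < 2) stop("k_prime must be at least 2")
  if (delta < 1) stop("delta must be at least 1")
  k <- k_prime + delta
  if (k %% 2 != 0) stop("k = k_prime + delta must be even")
  if (is.null(alpha0)) alpha0 <- k + 2
  if (alpha0 <= k - 1) stop("alpha0 must exceed k - 1 for a proper Wishart")
  structure(list(
    k_prime = as.integer(k_prime), delta = as.integer(delta),
    k = as.integer(k), spacing_mm = spacing_mm,
    n_components = as.integer(n_components), sigma_I = sigma_I,
    n0 = n0, alpha0 = alpha0, dir_alpha = dir_alpha,
    delta_prior_sd = delta_prior_sd,
    shape_h = shape_h, shape_w = shape_w, shape_n0 = shape_n0,
    shape_alpha = shape_alpha, shape_mode = match.arg(shape_mode),
    n_starts = as.integer(n_starts), maxit = as.integer(maxit)),
    class = "mist_config")
}

# positions (mm from the profile centre) of the k reference samples;
# x = 0, the physical boundary, falls between samples k/2 and k/2 + 1
profile_positions <- function(k, spacing_mm) {
  ((seq_len(k) - 1) - k / 2 + 0.5) * spacing_mm
}

# discretised displacement prior over the displacement index 0..delta
# (index delta/2 = no shift); a zero-mean Gaussian evaluated on the grid
# and renormalised
displacement_log_prior <- function(delta, prior_sd) {
  x <- (0:delta) - delta / 2
  lp <- stats::dnorm(x, 0, prior_sd, log = TRUE)
  lp - log(sum(exp(lp - max(lp)))) - max(lp)
}
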