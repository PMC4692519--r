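#' Prior profile specification
#'
#' Describes the prior mean profile of one mixture component of one
#' modality as a simple parametric function of the distance `x` (mm) along
#' the normal, with `x = 0` at the physical boundary: `flat` (constant `a`),
#' `step` (`a` inside, `b` outside) or `exponential` (`a` inside; a step to
#' `b` at the boundary decaying back to `a` with length scale `v_mm`). The
#' exponential form suits boundaries against thin structures (e.g. a white
#' matter sheet) because it contains a single sharp edge.
#'
#' @param fun `"flat"`, `"step"` or `"exponential"`.
#' @param a inside intensity.
#' @param b outside intensity (step/exponential).
#' @param v_mm decay length scale, mm (exponential; must be > 0).
#' @param beta scalar covariance-scale hyperparameter `beta_mr`
#'   (intensity^2 units); `NULL` to derive from `|b - a|` at model setup.
#' @return a `prior_profile_spec`.
#' @export
prior_profile_spec <- function(fun = c("flat", "step", "exponential"),
                               a, b = NULL, v_mm = NULL, beta = NULL) {
  fun <- match.arg(fun)
  if (fun != "flat" && is.null(b)) stop(fun, " prior requires parameter b")
  if (fun == "exponential") {
    if (is.null(v_mm) || v_mm <= 0) stop("exponential prior requires v_mm > 0")
  }
  if (!is.null(beta) && beta <= 0) stop("beta must be positive")
  structure(list(fun = fun, a = a, b = b, v_mm = v_mm, beta = beta),
            class = "prior_profile_spec")
}

#' Evaluate a prior profile function
#'
#' @param spec a [prior_profile_spec()].
#' @param x distance along the profile, mm; `x = 0` at the boundary.
#' @return intensities at `x`.
#' @export
eval_prior_function <- function(spec, x) {
  switch(spec$fun,
         flat = rep(spec$a, length(x)),
         step = ifelse(x < 0, spec$a, spec$b),
         exponential = ifelse(x < 0, spec$a,
                              spec$a + (spec$b - spec$a) * exp(-x / spec$v_mm)),
         stop("unknown prior function: ", spec$fun))
}

#' Build the prior mean profile vector
#'
#' Samples the prior function at the k reference-profile positions; the
#' boundary (`x = 0`) sits at the centre of the profile, between samples
#' `k/2` and `k/2 + 1`.
#'
#' @param spec a [prior_profile_spec()].
#' @param k reference profile length (even).
#' @param spacing_mm sample spacing, mm.
#' @return length-`k` numeric vector.
#' @export
build_mean_prior <- function(spec, k, spacing_mm) {
  if (k %% 2 != 0) stop("k must be even")
  eval_prior_function(spec, profile_positions(k, spacing_mm))
}

#' Median region intensities for automated prior setup
#'
#' Pools voxel intensities inside each named region mask across training
#' subjects and returns the median per region (robust to focal outliers
#' such as vessels). These medians feed the `a`/`b` parameters of the prior
#' profile specifications through a rule table.
#'
#' @param vols list over subjects of [image_volume()] (one modality).
#' @param region_masks named list of [image_volume()] masks (non-zero =
#'   in region), shared across subjects, or a list over subjects of such
#'   lists.
#' @return named numeric vector of median intensities.
#' @export
auto_intensity_setup <- function(vols, region_masks) {
  per_subject <- !inherits(region_masks[[1]], "image_volume")
  regions <- if (per_subject) names(region_masks[[1]]) else names(region_masks)
  out <- stats::setNames(numeric(length(regions)), regions)
  for (rg in regions) {
    vals <- numeric(0)
    for (s in seq_along(vols)) {
      msk <- if (per_subject) region_masks[[s]][[rg]] else region_masks[[rg]]
      sel <- vols[[s]]$data[msk$data != 0]
      vals <- c(vals, sel)
    }
    if (!length(vals)) stop("region mask '", rg, "' is empty")
    out[rg] <- stats::median(vals)
  }
  out
}

#' Build per-modality component priors from a declarative rule table
#'
#' The rule table (typically loaded from YAML, see
#' `inst/extdata/priors/ellipsoid_rules.yaml` for the shipped example) maps
#' each modality to a list of components whose `a`/`b` parameters name
#' regions whose median intensity (from [auto_intensity_setup()]) is
#' substituted, or give numeric values directly.
#'
#' @param rules list: per modality, a list of components with fields
#'   `function`, `a`, `b`, `v_mm`, `beta_rel` (relative covariance scale:
#'   `beta` is set so the expected profile SD is `beta_rel * |b - a|`).
#' @param medians named numeric vector of region medians per modality
#'   (list over modalities of named vectors).
#' @return named list per modality of lists of [prior_profile_spec()].
#' @export
build_priors_from_rules <- function(rules, medians) {
  resolve <- function(x, med) {
    if (is.character(x)) {
      if (!x %in% names(med)) stop("unknown region in rule table: ", x)
      unname(med[x])
    } else x
  }
  out <- list()
  for (m in names(rules)) {
    med <- medians[[m]]
    comps <- lapply(rules[[m]], function(cmp) {
      spec <- prior_profile_spec(
        fun = cmp[["function"]],
        a = resolve(cmp$a, med),
        b = if (!is.null(cmp$b)) resolve(cmp$b, med) else NULL,
        v_mm = cmp$v_mm)
      attr(spec, "beta_rel") <- if (!is.null(cmp$beta_rel)) cmp$beta_rel else 0.2
      spec
    })
    out[[m]] <- comps
  }
  out
}

#' Read a YAML prior rule file
#'
#' @param path YAML file: top level `modalities:` mapping modality to a
#'   component list (see [build_priors_from_rules()]).
#' @return the rule list.
#' @export
read_prior_rules <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$modalities)) stop("rule file has no 'modalities' section")
  y$modalities
}

#' Assemble the intensity prior set
#'
#' Converts per-modality component specifications into the numeric
#' hyperparameters used in training: prior mean profiles `mu_mr0`, scalar
#' Wishart scales `beta_mr` (chosen so the expected marginal profile SD is
#' `beta_rel * |b - a|`, default 0.2, unless the spec carries an explicit
#' `beta`), and the shared strengths.
#'
#' @param priors named list per modality of [prior_profile_spec()] lists
#'   (all modalities must have the same number of components).
#' @param config a [mist_config()].
#' @return an `intensity_prior_set`: list with `mu0` (k x Nm x Nr array),
#'   `beta` (Nm x Nr), `n0`, `alpha0`, `dir_alpha`, `modalities`.
#' @export
intensity_prior_set <- function(priors, config) {
  Nm <- length(priors)
  Nr <- length(priors[[1]])
  if (Nr < 1) stop("at least one component per modality is required")
  if (!all(vapply(priors, length, 1L) == Nr))
    stop("all modalities must have the same number of components")
  if (Nr != config$n_components)
    stop("prior component count (", Nr, ") does not match the configured ",
         "n_components (", config$n_components, ")")
  k <- config$k
  G <- make_smoothing_matrix(k, config$sigma_I)
  gg_diag_mean <- mean(diag(G %*% G))
  mu0 <- array(NA_real_, dim = c(k, Nm, Nr))
  beta <- matrix(NA_real_, Nm, Nr)
  for (m in seq_len(Nm)) {
    for (r in seq_len(Nr)) {
      spec <- priors[[m]][[r]]
      mu0[, m, r] <- build_mean_prior(spec, k, config$spacing_mm)
      if (!is.null(spec$beta)) {
        beta[m, r] <- spec$beta
      } else {
        rel <- attr(spec, "beta_rel")
        if (is.null(rel)) rel <- 0.2
        amp <- if (is.null(spec$b)) abs(spec$a) else abs(spec$b - spec$a)
        amp <- max(amp, 1e-3)
        # E[Sigma] ~ beta0 / alpha0 with beta0 = beta * G G; match diagonal
        beta[m, r] <- config$alpha0 * (rel * amp)^2 / gg_diag_mean
      }
    }
  }
  structure(list(mu0 = mu0, beta = beta, n0 = config$n0,
                 alpha0 = config$alpha0, dir_alpha = config$dir_alpha,
                 modalities = names(priors)),
            class = "intensity_prior_set")
}
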