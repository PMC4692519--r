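#' Intensity-profile smoothness kernel
#'
#' The intensity covariance is parameterised as `Sigma = G D G` with `D`
#' diagonal and `G_ij = exp(-(i-j)^2 / (2 sigma_I))`, a fixed correlation
#' structure across neighbouring profile samples. `sigma_I` is
#' variance-like: larger values give smoother profiles.
#'
#' @param k profile length.
#' @param sigma_I smoothness parameter (> 0).
#' @return k x k matrix `G` (unit diagonal, symmetric, positive definite;
#'   an error is raised if `sigma_I` is too large for `k` to keep `G`
#'   numerically positive definite).
#' @export
make_smoothing_matrix <- function(k, sigma_I) {
  if (sigma_I <= 0) stop("sigma_I must be positive")
  idx <- seq_len(k)
  G <- exp(-outer(idx, idx, "-")^2 / (2 * sigma_I))
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-10 * max(ev))
    stop("smoothing matrix is not positive definite; reduce sigma_I ",
         "(smallest eigenvalue ", signif(min(ev), 3), ")")
  G
}

#' Marginal parameters of a windowed profile model
#'
#' Marginalising a k-dimensional multivariate normal over the samples
#' outside a k'-length window reduces to dropping those dimensions from
#' the mean and *covariance*; the marginal precision is the inverse of the
#' covariance submatrix (not the precision submatrix).
#'
#' @param mu length-k mean.
#' @param Sigma k x k covariance.
#' @param shift window start (0-based, `0 <= shift <= k - k_prime`).
#' @param k_prime window length.
#' @return list with `mu` (length k') and `Lambda` (k' x k' precision).
#' @export
marginal_params <- function(mu, Sigma, shift, k_prime) {
  k <- length(mu)
  if (shift < 0 || shift > k - k_prime)
    stop("shift out of range [0, ", k - k_prime, "]")
  w <- (shift + 1):(shift + k_prime)
  Sw <- Sigma[w, w, drop = FALSE]
  list(mu = mu[w], Lambda = solve(Sw))
}

# model parameter containers ------------------------------------------------

new_vertex_model <- function(mu, Ddiag, theta, config, value = NA_real_,
                             convergence = NA_integer_) {
  structure(list(mu = mu, Ddiag = Ddiag, theta = theta,
                 value = value, convergence = convergence,
                 k = dim(mu)[1], Nm = dim(mu)[2], Nr = dim(mu)[3]),
            class = "vertex_intensity_model")
}

# flatten k x Nm x Nr arrays into the k x (Nm*Nr) layout used by the
# compiled kernels (column index m*Nr + r, 0-based)
flat_cols <- function(a) {
  k <- dim(a)[1]; Nm <- dim(a)[2]; Nr <- dim(a)[3]
  out <- matrix(NA_real_, k, Nm * Nr)
  for (m in seq_len(Nm)) for (r in seq_len(Nr))
    out[, (m - 1) * Nr + r] <- a[, m, r]
  out
}

pack_params <- function(mu, d, eta) {
  k <- dim(mu)[1]; Nm <- dim(mu)[2]; Nr <- dim(mu)[3]
  out <- numeric(0)
  for (m in seq_len(Nm)) for (r in seq_len(Nr))
    out <- c(out, mu[, m, r], d[, m, r])
  if (Nr > 1) for (m in seq_len(Nm)) out <- c(out, eta[[m]])
  out
}

unpack_params <- function(par, k, Nm, Nr) {
  mu <- array(NA_real_, c(k, Nm, Nr))
  d <- array(NA_real_, c(k, Nm, Nr))
  off <- 0
  for (m in seq_len(Nm)) for (r in seq_len(Nr)) {
    mu[, m, r] <- par[off + 1:k]; off <- off + k
    d[, m, r] <- par[off + 1:k]; off <- off + k
  }
  theta <- matrix(1 / Nr, Nm, Nr)
  if (Nr > 1) for (m in seq_len(Nm)) {
    eta <- c(par[off + 1:(Nr - 1)], 0); off <- off + Nr - 1
    e <- exp(eta - max(eta))
    theta[m, ] <- e / sum(e)
  }
  list(mu = mu, d = d, theta = theta)
}

#' Mixture log-likelihood of one subject's profiles at a given shift
#'
#' `sum_m log sum_r theta_mr N(y'_m | mu^w_mr, Lambda^w_mr)` where `w` is
#' the window start; modalities carry independent mixtures.
#'
#' @param yprime k' x Nm matrix of observed profiles.
#' @param model a `vertex_intensity_model`.
#' @param shift window start (0-based).
#' @param G smoothing matrix of the model's configuration.
#' @return scalar log-likelihood.
#' @export
profile_loglik <- function(yprime, model, shift, G) {
  yprime <- as.matrix(yprime)
  kp <- nrow(yprime)
  if (shift < 0 || shift > model$k - kp) stop("shift out of range")
  Z <- array(NA_real_, c(1, kp, model$Nm))
  for (m in seq_len(model$Nm)) Z[1, , m] <- yprime[, m]
  ll <- shift_logliks_cpp(Z, flat_cols(model$mu), flat_cols(model$Ddiag),
                          model$theta, G, model$Nr, model$Nm)
  ll[1, shift + 1]
}

#' Training objective for one vertex: negative log posterior and gradient
#'
#' The per-subject discrete displacement is marginalised over its grid
#' under the discretised zero-mean Gaussian prior; Normal-Wishart priors on
#' each component's mean/precision and a Dirichlet prior on the mixing
#' weights (with the log-Jacobian of the logit transform absorbed) complete
#' the posterior. Parameters are packed as, per (modality, component),
#' `mu` (k) then `log diag(D)` (k), followed by the `Nr - 1` mixing logits
#' per modality.
#'
#' @param par packed parameter vector.
#' @param profiles S x k' x Nm array of valid training profiles.
#' @param priors an [intensity_prior_set()].
#' @param config a [mist_config()].
#' @param want_grad compute the analytic gradient (default TRUE).
#' @return list with `value` (negative log posterior) and `gradient`.
#' @export
training_objective <- function(par, profiles, priors, config,
                               want_grad = TRUE) {
  G <- make_smoothing_matrix(config$k, config$sigma_I)
  Ginv <- solve(G)
  logdetG <- determinant(G, logarithm = TRUE)$modulus[1]
  lp <- displacement_log_prior(config$delta, config$delta_prior_sd)
  Nm <- dim(profiles)[3]
  res <- vertex_nlp_cpp(par, profiles, G, Ginv, logdetG,
                        flat_cols(priors$mu0), as.vector(t_beta(priors)),
                        priors$n0, priors$alpha0, priors$dir_alpha,
                        lp, config$n_components, Nm, want_grad)
  list(value = res$value, gradient = res$gradient)
}

# beta in column order m*Nr + r
t_beta <- function(priors) as.vector(t(priors$beta))

#' Packed starting parameters for per-vertex training
#'
#' The prior-defined initialisation (`mu <- mu0`, `D <- beta/alpha0`,
#' uniform mixing), optionally jittered for multi-start optimisation or
#' gradient checking.
#'
#' @param priors an [intensity_prior_set()].
#' @param config a [mist_config()].
#' @param jitter relative jitter scale (0 = exact prior initialisation).
#' @param seed optional seed for the jitter.
#' @return packed parameter vector (see [training_objective()]).
#' @export
init_training_params <- function(priors, config, jitter = 0, seed = NULL) {
  init_params(priors, config, jitter = jitter, seed = seed)
}

init_params <- function(priors, config, jitter = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  k <- config$k; Nr <- config$n_components
  Nm <- dim(priors$mu0)[2]
  G <- make_smoothing_matrix(k, config$sigma_I)
  ggd <- mean(diag(G %*% G))
  mu <- array(NA_real_, c(k, Nm, Nr))
  d <- array(NA_real_, c(k, Nm, Nr))
  for (m in seq_len(Nm)) for (r in seq_len(Nr)) {
    sd_prior <- sqrt(priors$beta[m, r] * ggd / priors$alpha0)
    mu[, m, r] <- priors$mu0[, m, r] +
      if (jitter > 0) stats::rnorm(k, 0, jitter * sd_prior) else 0
    d[, m, r] <- log(priors$beta[m, r] / priors$alpha0) +
      if (jitter > 0) stats::rnorm(k, 0, jitter * 0.5) else 0
  }
  eta <- replicate(Nm, if (jitter > 0) stats::rnorm(Nr - 1, 0, jitter)
                   else numeric(Nr - 1), simplify = FALSE)
  pack_params(mu, d, eta)
}

#' MAP training of a single vertex's intensity model
#'
#' Gradient-based local optimisation (L-BFGS-B, monotone in the objective)
#' of [training_objective()] from the prior-defined initialisation
#' (`mu <- mu0`, `D <- beta/alpha0`, uniform mixing), with optional seeded
#' multi-start to reduce the risk of a poor local optimum.
#'
#' @param profiles S x k' x Nm array of valid training profiles (S >= 1).
#' @param priors an [intensity_prior_set()].
#' @param config a [mist_config()].
#' @param seed integer seed for the multi-start jitter.
#' @return a `vertex_intensity_model` (MAP estimates of the mean profiles,
#'   covariance diagonals and mixing weights, plus the final objective
#'   value and convergence flag; non-convergence warns and returns the
#'   best iterate).
#' @export
train_vertex_model <- function(profiles, priors, config, seed = 1) {
  if (length(dim(profiles)) != 3 || dim(profiles)[1] < 1)
    stop("profiles must be a non-empty S x k_prime x Nm array")
  Nm <- dim(profiles)[3]
  Nr <- config$n_components
  G <- make_smoothing_matrix(config$k, config$sigma_I)
  Ginv <- solve(G)
  logdetG <- determinant(G, logarithm = TRUE)$modulus[1]
  lp <- displacement_log_prior(config$delta, config$delta_prior_sd)
  mu0 <- flat_cols(priors$mu0)
  bvec <- t_beta(priors)

  cache <- new.env()
  evalfun <- function(par) {
    if (!is.null(cache$par) && identical(cache$par, par)) return(cache$res)
    res <- vertex_nlp_cpp(par, profiles, G, Ginv, logdetG, mu0, bvec,
                          priors$n0, priors$alpha0, priors$dir_alpha,
                          lp, Nr, Nm, TRUE)
    cache$par <- par; cache$res <- res
    res
  }
  fn <- function(par) evalfun(par)$value
  gr <- function(par) evalfun(par)$gradient

  best <- NULL
  for (st in seq_len(max(1L, config$n_starts))) {
    par0 <- init_params(priors, config, jitter = if (st == 1) 0 else 0.3,
                        seed = if (st == 1) NULL else seed + 977L * st)
    opt <- stats::optim(par0, fn, gr, method = "L-BFGS-B",
                        control = list(maxit = config$maxit, factr = 1e8))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (best$convergence != 0 && best$convergence != 1)
    warning("vertex optimiser did not converge (code ", best$convergence,
            "); returning best iterate")
  up <- unpack_params(best$par, config$k, Nm, Nr)
  Dd <- up$d; Dd[] <- exp(up$d)
  new_vertex_model(up$mu, Dd, up$theta, config, value = best$value,
                   convergence = best$convergence)
}

#' Train the intensity models at every mesh vertex
#'
#' Trains each vertex independently on its valid training profiles
#' (subject-vertex pairs flagged out-of-FOV are dropped).
#'
#' @param pset a `profile_set` from [extract_profiles()].
#' @param priors an [intensity_prior_set()].
#' @param config a [mist_config()].
#' @param seed integer seed.
#' @param verbose print progress every 50 vertices.
#' @return list of `vertex_intensity_model`, one per vertex, with class
#'   `mist_intensity_models`.
#' @export
train_intensity_models <- function(pset, priors, config, seed = 1,
                                   verbose = FALSE) {
  N <- dim(pset$profiles)[3]
  models <- vector("list", N)
  for (i in seq_len(N)) {
    keep <- which(pset$valid[, i])
    if (!length(keep))
      stop("no valid training profiles at vertex ", i)
    Z <- pset$profiles[keep, , i, , drop = FALSE]
    # reorder to S x k' x Nm
    Zc <- aperm(array(Z, dim = dim(Z)[c(1, 2, 4)]), c(1, 3, 2))
    models[[i]] <- train_vertex_model(Zc, priors, config,
                                      seed = seed + i)
    if (verbose && i %% 50 == 0) message("trained vertex ", i, "/", N)
  }
  structure(models, class = "mist_intensity_models")
}

#' Posterior over the integer displacement for one subject at one vertex
#'
#' `p(displacement | profiles)` on the grid `0..Delta` (displacement index;
#' `Delta/2` = no shift, larger = outward), combining the trained mixture
#' likelihood with the discretised displacement prior. Ties in the argmax
#' are broken toward the centre.
#'
#' @param z k' x Nm matrix of the subject's observed profiles at the vertex.
#' @param model a `vertex_intensity_model`.
#' @param config a [mist_config()].
#' @return list with `prob` (length Delta+1, sums to 1), `argmax`
#'   (0-based displacement index) and `delta_samples` (argmax - Delta/2).
#' @export
displacement_posterior <- function(z, model, config) {
  z <- as.matrix(z)
  kp <- nrow(z)
  delta <- model$k - kp
  G <- make_smoothing_matrix(model$k, config$sigma_I)
  Z <- array(NA_real_, c(1, kp, model$Nm))
  for (m in seq_len(model$Nm)) Z[1, , m] <- z[, m]
  ll_w <- shift_logliks_cpp(Z, flat_cols(model$mu), flat_cols(model$Ddiag),
                            model$theta, G, model$Nr, model$Nm)[1, ]
  # window start w corresponds to displacement index delta - w
  ll <- rev(ll_w)
  lp <- displacement_log_prior(delta, config$delta_prior_sd)
  post <- ll + lp
  post <- exp(post - max(post))
  post <- post / sum(post)
  idx <- which(post >= max(post) - 1e-12) - 1L
  argmax <- idx[which.min(abs(idx - delta / 2))]
  list(prob = post, argmax = argmax, delta_samples = argmax - delta / 2)
}
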