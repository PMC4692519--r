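#' Normal-Wishart shape prior over vertex displacements
#'
#' The prior covariance scale is a Gaussian kernel of the mesh graph
#' distances, `beta_ij = h^2 exp(-d_ij^2 / (2 w^2))`: `h` (height, samples)
#' sets the expected displacement scale and `w` (width, edges) how strongly
#' neighbouring vertices co-vary. The prior mean is zero (the reference
#' mesh). Positive definiteness is enforced by adding diagonal jitter when
#' needed (recorded in the returned object).
#'
#' @param dist N x N edge-distance matrix from [edge_distances()]; `Inf`
#'   entries become zero covariance.
#' @param h height parameter, samples.
#' @param w width parameter, edges.
#' @param n0s prior strength on the mean.
#' @param alphas Wishart degrees of freedom (default `N + 2`).
#' @return a `shape_prior`: list with `mu0`, `n0`, `alpha`, `beta`, `h`,
#'   `w`, `jitter`.
#' @export
build_shape_prior <- function(dist, h, w, n0s = 1, alphas = NULL) {
  if (h <= 0 || w <= 0) stop("h and w must be positive")
  N <- nrow(dist)
  if (is.null(alphas)) alphas <- N + 2
  if (alphas <= N - 1) stop("alphas must exceed N - 1")
  beta <- h^2 * exp(-dist^2 / (2 * w^2))
  beta[!is.finite(dist)] <- 0
  if (!all(is.finite(beta))) stop("non-finite kernel values")
  jitter <- 0
  ev <- eigen(beta, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8 * h^2) {
    jitter <- 1e-8 * h^2 - min(ev)
    beta <- beta + diag(jitter, N)
  }
  structure(list(mu0 = rep(0, N), n0 = n0s, alpha = alphas, beta = beta,
                 h = h, w = w, jitter = jitter, N = N, n_subjects = 0L),
            class = "shape_prior")
}

#' Conjugate update of the shape model from training displacements
#'
#' Standard Normal-Wishart update with the per-subject most-likely
#' displacements (in samples) as observations. With zero subjects the
#' prior is returned as the posterior.
#'
#' @param prior a [build_shape_prior()] object (or a previous posterior,
#'   enabling sequential updating).
#' @param displacements Nt x N matrix of per-subject displacements, samples.
#' @return a `shape_posterior`: updated `mu`, `n`, `alpha`, `beta`, with
#'   cached point estimates `mean` and `precision` (`E[Lambda] =
#'   alpha * beta^-1`).
#' @export
update_shape_posterior <- function(prior, displacements = NULL) {
  N <- prior$N
  if (is.null(prior$mu0)) {
    # sequential updating: a previous posterior serves as the prior
    prior$mu0 <- prior$mu
    prior$n0 <- prior$n
  }
  if (is.null(displacements) || nrow(displacements) == 0) {
    post <- prior
  } else {
    displacements <- as.matrix(displacements)
    if (ncol(displacements) != N) stop("displacement width must equal N")
    if (!all(is.finite(displacements))) stop("non-finite displacements")
    Nt <- nrow(displacements)
    dbar <- colMeans(displacements)
    centred <- sweep(displacements, 2, dbar)
    scatter <- crossprod(centred)
    shift <- (prior$n0 * Nt / (prior$n0 + Nt)) *
      tcrossprod(dbar - prior$mu0)
    post <- prior
    post$mu0 <- (prior$n0 * prior$mu0 + Nt * dbar) / (prior$n0 + Nt)
    post$n0 <- prior$n0 + Nt
    post$alpha <- prior$alpha + Nt
    post$beta <- prior$beta + scatter + shift
    post$n_subjects <- prior$n_subjects + Nt
  }
  betainv <- solve(post$beta)
  structure(list(mu = post$mu0, n = post$n0, alpha = post$alpha,
                 beta = post$beta, N = N, n_subjects = post$n_subjects,
                 mean = post$mu0,
                 precision = post$alpha * betainv,
                 h = post$h, w = post$w, jitter = post$jitter),
            class = "shape_posterior")
}

#' Shape log-density of a displacement vector, with gradient
#'
#' `plugin` mode evaluates a multivariate normal at the posterior point
#' estimates (`mu_n`, `E[Lambda] = alpha_n beta_n^-1`); `predictive` mode
#' evaluates the multivariate Student-t posterior predictive with
#' `alpha_n - N + 1` degrees of freedom and scale
#' `((n_n + 1) / (n_n (alpha_n - N + 1))) beta_n`, which accounts for the
#' remaining posterior uncertainty in the shape parameters.
#'
#' @param delta length-N displacement vector, samples.
#' @param post a `shape_posterior`.
#' @param mode `"plugin"` or `"predictive"`.
#' @return list with `value` (log density) and `gradient` (length N).
#' @export
shape_logpdf <- function(delta, post, mode = c("predictive", "plugin")) {
  mode <- match.arg(mode)
  N <- post$N
  r <- delta - post$mu
  if (mode == "plugin") {
    Lam <- post$precision
    ch <- tryCatch(chol(Lam), error = function(e) NULL)
    if (is.null(ch)) stop("shape precision is not positive definite")
    logdet <- 2 * sum(log(diag(ch)))
    Lr <- as.vector(Lam %*% r)
    val <- 0.5 * logdet - 0.5 * N * log(2 * pi) - 0.5 * sum(r * Lr)
    list(value = val, gradient = -Lr)
  } else {
    nu <- post$alpha - N + 1
    if (nu <= 0) stop("predictive dof must be positive")
    S <- ((post$n + 1) / (post$n * nu)) * post$beta
    ch <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(ch)) stop("predictive scale is not positive definite")
    logdetS <- 2 * sum(log(diag(ch)))
    Sinv_r <- backsolve(ch, forwardsolve(t(ch), r))
    q <- sum(r * Sinv_r)
    val <- lgamma((nu + N) / 2) - lgamma(nu / 2) -
      0.5 * N * log(nu * pi) - 0.5 * logdetS -
      0.5 * (nu + N) * log1p(q / nu)
    g <- -as.vector((nu + N) / (nu + q) * Sinv_r)
    list(value = val, gradient = g)
  }
}
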