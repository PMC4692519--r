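test_that("log-likelihood interpolation is exact and differentiable", {
  set.seed(14)
  row <- rnorm(13, -50, 3)
  x <- (0:12) - 6
  got <- interpolate_loglik(row, x)
  expect_equal(got$value, row, tolerance = 1e-12)

  lin <- seq(-30, -18, length.out = 13)
  gl <- interpolate_loglik(lin, c(-5.5, 0.25, 3.7))
  expect_equal(gl$derivative, rep(1, 3), tolerance = 1e-9)

  xs <- seq(-5.7, 5.7, by = 0.31)
  d_an <- interpolate_loglik(row, xs)$derivative
  h <- 1e-5
  d_fd <- (interpolate_loglik(row, xs + h)$value -
           interpolate_loglik(row, xs - h)$value) / (2 * h)
  expect_lt(max(abs(d_an - d_fd) / pmax(abs(d_fd), 1e-3)), 1e-5)

  # out-of-range values are clamped
  expect_equal(interpolate_loglik(row, 100)$value, row[13], tolerance = 1e-12)
})

make_toy_table <- function(rows, spacing = 0.7) {
  structure(list(loglik = rows, valid = rep(TRUE, nrow(rows)),
                 delta = ncol(rows) - 1L, spacing_mm = spacing),
            class = "likelihood_table")
}

toy_shape <- function(N, mean = NULL, prec_scale = 1) {
  m <- icosphere_mesh(0, c(5, 5, 5))
  stopifnot(nrow(m$vertices) == N)
  prior <- build_shape_prior(edge_distances(m), h = 1.5, w = 2)
  set.seed(15)
  post <- update_shape_posterior(prior, matrix(rnorm(25 * N, 0, 1), 25, N))
  if (!is.null(mean)) post$mu <- post$mean <- mean
  post$precision <- post$precision * prec_scale
  post$beta <- post$beta / prec_scale
  post
}

test_that("flat likelihood returns the shape mean exactly", {
  N <- 12
  mu <- seq(-1, 1, length.out = N)
  post <- toy_shape(N, mean = mu)
  tab <- make_toy_table(matrix(-40, N, 13))
  cfg <- mist_config(k_prime = 12, n_components = 1,
                     shape_mode = "predictive")
  fit <- fit_displacements(tab, post, cfg)
  expect_equal(fit$delta_samples, mu, tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(fit$delta_mm, mu * 0.7, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("extreme shape precision selects prior mean or likelihood argmax", {
  N <- 12
  set.seed(16)
  mu <- runif(N, -2, 2)
  peaks <- sample(2:10, N, replace = TRUE)
  rows <- t(sapply(peaks, function(p) -0.5 * ((0:12) - p)^2 * 4))
  cfg <- mist_config(k_prime = 12, n_components = 1, shape_mode = "plugin")

  tight <- toy_shape(N, mean = mu, prec_scale = 1e6)
  fit_t <- fit_displacements(make_toy_table(rows), tight, cfg)
  expect_lt(max(abs(fit_t$delta_samples - mu)), 0.05)

  loose <- toy_shape(N, mean = mu, prec_scale = 1e-6)
  fit_l <- fit_displacements(make_toy_table(rows), loose, cfg)
  expect_lt(max(abs(fit_l$delta_samples - (peaks - 6))), 0.05)

  # the final objective dominates both canonical starting points
  obj <- function(d, tab, post) {
    v <- shape_logpdf(d, post, "plugin")$value
    for (i in 1:N) v <- v + interpolate_loglik(tab$loglik[i, ], d[i])$value
    v
  }
  tab <- make_toy_table(rows)
  mid <- toy_shape(N, mean = mu)
  fit_m <- fit_displacements(tab, mid, cfg)
  f_final <- obj(fit_m$delta_samples, tab, mid)
  expect_gte(f_final + 1e-6, obj(pmin(6, pmax(-6, mu)), tab, mid))
  expect_gte(f_final + 1e-6, obj(rep(0, N), tab, mid))
})

test_that("likelihood tables are additive over modalities", {
  spec <- standard_spec(1)
  coh <- generate_cohort(spec, 3, 1, seed = 19)
  norm1 <- function(s) normalise_subject(s$volumes, csf_mask = s$csf_mask)
  tv <- lapply(coh$train, norm1)
  pri <- phantom_priors(coh, tv)
  model <- train_mist(tv, coh$base$mesh, pri, spec$config, seed = 2)
  sv <- norm1(coh$test[[1]])
  cfg <- spec$config
  t_all <- build_likelihood_table(sv, model$mesh, model$normals,
                                  model$intensity, cfg)
  t_t1 <- build_likelihood_table(sv, model$mesh, model$normals,
                                 model$intensity, cfg, modalities = "t1w")
  t_t2 <- build_likelihood_table(sv, model$mesh, model$normals,
                                 model$intensity, cfg, modalities = "t2w")
  expect_equal(t_all$loglik, t_t1$loglik + t_t2$loglik, tolerance = 1e-8)

  # config mismatch is rejected
  bad_cfg <- mist_config(k_prime = 10, n_components = 2)
  expect_error(build_likelihood_table(sv, model$mesh, model$normals,
                                      model$intensity, bad_cfg),
               "config mismatch")
  expect_error(build_likelihood_table(sv, model$mesh, model$normals,
                                      model$intensity, cfg,
                                      modalities = "fa"), "missing volumes")

  # rigid translation of volumes and mesh leaves the table unchanged
  off <- c(3.2, -1.7, 2.9)
  sv_t <- lapply(sv, function(v) {
    a <- v$affine; a[1:3, 4] <- a[1:3, 4] + off
    image_volume(v$data, a, modality = v$modality,
                 normalisation = v$normalisation)
  })
  mesh_t <- triangle_mesh(sweep(model$mesh$vertices, 2, off, "+"),
                          model$mesh$faces)
  t_shift <- build_likelihood_table(sv_t, mesh_t, model$normals,
                                    model$intensity, cfg)
  expect_equal(t_shift$loglik, t_all$loglik, tolerance = 1e-8)
})

test_that("invalid vertices fall back to the shape prior", {
  N <- 12
  mu <- seq(-1, 1, length.out = N)
  post <- toy_shape(N, mean = mu, prec_scale = 1)
  rows <- matrix(rep(-0.5 * ((0:12) - 9)^2 * 8, N), N, byrow = TRUE)
  tab <- make_toy_table(rows)
  tab$valid[3] <- FALSE
  cfg <- mist_config(k_prime = 12, n_components = 1, shape_mode = "plugin")
  fit <- fit_displacements(tab, post, cfg)
  # vertex 3 has no data: it stays near the (conditional) shape estimate
  # rather than at the data peak (+3 samples) the other vertices move to
  expect_gt(fit$delta_samples[1], 2)
  expect_lt(fit$delta_samples[3], 1.5)
  expect_gt(fit$delta_samples[1] - fit$delta_samples[3], 1)
})

test_that("the zero-displacement baseline reproduces the reference mesh", {
  m <- icosphere_mesh(1, c(8, 7, 6))
  g <- voxel_grid(c(24, 24, 24), voxel_mm = 1)
  nlr <- nlr_baseline(m, grid = g)
  expect_equal(nlr$delta_samples, rep(0, nrow(m$vertices)))
  expect_equal(nlr$mask$data, rasterise_mesh(m, g)$data)
  expect_equal(nlr$mesh$vertices, m$vertices)
})
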