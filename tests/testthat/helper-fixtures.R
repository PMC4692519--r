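# shared fixtures and independent oracles, built in code at test time

# axis-aligned cube mesh [-h, h]^3 (12 triangles, outward winding)
cube_mesh <- function(h = 2.5) {
  v <- as.matrix(expand.grid(x = c(-h, h), y = c(-h, h), z = c(-h, h)))
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = -h
    c(5, 6, 7), c(6, 8, 7),   # z = +h
    c(1, 2, 5), c(2, 6, 5),   # y = -h
    c(3, 7, 4), c(4, 7, 8),   # y = +h
    c(1, 5, 3), c(3, 5, 7),   # x = -h
    c(2, 4, 6), c(4, 8, 6))   # x = +h
  triangle_mesh(v, f)
}

# brute-force all-pairs shortest paths on the mesh edge graph
floyd_warshall_distances <- function(mesh) {
  n <- nrow(mesh$vertices)
  d <- matrix(Inf, n, n); diag(d) <- 0
  f <- mesh$faces
  for (t in seq_len(nrow(f)))
    for (pair in list(f[t, 1:2], f[t, 2:3], f[t, c(3, 1)])) {
      d[pair[1], pair[2]] <- 1; d[pair[2], pair[1]] <- 1
    }
  for (k in seq_len(n))
    for (i in seq_len(n)) {
      via <- d[i, k] + d[k, ]
      upd <- via < d[i, ]
      d[i, upd] <- via[upd]
    }
  d
}

# product Gauss-Legendre integration of a k=4 Gaussian density over two
# dropped coordinates; independent oracle for the marginalisation rule
quadrature_marginal_density <- function(mu, Sigma, shift, y, n_nodes = 64) {
  Lam4 <- solve(Sigma)
  keep <- shift + 1:2
  drop_idx <- setdiff(seq_along(mu), keep)
  lo <- mu[drop_idx] - 9 * sqrt(diag(Sigma)[drop_idx])
  hi <- mu[drop_idx] + 9 * sqrt(diag(Sigma)[drop_idx])
  g1 <- pracma::gaussLegendre(n_nodes, lo[1], hi[1])
  g2 <- pracma::gaussLegendre(n_nodes, lo[2], hi[2])
  tot <- 0
  for (a in seq_len(n_nodes)) for (b in seq_len(n_nodes)) {
    yy <- numeric(length(mu)); yy[keep] <- y
    yy[drop_idx] <- c(g1$x[a], g2$x[b])
    q <- drop(t(yy - mu) %*% Lam4 %*% (yy - mu))
    tot <- tot + g1$w[a] * g2$w[b] * exp(-0.5 * q)
  }
  tot * sqrt(det(Lam4)) / (2 * pi)^2
}

# a small two-component, possibly multimodal prior set for training tests
toy_prior_set <- function(cfg, Nm = 1) {
  pris <- lapply(seq_len(Nm), function(m)
    lapply(seq_len(cfg$n_components), function(r)
      if (r == 1) prior_profile_spec("step", a = 100, b = 60)
      else prior_profile_spec("exponential", a = 100, b = 130, v_mm = 1)))
  names(pris) <- paste0("m", seq_len(Nm))
  intensity_prior_set(pris, cfg)
}

# simulate observed profiles from a reference profile at planted
# displacement indices (window start = delta - shift)
simulate_profiles <- function(mu_true, shifts, kp, noise_sd, Nm = 1) {
  S <- length(shifts)
  delta <- length(mu_true) - kp
  Z <- array(NA_real_, c(S, kp, Nm))
  for (s in seq_len(S)) {
    w <- delta - shifts[s]
    for (m in seq_len(Nm))
      Z[s, , m] <- mu_true[(w + 1):(w + kp)] + rnorm(kp, 0, noise_sd)
  }
  Z
}

# constant-intensity volume on a default grid
constant_volume <- function(value, dim = c(12, 12, 12), voxel_mm = 1,
                            modality = "t1w") {
  g <- voxel_grid(dim, voxel_mm = voxel_mm)
  image_volume(array(value, dim), g$affine, modality = modality)
}

# volume whose intensity equals the x coordinate in mm (linear field)
linear_x_volume <- function(dim = c(31, 15, 15), voxel_mm = 1) {
  g <- voxel_grid(dim, voxel_mm = voxel_mm)
  idx <- array(rep(0:(dim[1] - 1), times = prod(dim[2:3])), dim)
  x_mm <- idx * voxel_mm + g$affine[1, 4]
  image_volume(x_mm, g$affine, modality = "other", normalisation = "none")
}
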