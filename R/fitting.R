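#' Per-vertex displacement log-likelihood table for a new subject
#'
#' Samples the observed profile (k' points centred on each reference
#' vertex) from the normalised subject volumes and evaluates the trained
#' mixture log-likelihood for every integer displacement. Columns are
#' indexed by the displacement index `0..Delta` (`Delta/2` = no shift,
#' larger = outward); internally the displacement index `db` maps to the
#' reference-profile window starting at `Delta - db`. Vertices with any
#' out-of-FOV sample are flagged invalid and contribute only the shape
#' prior during fitting.
#'
#' @param vols named list of normalised [image_volume()] per modality (the
#'   model's modalities, or a subset via `modalities` for unimodal fits).
#' @param mesh reference [triangle_mesh()] the models were trained on.
#' @param normals vertex normals for `mesh`.
#' @param models a `mist_intensity_models` list.
#' @param config a [mist_config()] (must match the training configuration).
#' @param modalities optional character subset of the model's modalities.
#' @return a `likelihood_table`: list with `loglik` (N x (Delta+1)),
#'   `valid` (length N), `delta`, `spacing_mm`.
#' @export
build_likelihood_table <- function(vols, mesh, normals, models, config,
                                   modalities = NULL) {
  N <- nrow(mesh$vertices)
  if (length(models) != N) stop("model count does not match mesh vertices")
  mod_names <- attr(models, "modalities")
  if (is.null(mod_names)) mod_names <- names(vols)
  use <- if (is.null(modalities)) mod_names else modalities
  if (!all(use %in% names(vols)))
    stop("missing volumes for modalities: ",
         paste(setdiff(use, names(vols)), collapse = ", "))
  midx <- match(use, mod_names)
  if (anyNA(midx)) stop("model was not trained on: ",
                        paste(use[is.na(midx)], collapse = ", "))
  if (models[[1]]$k != config$k)
    stop("config mismatch: model k = ", models[[1]]$k,
         ", requested k = ", config$k)
  kp <- config$k_prime; delta <- config$delta
  G <- make_smoothing_matrix(config$k, config$sigma_I)
  loglik <- matrix(NA_real_, N, delta + 1)
  valid <- rep(TRUE, N)
  for (i in seq_len(N)) {
    z <- matrix(NA_real_, kp, length(use))
    ok <- TRUE
    for (mi in seq_along(use)) {
      pr <- sample_profile(vols[[use[mi]]], mesh$vertices[i, ], normals[i, ],
                           config$spacing_mm, kp)
      if (!all(pr$valid)) { ok <- FALSE; break }
      z[, mi] <- pr$values
    }
    if (!ok) { valid[i] <- FALSE; next }
    mdl <- models[[i]]
    sub <- subset_model(mdl, midx)
    Z <- array(NA_real_, c(1, kp, length(use)))
    for (mi in seq_along(use)) Z[1, , mi] <- z[, mi]
    llw <- shift_logliks_cpp(Z, flat_cols(sub$mu), flat_cols(sub$Ddiag),
                             sub$theta, G, sub$Nr, sub$Nm)[1, ]
    loglik[i, ] <- rev(llw)  # window start Delta - db -> displacement db
  }
  structure(list(loglik = loglik, valid = valid, delta = delta,
                 spacing_mm = config$spacing_mm),
            class = "likelihood_table")
}

# restrict a vertex model to a subset of modalities
subset_model <- function(model, midx) {
  new_vertex_model(model$mu[, midx, , drop = FALSE],
                   model$Ddiag[, midx, , drop = FALSE],
                   model$theta[midx, , drop = FALSE],
                   NULL, value = model$value)
}

#' Interpolate a displacement log-likelihood row to continuous shifts
#'
#' Natural cubic spline through the grid values as a function of the
#' displacement in samples (`delta_samples = db - Delta/2`); exact at grid
#' points, C1 derivative returned.
#'
#' @param row length-(Delta+1) log-likelihood values.
#' @param delta_samples continuous displacement(s), in `[-Delta/2, Delta/2]`
#'   (out-of-range values are clamped).
#' @return list with `value` and `derivative` at `delta_samples`.
#' @export
interpolate_loglik <- function(row, delta_samples) {
  delta <- length(row) - 1L
  x <- (0:delta) - delta / 2
  f <- stats::splinefun(x, row, method = "natural")
  ds <- pmin(delta / 2, pmax(-delta / 2, delta_samples))
  list(value = f(ds), derivative = f(ds, deriv = 1))
}

#' MAP estimate of the continuous displacement field
#'
#' Maximises the sum of the interpolated per-vertex profile log-likelihoods
#' and the shape log-density over the box `|delta_i| <= Delta/2` (the hard
#' limit implied by the profile window) by bounded gradient ascent
#' (L-BFGS-B) started at the posterior shape mean.
#'
#' @param table a [build_likelihood_table()] result.
#' @param shape a `shape_posterior` on the same mesh.
#' @param config a [mist_config()].
#' @param mesh reference mesh; if supplied the deformed mesh is returned.
#' @param grid optional [voxel_grid()] (or [image_volume()]); if supplied
#'   the deformed mesh is rasterised to a mask.
#' @param normals optional precomputed normals.
#' @return a `segmentation_result`: `delta_samples`, `delta_mm`, `mesh`
#'   (deformed, if `mesh` given), `mask` (if `grid` given), and `fit`
#'   diagnostics (final log posterior, convergence, iterations).
#' @export
fit_displacements <- function(table, shape, config, mesh = NULL,
                              grid = NULL, normals = NULL) {
  N <- nrow(table$loglik)
  if (shape$N != N) stop("shape posterior and table sizes differ")
  delta <- table$delta
  half <- delta / 2
  x <- (0:delta) - half
  splines <- vector("list", N)
  for (i in seq_len(N)) {
    if (table$valid[i])
      splines[[i]] <- stats::splinefun(x, table$loglik[i, ], method = "natural")
  }
  mode <- config$shape_mode
  negobj <- function(d) {
    sl <- shape_logpdf(d, shape, mode = mode)
    v <- sl$value
    for (i in seq_len(N)) if (table$valid[i]) v <- v + splines[[i]](d[i])
    -v
  }
  neggrad <- function(d) {
    sl <- shape_logpdf(d, shape, mode = mode)
    g <- sl$gradient
    for (i in seq_len(N)) if (table$valid[i])
      g[i] <- g[i] + splines[[i]](d[i], deriv = 1)
    -g
  }
  d0 <- pmin(half, pmax(-half, shape$mean))
  opt <- stats::optim(d0, negobj, neggrad, method = "L-BFGS-B",
                      lower = rep(-half, N), upper = rep(half, N),
                      control = list(maxit = 1000))
  if (opt$convergence != 0)
    warning("displacement optimiser did not converge (code ",
            opt$convergence, "); returning best iterate")
  delta_samples <- opt$par
  delta_mm <- delta_samples * table$spacing_mm
  out <- list(delta_samples = delta_samples, delta_mm = delta_mm,
              mesh = NULL, mask = NULL,
              fit = list(log_posterior = -opt$value,
                         convergence = opt$convergence,
                         counts = opt$counts))
  if (!is.null(mesh)) {
    if (is.null(normals)) normals <- compute_vertex_normals(mesh)
    out$mesh <- deform_mesh(mesh, delta_mm, normals)
    if (!is.null(grid)) out$mask <- rasterise_mesh(out$mesh, grid)
  }
  class(out) <- "segmentation_result"
  out
}

#' Zero-displacement baseline segmentation
#'
#' Returns the reference mesh unchanged (all displacements zero) — the
#' result of relying on the prior registration alone, used as a baseline
#' in comparison experiments.
#'
#' @param mesh reference [triangle_mesh()].
#' @param shape a `shape_posterior` (recorded for diagnostics only).
#' @param grid optional [voxel_grid()] for the mask.
#' @param spacing_mm sample spacing used for the mm conversion.
#' @return a `segmentation_result` with `delta_samples` identically zero.
#' @export
nlr_baseline <- function(mesh, shape = NULL, grid = NULL, spacing_mm = NA) {
  N <- nrow(mesh$vertices)
  out <- list(delta_samples = rep(0, N), delta_mm = rep(0, N),
              mesh = mesh,
              mask = if (!is.null(grid)) rasterise_mesh(mesh, grid) else NULL,
              fit = list(log_posterior = NA_real_, convergence = 0L,
                         counts = c(0, 0)))
  class(out) <- "segmentation_result"
  out
}
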