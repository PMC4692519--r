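#' Synthetic multimodal phantom specification
#'
#' Describes a seeded synthetic cohort: a smooth closed base shape
#' (ellipsoid), per-modality inside/outside/neighbour-band intensities and
#' noise, a thin neighbour band hugging one side of the surface (emulating
#' an adjacent structure such as a white-matter sheet), smooth per-subject
#' boundary deformations drawn from a Gaussian-kernel field over mesh
#' vertices, and the voxel grid. Everything downstream (reference mesh,
#' truth meshes/masks, volumes, CSF mask, priors) derives from this spec,
#' deterministically given the seeds.
#'
#' @param semiaxes ellipsoid semi-axes, mm.
#' @param centre ellipsoid centre, mm.
#' @param subdivisions icosphere subdivision level of the meshes.
#' @param modalities named list; per modality a list with `inside`,
#'   `outside`, `neighbour`, `noise_sd` intensities, optional `beyond`
#'   (intensity past the neighbour band on the band side; defaults to
#'   `inside`, emulating a thin sheet separating two similar tissues) and
#'   optional `type` (modality tag for [image_volume()], default the name).
#' @param band_thickness_mm thickness of the neighbour band.
#' @param band_side unit-ish vector; the band is kept where the outward
#'   direction from the centre has positive dot product with it.
#' @param def_h_mm SD of the per-vertex boundary deformation, mm.
#' @param def_w_edges correlation width of the deformation field, edges.
#' @param grid_dim voxel grid dimensions.
#' @param voxel_mm voxel size, mm.
#' @param config a [mist_config()]; its profile window bounds the
#'   admissible deformation.
#' @return a `phantom_spec`.
#' @export
phantom_spec <- function(semiaxes = c(10, 8, 7), centre = c(0, 0, 0),
                         subdivisions = 2,
                         modalities = list(
                           t1w = list(inside = 100, outside = 60,
                                      neighbour = 135, noise_sd = 8),
                           t2w = list(inside = 80, outside = 110,
                                      neighbour = 50, noise_sd = 6)),
                         band_thickness_mm = 2,
                         band_side = c(1, 0, 0),
                         def_h_mm = 0.9, def_w_edges = 2,
                         grid_dim = c(40, 40, 40), voxel_mm = 1,
                         config = mist_config(k_prime = 12, delta = 12,
                                              spacing_mm = 0.7,
                                              n_components = 2,
                                              delta_prior_sd = 1.2)) {
  stopifnot(all(vapply(modalities, function(m) m$noise_sd >= 0, TRUE)))
  max_def <- config$spacing_mm * config$delta / 2
  structure(list(semiaxes = semiaxes, centre = centre,
                 subdivisions = subdivisions, modalities = modalities,
                 band_thickness_mm = band_thickness_mm,
                 band_side = band_side / sqrt(sum(band_side^2)),
                 def_h_mm = def_h_mm, def_w_edges = def_w_edges,
                 grid_dim = grid_dim, voxel_mm = voxel_mm,
                 max_def_mm = max_def, config = config),
            class = "phantom_spec")
}

phantom_grid <- function(spec) {
  voxel_grid(spec$grid_dim, voxel_mm = spec$voxel_mm,
             origin = spec$centre - spec$voxel_mm * (spec$grid_dim - 1) / 2)
}

phantom_base_mesh <- function(spec) {
  icosphere_mesh(spec$subdivisions, spec$semiaxes, spec$centre)
}

# Cholesky factor of the deformation covariance over mesh vertices
phantom_def_chol <- function(spec, mesh = phantom_base_mesh(spec)) {
  d <- edge_distances(mesh)
  K <- spec$def_h_mm^2 * exp(-d^2 / (2 * spec$def_w_edges^2))
  # the graph-distance kernel need not be positive definite; clip spectrum
  es <- eigen(K, symmetric = TRUE)
  lam <- pmax(es$values, 1e-10 * spec$def_h_mm^2)
  diag(sqrt(lam)) %*% t(es$vectors)
}

#' Generate one phantom subject
#'
#' Draws a smooth boundary-deformation field, deforms the base mesh along
#' its normals to obtain the subject's truth mesh, and builds per-modality
#' volumes (inside / outside / neighbour-band intensities plus i.i.d.
#' Gaussian voxel noise). The reference mesh is the undeformed base mesh,
#' playing the role of the registered atlas mesh. Bit-identical output for
#' identical `(spec, subject_seed)`.
#'
#' @param spec a [phantom_spec()].
#' @param subject_seed integer seed for this subject.
#' @param base optional precomputed list with `mesh`, `normals`, `chol`
#'   (from [phantom_base_mesh()] etc.), to avoid recomputation in cohorts.
#' @param with_mask rasterise the truth mesh to a mask (default TRUE; the
#'   mask is only needed for evaluation subjects).
#' @return list with `volumes` (named [image_volume()] list), `truth_mesh`,
#'   `truth_mask` (or NULL), `reference_mesh`, `csf_mask`, `delta_mm`
#'   (planted per-vertex displacement field).
#' @export
generate_subject <- function(spec, subject_seed, base = NULL,
                             with_mask = TRUE) {
  if (is.null(base)) {
    mesh <- phantom_base_mesh(spec)
    base <- list(mesh = mesh, normals = compute_vertex_normals(mesh),
                 chol = phantom_def_chol(spec, mesh))
  }
  grid <- phantom_grid(spec)
  set.seed(as.integer(subject_seed %% .Machine$integer.max))
  N <- nrow(base$mesh$vertices)
  delta_mm <- as.vector(crossprod(base$chol, stats::rnorm(N)))
  if (max(abs(delta_mm)) >= spec$max_def_mm)
    stop("planted deformation (", signif(max(abs(delta_mm)), 3),
         " mm) exceeds the profile half-window (", spec$max_def_mm, " mm)")
  truth <- deform_mesh(base$mesh, delta_mm, base$normals)
  inside <- voxel_centres_inside(truth, grid)
  truth_normals <- compute_vertex_normals(truth)
  band_outer <- deform_mesh(truth, rep(spec$band_thickness_mm, N),
                            truth_normals)
  in_band <- voxel_centres_inside(band_outer, grid) & !inside
  # keep the band on one side only
  ctr <- to_voxel_coords(matrix(spec$centre, 1), grid$affine)
  nd <- grid$dim
  cx <- array(rep(0:(nd[1] - 1), times = nd[2] * nd[3]), nd)
  cy <- array(rep(rep(0:(nd[2] - 1), each = nd[1]), times = nd[3]), nd)
  cz <- array(rep(0:(nd[3] - 1), each = nd[1] * nd[2]), nd)
  vx <- spec$voxel_mm
  side <- (cx - ctr[1]) * spec$band_side[1] * vx +
    (cy - ctr[2]) * spec$band_side[2] * vx +
    (cz - ctr[3]) * spec$band_side[3] * vx
  in_band <- in_band & (side > 0)
  vols <- list()
  for (mn in names(spec$modalities)) {
    mm <- spec$modalities[[mn]]
    beyond <- if (!is.null(mm$beyond)) mm$beyond else mm$inside
    dat <- array(mm$outside, dim = nd)
    dat[side > 0] <- beyond
    dat[in_band] <- mm$neighbour
    dat[inside] <- mm$inside
    if (mm$noise_sd > 0)
      dat <- dat + array(stats::rnorm(prod(nd), 0, mm$noise_sd), nd)
    type <- if (!is.null(mm$type)) mm$type else mn
    if (!type %in% c("t1w", "t2w", "fa", "qsm", "other")) type <- "other"
    vols[[mn]] <- image_volume(dat, grid$affine, modality = type)
  }
  csf <- array(0, nd)
  csf[2:5, 2:5, 2:5] <- 1  # far-corner stand-in region for CSF exclusion
  list(volumes = vols,
       truth_mesh = truth,
       truth_mask = if (with_mask) rasterise_mesh(truth, grid) else NULL,
       reference_mesh = base$mesh,
       csf_mask = image_volume(csf, grid$affine, modality = "mask"),
       delta_mm = delta_mm)
}

#' Generate a training and held-out phantom cohort
#'
#' Independent subjects from the same spec with disjoint per-subject
#' seeds; deterministic given `(spec, n_train, n_test, seed)`.
#'
#' @param spec a [phantom_spec()].
#' @param n_train,n_test subject counts.
#' @param seed integer master seed.
#' @param train_masks also rasterise truth masks for training subjects
#'   (default FALSE; they are only needed for evaluation).
#' @return list with `train`, `test` (lists of [generate_subject()]
#'   results), `spec`, `base` (shared mesh/normals/deformation factor).
#' @export
generate_cohort <- function(spec, n_train, n_test = 0, seed = 1,
                            train_masks = FALSE) {
  if (n_train < 1) stop("n_train must be at least 1")
  mesh <- phantom_base_mesh(spec)
  base <- list(mesh = mesh, normals = compute_vertex_normals(mesh),
               chol = phantom_def_chol(spec, mesh))
  mk <- function(i, with_mask) generate_subject(spec, seed + 7919L * i,
                                                base = base,
                                                with_mask = with_mask)
  list(train = lapply(seq_len(n_train), mk, with_mask = train_masks),
       test = if (n_test > 0)
         lapply(n_train + seq_len(n_test), mk, with_mask = TRUE) else list(),
       spec = spec, base = base)
}

#' Region masks for rule-based prior setup on phantoms
#'
#' Atlas-style volumetric regions derived from the reference mesh: an
#' eroded interior (`inside`), an exterior shell away from the structure
#' (`outside`), and the neighbour band region (`neighbour`).
#'
#' @param spec a [phantom_spec()].
#' @return named list of [image_volume()] masks on the phantom grid.
#' @export
phantom_region_masks <- function(spec) {
  grid <- phantom_grid(spec)
  mesh <- phantom_base_mesh(spec)
  normals <- compute_vertex_normals(mesh)
  N <- nrow(mesh$vertices)
  inner <- voxel_centres_inside(deform_mesh(mesh, rep(-1.5, N), normals), grid)
  outer1 <- voxel_centres_inside(deform_mesh(mesh, rep(2.5, N), normals), grid)
  outer2 <- voxel_centres_inside(deform_mesh(mesh, rep(5, N), normals), grid)
  band_outer <- deform_mesh(mesh, rep(spec$band_thickness_mm, N), normals)
  in_mesh <- voxel_centres_inside(mesh, grid)
  nd <- grid$dim
  ctr <- to_voxel_coords(matrix(spec$centre, 1), grid$affine)
  cx <- array(rep(0:(nd[1] - 1), times = nd[2] * nd[3]), nd)
  cy <- array(rep(rep(0:(nd[2] - 1), each = nd[1]), times = nd[3]), nd)
  cz <- array(rep(0:(nd[3] - 1), each = nd[1] * nd[2]), nd)
  side <- (cx - ctr[1]) * spec$band_side[1] +
    (cy - ctr[2]) * spec$band_side[2] + (cz - ctr[3]) * spec$band_side[3]
  band <- voxel_centres_inside(band_outer, grid) & !in_mesh & side > 0
  asmask <- function(a) image_volume(array(as.numeric(a), nd), grid$affine,
                                     modality = "mask")
  list(inside = asmask(inner),
       outside = asmask(outer2 & !outer1 & side < 0),
       neighbour = asmask(band))
}

#' Rule-based intensity priors for a phantom cohort
#'
#' Applies the automated setup: pooled median intensities in the region
#' masks across training subjects populate a two-component prior per
#' modality — a step from the inside to the outside intensity, and an
#' exponential edge toward the neighbour-band intensity (decaying back to
#' the inside value, suited to a thin adjacent structure).
#'
#' @param cohort a [generate_cohort()] result.
#' @param train_vols optional list (over training subjects) of named,
#'   already-normalised [image_volume()] lists; the priors must be derived
#'   from intensities on the same scale the model will see. Defaults to
#'   the raw cohort volumes.
#' @param v_mm decay scale of the exponential component, mm.
#' @return named list per modality of [prior_profile_spec()] lists, for
#'   [intensity_prior_set()].
#' @export
phantom_priors <- function(cohort, train_vols = NULL, v_mm = 1.5) {
  spec <- cohort$spec
  masks <- phantom_region_masks(spec)
  nr <- spec$config$n_components
  if (is.null(train_vols))
    train_vols <- lapply(cohort$train, function(s) s$volumes)
  out <- list()
  for (mn in names(spec$modalities)) {
    vols <- lapply(train_vols, function(s) s[[mn]])
    med <- auto_intensity_setup(vols, masks)
    comps <- list(
      prior_profile_spec("step", a = med[["inside"]], b = med[["outside"]]),
      prior_profile_spec("exponential", a = med[["inside"]],
                         b = med[["neighbour"]], v_mm = v_mm))
    if (nr > length(comps))
      comps <- c(comps, replicate(nr - length(comps),
                                  prior_profile_spec("flat",
                                                     a = med[["inside"]]),
                                  simplify = FALSE))
    out[[mn]] <- comps[seq_len(nr)]
  }
  out
}
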