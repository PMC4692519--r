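#' Sample an intensity profile along a line
#'
#' Trilinear interpolation of the volume at `n` equidistant points along a
#' unit direction, centred on `origin` (sample `j` sits at
#' `origin + (j - centre) * spacing * direction` for 0-based `j`, with
#' `centre = (n - 1) / 2 + centre_offset`). Samples outside the volume's
#' field of view are returned as `NA` and flagged, not an error.
#'
#' @param vol an [image_volume()].
#' @param origin length-3 mm point.
#' @param direction length-3 unit vector (checked to 1e-6).
#' @param spacing sample spacing, mm.
#' @param n number of samples.
#' @param centre_offset shift of the profile centre, in samples.
#' @return list with `values` (length `n`, `NA` where out of FOV) and
#'   `valid` (logical).
#' @export
sample_profile <- function(vol, origin, direction, spacing, n,
                           centre_offset = 0) {
  if (abs(sqrt(sum(direction^2)) - 1) > 1e-6)
    stop("direction must be a unit vector")
  if (spacing <= 0) stop("spacing must be positive")
  j <- 0:(n - 1)
  centre <- (n - 1) / 2 + centre_offset
  pts <- outer(j - centre, direction * spacing) +
    matrix(origin, n, 3, byrow = TRUE)
  vals <- interp_trilinear(vol, pts)
  list(values = vals, valid = !is.na(vals))
}

interp_trilinear <- function(vol, points_mm) {
  p <- to_voxel_coords(points_mm, vol$affine)
  nd <- dim(vol$data)
  # clamp the exact upper-edge case into the last cell
  for (d in 1:3) p[, d] <- ifelse(abs(p[, d] - (nd[d] - 1)) < 1e-9,
                                  nd[d] - 1 - 1e-9, p[, d])
  i0 <- floor(p)
  fr <- p - i0
  ok <- i0[, 1] >= 0 & i0[, 2] >= 0 & i0[, 3] >= 0 &
    i0[, 1] <= nd[1] - 2 & i0[, 2] <= nd[2] - 2 & i0[, 3] <= nd[3] - 2
  out <- rep(NA_real_, nrow(p))
  if (any(ok)) {
    i <- i0[ok, 1] + 1L; jj <- i0[ok, 2] + 1L; kk <- i0[ok, 3] + 1L
    fx <- fr[ok, 1]; fy <- fr[ok, 2]; fz <- fr[ok, 3]
    v <- vol$data
    idx <- function(a, b, c) v[cbind(a, b, c)]
    out[ok] <-
      idx(i, jj, kk) * (1 - fx) * (1 - fy) * (1 - fz) +
      idx(i + 1L, jj, kk) * fx * (1 - fy) * (1 - fz) +
      idx(i, jj + 1L, kk) * (1 - fx) * fy * (1 - fz) +
      idx(i + 1L, jj + 1L, kk) * fx * fy * (1 - fz) +
      idx(i, jj, kk + 1L) * (1 - fx) * (1 - fy) * fz +
      idx(i + 1L, jj, kk + 1L) * fx * (1 - fy) * fz +
      idx(i, jj + 1L, kk + 1L) * (1 - fx) * fy * fz +
      idx(i + 1L, jj + 1L, kk + 1L) * fx * fy * fz
  }
  out
}

#' Extract observed intensity profiles for a cohort
#'
#' Samples, for every subject, modality and mesh vertex, the observed
#' profile of `k_prime` points centred on the reference-mesh vertex along
#' the outward vertex normal (increasing sample index = outward). Volumes
#' must already be co-registered and normalised. A subject-vertex pair with
#' any out-of-FOV sample in any modality is flagged invalid and excluded
#' from training.
#'
#' @param vols list over subjects; each element a named list of
#'   [image_volume()] per modality. All subjects must share modality names.
#' @param mesh reference [triangle_mesh()].
#' @param normals [compute_vertex_normals()] output for `mesh`.
#' @param config a [mist_config()].
#' @return a `profile_set`: list with `profiles` (S x Nm x N x k_prime
#'   array), `valid` (S x N logical), `modalities`, and the profile
#'   geometry (`spacing_mm`, `k_prime`, `delta`, `k`).
#' @export
extract_profiles <- function(vols, mesh, normals, config) {
  modalities <- names(vols[[1]])
  if (is.null(modalities)) stop("per-subject volumes must be a named list")
  for (s in seq_along(vols)) {
    missing <- setdiff(modalities, names(vols[[s]]))
    if (length(missing))
      stop("subject ", s, " is missing modalities: ",
           paste(missing, collapse = ", "))
  }
  S <- length(vols); Nm <- length(modalities); N <- nrow(mesh$vertices)
  kp <- config$k_prime
  profiles <- array(NA_real_, dim = c(S, Nm, N, kp))
  valid <- matrix(TRUE, S, N)
  for (s in seq_len(S)) {
    for (m in seq_len(Nm)) {
      vol <- vols[[s]][[modalities[m]]]
      for (i in seq_len(N)) {
        pr <- sample_profile(vol, mesh$vertices[i, ], normals[i, ],
                             config$spacing_mm, kp)
        profiles[s, m, i, ] <- pr$values
        if (!all(pr$valid)) valid[s, i] <- FALSE
      }
    }
  }
  structure(list(profiles = profiles, valid = valid, modalities = modalities,
                 spacing_mm = config$spacing_mm, k_prime = kp,
                 delta = config$delta, k = config$k),
            class = "profile_set")
}
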