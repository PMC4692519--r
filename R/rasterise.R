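#' Voxel grid description
#'
#' @param dim length-3 integer grid dimensions (voxels).
#' @param affine 4 x 4 voxel-to-mm affine (0-based voxel indices map to mm
#'   voxel centres). If omitted, built from `voxel_mm` and `origin`.
#' @param voxel_mm isotropic or length-3 voxel size in mm.
#' @param origin mm coordinate of voxel (0,0,0)'s centre.
#' @return object of class `voxel_grid` with `dim` and `affine`.
#' @export
voxel_grid <- function(dim, affine = NULL, voxel_mm = 1, origin = NULL) {
  dim <- as.integer(rep_len(dim, 3))
  if (is.null(affine)) {
    voxel_mm <- rep_len(voxel_mm, 3)
    if (is.null(origin)) origin <- -voxel_mm * (dim - 1) / 2
    affine <- diag(c(voxel_mm, 1))
    affine[1:3, 4] <- origin
  }
  affine <- as.matrix(affine)
  stopifnot(all(dim(affine) == c(4, 4)))
  if (abs(det(affine)) < 1e-12) stop("affine is singular")
  structure(list(dim = dim, affine = affine), class = "voxel_grid")
}

grid_of <- function(x) {
  if (inherits(x, "voxel_grid")) return(x)
  if (inherits(x, "image_volume")) return(voxel_grid(dim(x$data), x$affine))
  stop("cannot interpret as a voxel grid")
}

#' Convert a mesh to a binary voxel mask
#'
#' A voxel is included iff at least one of its eight corner points (at
#' half-voxel offsets from the centre) lies inside the closed surface;
#' corners lying on the surface count as inside. The test is performed in
#' voxel-index space (inside/outside is affine-invariant) by casting rays
#' along the third index axis and counting parity of surface crossings.
#'
#' @param mesh a watertight [triangle_mesh()] in mm coordinates.
#' @param grid a [voxel_grid()] or an [image_volume()] to take the grid from.
#' @return an [image_volume()] with 0/1 data and modality `"mask"`.
#' @export
rasterise_mesh <- function(mesh, grid) {
  grid <- grid_of(grid)
  if (!is_watertight(mesh))
    stop("mesh is not watertight; cannot rasterise an open surface")
  nd <- grid$dim
  vin <- to_voxel_coords(mesh$vertices, grid$affine)
  m <- inside_on_grid(vin, mesh$faces,
                      (0:nd[1]) - 0.5, (0:nd[2]) - 0.5, (0:nd[3]) - 0.5)
  vox <- m[1:nd[1], 1:nd[2], 1:nd[3]] |
    m[2:(nd[1] + 1), 1:nd[2], 1:nd[3]] |
    m[1:nd[1], 2:(nd[2] + 1), 1:nd[3]] |
    m[2:(nd[1] + 1), 2:(nd[2] + 1), 1:nd[3]] |
    m[1:nd[1], 1:nd[2], 2:(nd[3] + 1)] |
    m[2:(nd[1] + 1), 1:nd[2], 2:(nd[3] + 1)] |
    m[1:nd[1], 2:(nd[2] + 1), 2:(nd[3] + 1)] |
    m[2:(nd[1] + 1), 2:(nd[2] + 1), 2:(nd[3] + 1)]
  image_volume(array(as.numeric(vox), dim = nd), grid$affine,
               modality = "mask", normalisation = "none")
}

#' Voxel-centre inside test for a closed mesh
#'
#' Like [rasterise_mesh()] but classifies voxel centres rather than
#' applying the any-corner rule; used for assigning region intensities.
#'
#' @param mesh a watertight [triangle_mesh()].
#' @param grid a [voxel_grid()] or [image_volume()].
#' @return logical 3D array over the grid.
#' @export
voxel_centres_inside <- function(mesh, grid) {
  grid <- grid_of(grid)
  if (!is_watertight(mesh)) stop("mesh is not watertight")
  nd <- grid$dim
  vin <- to_voxel_coords(mesh$vertices, grid$affine)
  inside_on_grid(vin, mesh$faces, 0:(nd[1] - 1), 0:(nd[2] - 1), 0:(nd[3] - 1))
}

to_voxel_coords <- function(points_mm, affine) {
  p <- cbind(points_mm, 1) %*% t(solve(affine))
  p[, 1:3, drop = FALSE]
}

# Inside flags for all points of a rectilinear grid (in voxel coordinates):
# rays are cast along the third axis and surface-crossing parity counted;
# points on the surface (within eps_surf) count as inside.
inside_on_grid <- function(v, faces, cx, cy, cz, eps_surf = 1e-7) {
  ncx <- length(cx); ncy <- length(cy); ncz <- length(cz)
  col_id <- integer(0); col_z <- numeric(0)
  surf_id <- integer(0); surf_zlo <- numeric(0); surf_zhi <- numeric(0)
  A <- v[faces[, 1], , drop = FALSE]
  B <- v[faces[, 2], , drop = FALSE]
  C <- v[faces[, 3], , drop = FALSE]
  acc_z <- vector("list", nrow(faces)); acc_c <- vector("list", nrow(faces))
  seg_cols <- integer(0); seg_lo <- numeric(0); seg_hi <- numeric(0)
  for (t in seq_len(nrow(faces))) {
    a <- A[t, ]; b <- B[t, ]; cc <- C[t, ]
    xr <- range(a[1], b[1], cc[1]); yr <- range(a[2], b[2], cc[2])
    ix <- which(cx >= xr[1] - 1e-9 & cx <= xr[2] + 1e-9)
    iy <- which(cy >= yr[1] - 1e-9 & cy <= yr[2] + 1e-9)
    if (!length(ix) || !length(iy)) next
    px <- rep(cx[ix], times = length(iy))
    py <- rep(cy[iy], each = length(ix))
    denom <- (b[1] - a[1]) * (cc[2] - a[2]) - (b[2] - a[2]) * (cc[1] - a[1])
    cid <- rep(ix, times = length(iy)) +
      (rep(iy, each = length(ix)) - 1L) * ncx
    if (abs(denom) < 1e-9) {
      # projection degenerate (face parallel to the ray): corners lying on
      # the projected segment are on the surface for z within the face range
      d2 <- point_segseg_d2(px, py, a, b, cc)
      on <- which(d2 <= eps_surf^2)
      if (length(on)) {
        seg_cols <- c(seg_cols, cid[on])
        seg_lo <- c(seg_lo, rep(min(a[3], b[3], cc[3]) - eps_surf, length(on)))
        seg_hi <- c(seg_hi, rep(max(a[3], b[3], cc[3]) + eps_surf, length(on)))
      }
      next
    }
    w1 <- ((b[1] - px) * (cc[2] - py) - (b[2] - py) * (cc[1] - px)) / denom
    w2 <- ((cc[1] - px) * (a[2] - py) - (cc[2] - py) * (a[1] - px)) / denom
    w3 <- 1 - w1 - w2
    keep <- w1 >= -1e-12 & w2 >= -1e-12 & w3 >= -1e-12
    if (!any(keep)) next
    zc <- w1[keep] * a[3] + w2[keep] * b[3] + w3[keep] * cc[3]
    acc_z[[t]] <- zc; acc_c[[t]] <- cid[keep]
  }
  col_id <- unlist(acc_c); col_z <- unlist(acc_z)
  inside <- array(FALSE, dim = c(ncx, ncy, ncz))
  odd_cols <- integer(0)
  if (length(col_id)) {
    o <- order(col_id, col_z)
    col_id <- col_id[o]; col_z <- col_z[o]
    starts <- which(!duplicated(col_id))
    ends <- c(starts[-1] - 1L, length(col_id))
    for (s in seq_along(starts)) {
      zc <- col_z[starts[s]:ends[s]]
      if (length(zc) > 1) zc <- zc[c(TRUE, diff(zc) > 1e-9)]  # dedupe edge hits
      cidx <- col_id[starts[s]]
      if (length(zc) %% 2 == 1) {
        # a ray through a watertight surface crosses it an even number of
        # times; an odd count flags a tangential/sliver-projection column —
        # re-classify its corners with the robust generic-ray test below
        odd_cols <- c(odd_cols, cidx)
        next
      }
      n_above <- length(zc) - findInterval(cz + eps_surf, zc)
      on_surf <- (findInterval(cz + eps_surf, zc) -
                  findInterval(cz - eps_surf, zc)) > 0
      flag <- (n_above %% 2 == 1) | on_surf
      if (any(flag)) {
        i <- (cidx - 1L) %% ncx + 1L
        j <- (cidx - 1L) %/% ncx + 1L
        inside[i, j, which(flag)] <- TRUE
      }
    }
  }
  if (length(odd_cols)) {
    vm <- triangle_mesh(v, faces)
    for (cidx in odd_cols) {
      i <- (cidx - 1L) %% ncx + 1L
      j <- (cidx - 1L) %/% ncx + 1L
      pts <- cbind(cx[i], cy[j], cz)
      inside[i, j, ] <- points_in_mesh(vm, pts, eps = eps_surf)
    }
  }
  if (length(seg_cols)) {
    for (s in seq_along(seg_cols)) {
      cidx <- seg_cols[s]
      i <- (cidx - 1L) %% ncx + 1L
      j <- (cidx - 1L) %/% ncx + 1L
      flag <- cz >= seg_lo[s] & cz <= seg_hi[s]
      inside[i, j, which(flag)] <- inside[i, j, which(flag)] | TRUE
    }
  }
  inside
}

# squared 2D distance from points to the triangle's three edges (used when a
# face projects to a segment)
point_segseg_d2 <- function(px, py, a, b, cc) {
  d2 <- pmin(seg_d2(px, py, a, b), seg_d2(px, py, b, cc))
  pmin(d2, seg_d2(px, py, cc, a))
}

seg_d2 <- function(px, py, p, q) {
  ux <- q[1] - p[1]; uy <- q[2] - p[2]
  L2 <- ux^2 + uy^2
  if (L2 < 1e-24) return((px - p[1])^2 + (py - p[2])^2)
  tt <- pmin(1, pmax(0, ((px - p[1]) * ux + (py - p[2]) * uy) / L2))
  (px - p[1] - tt * ux)^2 + (py - p[2] - tt * uy)^2
}

#' Test whether points are inside a closed mesh
#'
#' Ray casting along a fixed generic direction with parity counting; points
#' within `eps` of the surface are reported as inside (ties count as inside).
#'
#' @param mesh a watertight [triangle_mesh()].
#' @param points P x 3 matrix, mm.
#' @param eps surface tolerance in mm.
#' @return logical vector of length P.
#' @export
points_in_mesh <- function(mesh, points, eps = 1e-7) {
  if (!is_watertight(mesh)) stop("mesh is not watertight")
  points <- matrix(points, ncol = 3)
  dirn <- c(0.5313292, 0.3691123, 0.7626953)
  dirn <- dirn / sqrt(sum(dirn^2))
  d_surf <- point_to_surface_distance(points, mesh)
  out <- logical(nrow(points))
  A <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  E1 <- mesh$vertices[mesh$faces[, 2], , drop = FALSE] - A
  E2 <- mesh$vertices[mesh$faces[, 3], , drop = FALSE] - A
  pvec <- cross3(matrix(dirn, nrow(A), 3, byrow = TRUE), E2)
  det <- rowSums(E1 * pvec)
  ok <- abs(det) > 1e-12
  for (p in seq_len(nrow(points))) {
    if (d_surf[p] <= eps) { out[p] <- TRUE; next }
    tv <- sweep(A, 2, points[p, ], "-")
    tvec <- -tv
    u <- rowSums(tvec * pvec) / det
    qvec <- cross3(tvec, E1)
    vv <- (qvec[, 1] * dirn[1] + qvec[, 2] * dirn[2] + qvec[, 3] * dirn[3]) / det
    tt <- rowSums(E2 * qvec) / det
    hit <- ok & u >= 0 & vv >= 0 & (u + vv) <= 1 & tt > eps
    out[p] <- (sum(hit) %% 2) == 1
  }
  out
}
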