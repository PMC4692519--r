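#' Distance from points to a triangulated surface
#'
#' Minimum Euclidean distance from each point to any triangle of the mesh
#' (point-to-triangle, not point-to-vertex).
#'
#' @param points P x 3 matrix, mm.
#' @param mesh a [triangle_mesh()].
#' @return numeric vector of length P, mm.
#' @export
point_to_surface_distance <- function(points, mesh) {
  points <- matrix(points, ncol = 3)
  v <- mesh$vertices; f <- mesh$faces
  best <- rep(Inf, nrow(points))
  for (t in seq_len(nrow(f))) {
    d2 <- point_triangle_d2(points, v[f[t, 1], ], v[f[t, 2], ], v[f[t, 3], ])
    best <- pmin(best, d2)
  }
  sqrt(best)
}

# squared distances from many points to one triangle: interior projection
# where the barycentric solution is admissible, otherwise nearest edge
point_triangle_d2 <- function(P, a, b, c) {
  e0 <- b - a; e1 <- c - a
  aa <- sum(e0 * e0); bb <- sum(e0 * e1); cc <- sum(e1 * e1)
  det <- aa * cc - bb * bb
  w <- sweep(P, 2, a, "-")
  d0 <- w %*% e0; d1 <- w %*% e1
  s <- (cc * d0 - bb * d1) / det
  t <- (aa * d1 - bb * d0) / det
  inside <- s >= 0 & t >= 0 & (s + t) <= 1
  qx <- a[1] + s * e0[1] + t * e1[1]
  qy <- a[2] + s * e0[2] + t * e1[2]
  qz <- a[3] + s * e0[3] + t * e1[3]
  d2in <- (P[, 1] - qx)^2 + (P[, 2] - qy)^2 + (P[, 3] - qz)^2
  d2out <- pmin(point_segment_d2(P, a, b),
                pmin(point_segment_d2(P, a, c), point_segment_d2(P, b, c)))
  ifelse(as.vector(inside), as.vector(d2in), d2out)
}

point_segment_d2 <- function(P, p, q) {
  u <- q - p
  L2 <- sum(u * u)
  w <- sweep(P, 2, p, "-")
  tt <- pmin(1, pmax(0, (w %*% u) / L2))
  (w[, 1] - tt * u[1])^2 + (w[, 2] - tt * u[2])^2 + (w[, 3] - tt * u[3])^2
}

#' Mean distance between two surface meshes
#'
#' Symmetrised mean of point-to-surface distances: vertices of `a` to the
#' surface of `b` and vertices of `b` to the surface of `a`, averaged (each
#' direction weighted equally). With `exclusion_mm` and `other` given,
#' source vertices closer than `exclusion_mm` to the `other` surface are
#' dropped before averaging (used when composite structures share an
#' internal boundary that should not contribute).
#'
#' @param a,b [triangle_mesh()] objects.
#' @param exclusion_mm optional exclusion radius, mm.
#' @param other optional [triangle_mesh()] defining the exclusion surface.
#' @param directed if `"ab"` or `"ba"`, return that directed mean instead of
#'   the symmetrised value (default `"both"`).
#' @return scalar mean distance, mm.
#' @export
mean_mesh_distance <- function(a, b, exclusion_mm = NULL, other = NULL,
                               directed = c("both", "ab", "ba")) {
  directed <- match.arg(directed)
  if (nrow(a$vertices) == 0 || nrow(b$vertices) == 0)
    stop("meshes must be non-empty")
  one_way <- function(src, dst) {
    pts <- src$vertices
    if (!is.null(exclusion_mm) && !is.null(other)) {
      keep <- point_to_surface_distance(pts, other) >= exclusion_mm
      if (!any(keep))
        stop("all source vertices fall within ", exclusion_mm,
             " mm of the exclusion mesh")
      pts <- pts[keep, , drop = FALSE]
    }
    mean(point_to_surface_distance(pts, dst))
  }
  switch(directed,
         ab = one_way(a, b),
         ba = one_way(b, a),
         both = (one_way(a, b) + one_way(b, a)) / 2)
}
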