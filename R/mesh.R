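#' Triangle surface mesh
#'
#' Constructs a closed triangle mesh in millimetre coordinates. Vertices are
#' an N x 3 real matrix, faces an M x 3 integer matrix of 1-based vertex
#' indices. Faces must be consistently wound; if the signed volume of the
#' mesh is negative the winding is repaired (all faces flipped) so that
#' computed normals point outward.
#'
#' @param vertices N x 3 numeric matrix, mm.
#' @param faces M x 3 integer matrix of 1-based vertex indices.
#' @param labels optional per-vertex labels (length N).
#' @param repair_winding flip faces automatically if the signed volume is
#'   negative (default TRUE); if FALSE an inverted mesh is an error.
#' @return object of class `triangle_mesh` with elements `vertices`, `faces`,
#'   and optionally `labels`.
#' @export
triangle_mesh <- function(vertices, faces, labels = NULL, repair_winding = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an N x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an M x 3 matrix")
  n <- nrow(vertices)
  if (any(faces < 1L) || any(faces > n))
    stop("face indices out of range [1, ", n, "]")
  if (!all(is.finite(vertices))) stop("vertex coordinates must be finite")
  areas <- face_areas(vertices, faces)
  if (any(areas <= 1e-12))
    stop("degenerate (zero-area) faces at rows: ",
         paste(utils::head(which(areas <= 1e-12), 5), collapse = ", "))
  mesh <- structure(list(vertices = vertices, faces = faces, labels = labels),
                    class = "triangle_mesh")
  sv <- mesh_signed_volume(mesh)
  if (sv < 0) {
    if (!repair_winding)
      stop("mesh has inverted winding (signed volume ", signif(sv, 4), " < 0)")
    mesh$faces <- faces[, c(1L, 3L, 2L), drop = FALSE]
  }
  mesh
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat("triangle_mesh:", nrow(x$vertices), "vertices,", nrow(x$faces), "faces\n")
  cat("  signed volume:", signif(mesh_signed_volume(x), 6), "mm^3\n")
  invisible(x)
}

face_areas <- function(vertices, faces) {
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE]
  c <- vertices[faces[, 3], , drop = FALSE]
  cr <- cross3(b - a, c - a)
  0.5 * sqrt(rowSums(cr^2))
}

cross3 <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

#' Signed volume enclosed by a mesh
#'
#' Sum of signed tetrahedron volumes against the origin; positive for a
#' closed outward-oriented surface.
#' @param mesh a [triangle_mesh()].
#' @return scalar volume in mm^3 (signed).
#' @export
mesh_signed_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c <- v[f[, 3], , drop = FALSE]
  sum(rowSums(a * cross3(b, c))) / 6
}

#' Outward unit vertex normals
#'
#' Area-weighted average of incident face normals, normalised to unit
#' length. Mesh winding is assumed outward (enforced by [triangle_mesh()]).
#'
#' @param mesh a [triangle_mesh()].
#' @return N x 3 matrix of unit normals.
#' @export
compute_vertex_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c <- v[f[, 3], , drop = FALSE]
  fn <- cross3(b - a, c - a)  # magnitude = 2 * face area -> area weighting
  n <- matrix(0, nrow(v), 3)
  for (j in 1:3) {
    rs <- rowsum(fn, group = f[, j])
    at <- as.integer(rownames(rs))
    n[at, ] <- n[at, ] + rs
  }
  len <- sqrt(rowSums(n^2))
  bad <- which(len < 1e-12)
  if (length(bad))
    stop("degenerate vertex normals at vertices: ",
         paste(utils::head(bad, 5), collapse = ", "))
  n / len
}

#' Graph distances (number of edges) between mesh vertices
#'
#' Breadth-first shortest-path distance over the mesh edge graph, used by the
#' shape-covariance kernel. Entries larger than `max_dist` are returned as
#' `Inf` (treated as zero covariance after the Gaussian kernel).
#'
#' @param mesh a [triangle_mesh()].
#' @param max_dist cap on stored distances; default `Inf` keeps all.
#' @return N x N matrix of non-negative integer distances (possibly `Inf`).
#' @export
edge_distances <- function(mesh, max_dist = Inf) {
  g <- mesh_graph(mesh)
  comp <- igraph::components(g)
  if (comp$no > 1L)
    stop("mesh graph is disconnected: ", comp$no, " components with sizes ",
         paste(comp$csize, collapse = ", "))
  d <- igraph::distances(g)
  d[d > max_dist] <- Inf
  unname(d)
}

mesh_graph <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- t(apply(e, 1, sort))
  e <- unique(e)
  igraph::graph_from_edgelist(e, directed = FALSE)
}

mesh_edge_table <- function(mesh) {
  f <- mesh$faces
  rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
}

#' Check that a mesh is watertight (closed, consistently oriented)
#'
#' Every undirected edge must be shared by exactly two faces and each
#' directed edge must appear exactly once.
#' @param mesh a [triangle_mesh()].
#' @return logical scalar.
#' @export
is_watertight <- function(mesh) {
  de <- mesh_edge_table(mesh)
  key <- paste(de[, 1], de[, 2])
  if (any(duplicated(key))) return(FALSE)
  ukey <- paste(pmin(de[, 1], de[, 2]), pmax(de[, 1], de[, 2]))
  all(table(ukey) == 2L)
}

#' Icosphere / ellipsoid reference mesh
#'
#' Generates a closed triangulated ellipsoid by subdividing an icosahedron
#' and projecting onto the unit sphere, then scaling by the semi-axes. Used
#' as the synthetic reference mesh (the atlas-derived mesh of a real study).
#'
#' @param subdivisions number of 4-way subdivision passes (0 = icosahedron,
#'   1 = 42 vertices, 2 = 162 vertices, 3 = 642 vertices).
#' @param semiaxes length-3 semi-axes in mm (scalar recycled).
#' @param centre length-3 centre in mm.
#' @return a [triangle_mesh()].
#' @export
icosphere_mesh <- function(subdivisions = 2, semiaxes = c(10, 10, 10),
                           centre = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    res <- subdivide_tri(v, f)
    v <- res$v / sqrt(rowSums(res$v^2))
    f <- res$f
  }
  semiaxes <- rep_len(semiaxes, 3)
  v <- sweep(v, 2, semiaxes, "*")
  v <- sweep(v, 2, centre, "+")
  triangle_mesh(v, f)
}

subdivide_tri <- function(v, f) {
  midkey <- function(i, j) paste(pmin(i, j), pmax(i, j))
  env <- new.env()
  verts <- v
  getmid <- function(i, j) {
    k <- midkey(i, j)
    id <- env[[k]]
    if (is.null(id)) {
      verts <<- rbind(verts, (v[i, ] + v[j, ]) / 2)
      id <- nrow(verts)
      env[[k]] <- id
    }
    id
  }
  nf <- matrix(0L, nrow(f) * 4, 3)
  for (t in seq_len(nrow(f))) {
    a <- f[t, 1]; b <- f[t, 2]; c <- f[t, 3]
    ab <- getmid(a, b); bc <- getmid(b, c); ca <- getmid(c, a)
    nf[(t - 1) * 4 + 1:4, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                     c(c, ca, bc), c(ab, bc, ca))
  }
  list(v = verts, f = nf)
}

#' Deform a mesh along its vertex normals
#'
#' @param mesh reference [triangle_mesh()].
#' @param displacement_mm length-N displacement (mm) along the outward
#'   vertex normals; positive = outward.
#' @param normals optional precomputed [compute_vertex_normals()] output.
#' @return deformed [triangle_mesh()].
#' @export
deform_mesh <- function(mesh, displacement_mm, normals = NULL) {
  if (is.null(normals)) normals <- compute_vertex_normals(mesh)
  stopifnot(length(displacement_mm) == nrow(mesh$vertices))
  triangle_mesh(mesh$vertices + displacement_mm * normals, mesh$faces,
                labels = mesh$labels)
}
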