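#' Read a triangle mesh from a VTK legacy ASCII polydata file
#'
#' Supports `POINTS` + `POLYGONS` sections with triangular cells, the format
#' used for surface meshes throughout this package.
#'
#' @param path file path.
#' @return a [triangle_mesh()].
#' @export
read_vtk_mesh <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 5 || !grepl("^# vtk DataFile", lines[1]))
    stop("not a VTK legacy file: ", path)
  if (!any(grepl("^ASCII", lines, ignore.case = TRUE)))
    stop("only ASCII VTK legacy files are supported")
  ip <- grep("^POINTS", lines)
  if (!length(ip)) stop("no POINTS section in ", path)
  np <- as.integer(strsplit(trimws(lines[ip[1]]), "\\s+")[[1]][2])
  toks <- scan_tokens(lines, ip[1] + 1, 3L * np)
  vertices <- matrix(as.numeric(toks), ncol = 3, byrow = TRUE)
  ic <- grep("^POLYGONS", lines)
  if (!length(ic)) stop("no POLYGONS section in ", path)
  hdr <- as.integer(strsplit(trimws(lines[ic[1]]), "\\s+")[[1]][2:3])
  ctoks <- as.integer(scan_tokens(lines, ic[1] + 1, hdr[2]))
  faces <- matrix(NA_integer_, hdr[1], 3)
  pos <- 1L
  for (i in seq_len(hdr[1])) {
    nv <- ctoks[pos]
    if (nv != 3L) stop("non-triangular polygon (", nv, " vertices) at cell ", i)
    faces[i, ] <- ctoks[(pos + 1L):(pos + 3L)] + 1L  # VTK is 0-based
    pos <- pos + nv + 1L
  }
  triangle_mesh(vertices, faces)
}

scan_tokens <- function(lines, start, n) {
  out <- character(0)
  i <- start
  while (length(out) < n && i <= length(lines)) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    out <- c(out, tok[nzchar(tok)])
    i <- i + 1
  }
  if (length(out) < n) stop("truncated VTK section")
  out[seq_len(n)]
}

#' Write a triangle mesh as VTK legacy ASCII polydata
#'
#' @param mesh a [triangle_mesh()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vtk_mesh <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "triangle mesh", "ASCII", "DATASET POLYDATA",
               sprintf("POINTS %d float", nrow(v))), con)
  writeLines(apply(format(v, trim = TRUE, digits = 9), 1, paste, collapse = " "),
             con)
  writeLines(sprintf("POLYGONS %d %d", nrow(f), 4L * nrow(f)), con)
  writeLines(paste(3L, f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  invisible(path)
}
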