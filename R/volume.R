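#' Scalar image volume
#'
#' 3D scalar array with a voxel-to-mm affine and a modality tag. The
#' modality determines the default intensity-normalisation mode:
#' multiplicative for relaxation-weighted contrasts (`t1w`, `t2w`, `other`),
#' additive for `qsm` (which is zero-referenced and signed), and none for
#' `fa` (already on an absolute 0-1 scale).
#'
#' @param data 3D numeric array.
#' @param affine 4 x 4 voxel-to-mm affine (0-based indices to mm).
#' @param modality one of `"t1w"`, `"t2w"`, `"fa"`, `"qsm"`, `"mask"`,
#'   `"other"`.
#' @param normalisation `"multiplicative"`, `"additive"` or `"none"`;
#'   defaults from the modality.
#' @return object of class `image_volume`.
#' @export
image_volume <- function(data, affine,
                         modality = c("other", "t1w", "t2w", "fa", "qsm", "mask"),
                         normalisation = NULL) {
  modality <- match.arg(modality)
  data <- as.array(data)
  if (length(dim(data)) != 3) stop("data must be a 3D array")
  affine <- as.matrix(affine)
  stopifnot(all(dim(affine) == c(4, 4)))
  if (abs(det(affine)) < 1e-12) stop("affine is singular")
  if (!all(is.finite(data))) stop("volume contains non-finite values")
  if (is.null(normalisation))
    normalisation <- switch(modality, qsm = "additive",
                            fa = "none", mask = "none", "multiplicative")
  normalisation <- match.arg(normalisation,
                             c("multiplicative", "additive", "none"))
  if (modality == "fa" && (min(data) < -1e-6 || max(data) > 1.2))
    stop("FA volume outside the sanity range [0, 1.2]")
  structure(list(data = data, affine = affine, modality = modality,
                 normalisation = normalisation),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat("image_volume:", paste(dim(x$data), collapse = " x "),
      "voxels;", x$modality, "/", x$normalisation, "\n")
  invisible(x)
}

#' Read a NIfTI volume
#'
#' @param path NIfTI-1 file (.nii or .nii.gz).
#' @param modality modality tag passed to [image_volume()].
#' @return an [image_volume()].
#' @export
read_volume <- function(path, modality = "other") {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  image_volume(array(as.numeric(img), dim = dim(img)[1:3]),
               unclass(aff), modality = modality)
}

#' Write an [image_volume()] as NIfTI-1
#'
#' @param vol an [image_volume()].
#' @param path output path (.nii or .nii.gz).
#' @param datatype NIfTI datatype; masks default to `uint8`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, datatype = NULL) {
  if (is.null(datatype))
    datatype <- if (vol$modality == "mask") "uint8" else "float"
  img <- RNifti::asNifti(vol$data)
  img <- RNifti::`sform<-`(img, structure(vol$affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Normalise volume intensities over a bounding box
#'
#' Scales (multiplicative mode) or shifts (additive mode, used for
#' zero-referenced QSM) a volume so that its mean intensity over the
#' bounding box, excluding CSF voxels, equals `target_mean`. FA volumes
#' (`normalisation == "none"`) are returned unchanged.
#'
#' @param vol an [image_volume()].
#' @param bbox 2 x 3 matrix of 1-based inclusive voxel index ranges
#'   (rows = lower/upper), or `NULL` for the whole volume.
#' @param csf_mask optional [image_volume()] mask (non-zero = CSF) on the
#'   same grid; CSF voxels are excluded from the mean.
#' @param target_mean target mean intensity.
#' @return normalised [image_volume()].
#' @export
normalise_volume <- function(vol, bbox = NULL, csf_mask = NULL,
                             target_mean = 100) {
  if (vol$normalisation == "none") return(vol)
  nd <- dim(vol$data)
  if (is.null(bbox)) bbox <- rbind(c(1, 1, 1), nd)
  bbox <- as.matrix(bbox)
  sel <- vol$data[bbox[1, 1]:bbox[2, 1], bbox[1, 2]:bbox[2, 2],
                  bbox[1, 3]:bbox[2, 3], drop = FALSE]
  if (!is.null(csf_mask)) {
    if (!all(dim(csf_mask$data) == nd))
      stop("CSF mask grid does not match the volume")
    m <- csf_mask$data[bbox[1, 1]:bbox[2, 1], bbox[1, 2]:bbox[2, 2],
                       bbox[1, 3]:bbox[2, 3], drop = FALSE]
    sel <- sel[m == 0]
    if (!length(sel)) stop("bounding box is empty after CSF exclusion")
  }
  mu <- mean(sel)
  out <- vol
  if (vol$normalisation == "multiplicative") {
    if (mu <= 0)
      stop("non-positive mean intensity (", signif(mu, 4),
           ") in multiplicative normalisation")
    out$data <- vol$data * (target_mean / mu)
  } else {
    out$data <- vol$data + (target_mean - mu)
  }
  out
}
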