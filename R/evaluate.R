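#' Dice overlap coefficient of two binary masks
#'
#' @param a,b [image_volume()] masks (non-zero = foreground) on the same
#'   grid, or plain arrays of matching dimensions.
#' @return `2|A n B| / (|A| + |B|)` in `[0, 1]`.
#' @export
dice <- function(a, b) {
  av <- if (inherits(a, "image_volume")) a$data else a
  bv <- if (inherits(b, "image_volume")) b$data else b
  if (!all(dim(av) == dim(bv))) stop("mask grids do not match")
  if (inherits(a, "image_volume") && inherits(b, "image_volume") &&
      max(abs(a$affine - b$affine)) > 1e-6)
    stop("mask affines do not match")
  na <- sum(av != 0); nb <- sum(bv != 0)
  if (na + nb == 0) stop("both masks are empty")
  2 * sum(av != 0 & bv != 0) / (na + nb)
}

#' Volume of a binary mask in mm^3
#'
#' Voxel count times voxel volume (from the affine determinant).
#' @param mask an [image_volume()] mask.
#' @return scalar mm^3.
#' @export
mask_volume <- function(mask) {
  sum(mask$data != 0) * abs(det(mask$affine[1:3, 1:3]))
}

#' Pearson correlation of automatic vs reference volumes
#'
#' @param vols_auto,vols_ref paired per-subject volumes, mm^3 (>= 3 pairs).
#' @return list with `r` and two-sided `p`.
#' @export
volume_correlation <- function(vols_auto, vols_ref) {
  if (length(vols_auto) != length(vols_ref)) stop("unpaired volume vectors")
  if (length(vols_auto) < 3) stop("at least 3 paired volumes required")
  if (stats::sd(vols_auto) == 0 || stats::sd(vols_ref) == 0)
    stop("zero variance in a volume vector")
  ct <- stats::cor.test(vols_auto, vols_ref)
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Williams's test for two dependent correlations sharing a variable
#'
#' Tests `r(x1, y) == r(x2, y)` where both correlations share the
#' reference `y` (e.g. two methods' volumes against manual volumes), using
#' the Williams/Steiger t approximation with `n - 3` degrees of freedom.
#'
#' @param r1 correlation of method 1 with the shared reference.
#' @param r2 correlation of method 2 with the shared reference.
#' @param r12 correlation between the two methods.
#' @param n number of subjects.
#' @return list with `t`, `df`, `p` (two-sided).
#' @export
williams_test <- function(r1, r2, r12, n) {
  if (n < 4) stop("n must be at least 4")
  detR <- 1 - r1^2 - r2^2 - r12^2 + 2 * r1 * r2 * r12
  rbar <- (r1 + r2) / 2
  tstat <- (r1 - r2) * sqrt((n - 1) * (1 + r12) /
    (2 * ((n - 1) / (n - 3)) * detR + rbar^2 * (1 - r12)^3))
  df <- n - 3
  list(t = tstat, df = df, p = 2 * stats::pt(-abs(tstat), df))
}

#' Compare segmentation methods across a cohort
#'
#' For each per-subject metric (e.g. Dice, mean mesh distance) a paired
#' two-sided Wilcoxon signed-rank test between each method and the first
#' (reference) method; for volumes, Williams's test on the dependent
#' correlations with the manual volumes. A method compared with itself
#' (all differences zero) is reported with p = 1.
#'
#' @param metrics named list of data frames; each data frame has one row
#'   per subject and one column per method.
#' @param volumes optional data frame of per-subject volumes per method.
#' @param ref_volumes optional manual (reference) volumes per subject.
#' @return data frame with columns `metric`, `method`, `estimate`
#'   (median metric or correlation), `p`.
#' @export
compare_methods <- function(metrics, volumes = NULL, ref_volumes = NULL) {
  rows <- list()
  for (mn in names(metrics)) {
    df <- metrics[[mn]]
    base <- df[[1]]
    for (meth in names(df)) {
      x <- df[[meth]]
      if (length(x) != length(base)) stop("unmatched subject sets")
      if (meth == names(df)[1] || all(x == base)) {
        p <- 1
      } else {
        p <- stats::wilcox.test(x, base, paired = TRUE, exact = FALSE)$p.value
      }
      rows[[length(rows) + 1]] <-
        data.frame(metric = mn, method = meth,
                   estimate = stats::median(x), p = p)
    }
  }
  if (!is.null(volumes) && !is.null(ref_volumes)) {
    base_r <- stats::cor(volumes[[1]], ref_volumes)
    for (meth in names(volumes)) {
      r <- stats::cor(volumes[[meth]], ref_volumes)
      if (meth == names(volumes)[1]) {
        p <- 1
      } else {
        r12 <- stats::cor(volumes[[meth]], volumes[[1]])
        p <- williams_test(r, base_r, r12, length(ref_volumes))$p
      }
      rows[[length(rows) + 1]] <-
        data.frame(metric = "volume_correlation", method = meth,
                   estimate = r, p = p)
    }
  }
  do.call(rbind, rows)
}
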