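#' Metaphase locating in 10x field images
#'
#' At low magnification, metaphase spreads are "pore-like" clusters of slim
#' chromosomes while nuclei and impurities are "blocky". The locator
#' binarizes the field with Otsu's threshold, suppresses the pore texture by
#' a morphological opening, subtracts the blocky residue from the original
#' binarization, cleans and inflates the remainder, and reads off connected
#' components as metaphase candidates.
#'
#' @name metaphase_locator
NULL

#' Otsu binarization of a field image
#'
#' Thresholds at the gray level maximizing between-class variance; the
#' foreground is the darker (stained) class.
#'
#' @param image A `field_image` (see [render_field_10x()]) or a numeric
#'   matrix in `[0,1]`.
#' @return Binary 0/1 matrix, 1 = foreground (darker than threshold).
#' @export
binarize_otsu <- function(image) {
  m <- if (inherits(image, "field_image")) image$pixels else image
  if (!is.matrix(m)) stop("expected a single-channel image", call. = FALSE)
  if (length(unique(as.vector(m))) < 2)
    stop("degenerate histogram: image has a single gray level",
         call. = FALSE)
  thr <- EBImage::otsu(EBImage::Image(m), range = c(0, 1), levels = 256)
  matrix(as.numeric(m < thr), nrow(m), ncol(m))
}

#' Suppress pore-like texture by morphological opening
#'
#' Opening (erosion then dilation) with a disc removes structures thinner
#' than the disc — the slim chromosome strokes of a metaphase — while
#' retaining blocky nuclei and large impurities.
#'
#' @param mask Binary matrix.
#' @param se_radius Disc radius in pixels (>= 1). The default 4 exceeds half
#'   the stroke width of 10x chromosomes but is far below a nucleus radius.
#' @return Binary matrix of the blocky residue.
#' @export
suppress_pore_texture <- function(mask, se_radius = 4) {
  stopifnot(se_radius >= 1)
  stopifnot_mask(mask)
  bin_open(mask, se_radius)
}

#' Candidate metaphase mask from the binarization and its blocky residue
#'
#' Set-subtracts the suppressed (blocky) mask from the original
#' binarization, closes the remainder with a small disc to drop tiny
#' impurity bits and bridge strokes, then dilates to highlight each
#' metaphase location as one solid region.
#'
#' @param original,suppressed Binary matrices of equal dimensions.
#' @param cleanup_radius Disc radius of the closing step (0 disables).
#' @param highlight_radius Disc radius of the final dilation (0 disables).
#' @return Binary candidate mask.
#' @export
candidate_mask <- function(original, suppressed, cleanup_radius = 2,
                           highlight_radius = 6) {
  if (!all(dim(original) == dim(suppressed)))
    stop("dimension mismatch between masks", call. = FALSE)
  out <- matrix(as.numeric(original > 0 & !(suppressed > 0)),
                nrow(original), ncol(original))
  if (cleanup_radius >= 1) out <- bin_close(out, cleanup_radius)
  if (highlight_radius >= 1) out <- bin_dilate(out, highlight_radius)
  out
}

#' Locate metaphase candidates in a 10x field image
#'
#' Composition binarize -> suppress -> candidate mask -> connected
#' components; components below `min_area` are dropped as debris.
#'
#' @param image A `field_image` or numeric matrix in `[0,1]`.
#' @param se_radius,cleanup_radius,highlight_radius See
#'   [suppress_pore_texture()] and [candidate_mask()].
#' @param min_area Minimum candidate area in pixels at 10x (after the
#'   highlight dilation; calibrated so dilated debris specks stay below it).
#' @param subtract_dilate Dilation (px) applied to the blocky residue
#'   before subtraction, so the thin boundary rings of nuclei do not
#'   survive as spurious candidates.
#' @param min_contrast Minimum spread between the 1% and 99% intensity
#'   quantiles; below it the field is treated as empty (Otsu on a
#'   noise-only histogram would otherwise split the noise in half).
#' @return Data frame with 0-based centroid `row`, `col`, `area_px`, and the
#'   0-based half-open bounding box `r0`, `c0`, `r1`, `c1`; one row per
#'   candidate.
#' @export
locate_metaphases <- function(image, se_radius = 4, cleanup_radius = 2,
                              highlight_radius = 6, min_area = 600,
                              subtract_dilate = 2, min_contrast = 0.2) {
  m <- if (inherits(image, "field_image")) image$pixels else image
  q <- stats::quantile(m, c(0.01, 0.99))
  empty <- data.frame(row = numeric(0), col = numeric(0),
                      area_px = integer(0), r0 = integer(0),
                      c0 = integer(0), r1 = integer(0), c1 = integer(0))
  if (diff(q) < min_contrast) return(empty)
  bin <- binarize_otsu(image)
  sup <- suppress_pore_texture(bin, se_radius)
  if (subtract_dilate >= 1) sup <- bin_dilate(sup, subtract_dilate)
  cand <- candidate_mask(bin, sup, cleanup_radius, highlight_radius)
  lab <- label_components(cand)
  out <- empty
  if (max(lab) == 0) return(out)
  for (k in seq_len(max(lab))) {
    idx <- which(lab == k, arr.ind = TRUE)
    if (nrow(idx) < min_area) next
    out <- rbind(out, data.frame(
      row = mean(idx[, 1]) - 1, col = mean(idx[, 2]) - 1,
      area_px = nrow(idx),
      r0 = min(idx[, 1]) - 1L, c0 = min(idx[, 2]) - 1L,
      r1 = max(idx[, 1]), c1 = max(idx[, 2])))
  }
  out
}

#' Screen a metaphase spread by object count
#'
#' A usable spread must contain 46 +/- 3 objects; adherent clusters and
#' acentric fragments justify the tolerance. Accepts iff
#' `43 <= object_count <= 49`.
#'
#' @param object_count Number of individual chromosomes counted after triage
#'   and mass splitting.
#' @param expected Nominal chromosome number (46 for human).
#' @param tolerance Accepted deviation (3).
#' @return Logical.
#' @export
screen_spread <- function(object_count, expected = 46L, tolerance = 3L) {
  stopifnot(object_count >= 0)
  object_count >= expected - tolerance & object_count <= expected + tolerance
}
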