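#' Chromosome extraction from 100x metaphase images
#'
#' Produces a clean chromosome foreground mask from a high-magnification RGB
#' metaphase image — k-means (k = 2) binarization on luminance, subtraction
#' of the morphological opening to remove nuclei and blocky contaminants,
#' median filtering — and cuts out one object crop per connected component.
#'
#' @name chromosome_extractor
NULL

.luminance <- function(pixels) {
  (pixels[, , 1] + pixels[, , 2] + pixels[, , 3]) / 3
}

#' k-means (k = 2) binarization
#'
#' Clusters pixel luminance into two groups (Lloyd iterations initialized at
#' the minimum and maximum observed intensity, hence deterministic) and
#' takes the darker cluster as foreground. In one dimension the k = 2
#' optimum is a threshold partition, so this adapts the cut to each image's
#' stain/illumination.
#'
#' @param image A `metaphase_image` (see [render_metaphase()]) or an RGB
#'   array `[H,W,3]` in `[0,1]`.
#' @param seed Unused by the deterministic initialization; kept so callers
#'   can thread one seed through the pipeline.
#' @return Binary 0/1 matrix, 1 = chromosome-stained (darker) cluster.
#' @export
kmeans_binarize <- function(image, seed = 1) {
  px <- if (inherits(image, "metaphase_image")) image$pixels else image
  lum <- if (length(dim(px)) == 3) .luminance(px) else px
  v <- as.vector(lum)
  if (diff(range(v)) < 1e-12)
    stop("degenerate clustering: image has a single intensity",
         call. = FALSE)
  km <- suppressWarnings(
    stats::kmeans(v, centers = matrix(c(min(v), max(v))),
                  iter.max = 100, algorithm = "Lloyd"))
  dark <- which.min(km$centers)
  matrix(as.numeric(km$cluster == dark), nrow(lum), ncol(lum))
}

#' Remove nuclei and blocky contaminants from a binary mask
#'
#' Computes `mask \ opening(mask, disc(se_radius))`: the opening keeps only
#' structures wide enough to contain the disc — nuclei and large blobs —
#' and subtracting it restores the slim chromosomes while deleting the
#' blobs.
#'
#' @param mask Binary matrix.
#' @param se_radius Disc radius in pixels (>= 1). The default 40 exceeds
#'   half the maximal chromosome width (65 px) so whole chromosome bodies
#'   pass through, yet is far below the radius of a 100x nucleus.
#' @return Binary matrix.
#' @export
suppress_nuclei <- function(mask, se_radius = 40) {
  stopifnot(se_radius >= 1)
  stopifnot_mask(mask)
  op <- bin_open(mask, se_radius)
  matrix(as.numeric(mask > 0 & !(op > 0)), nrow(mask), ncol(mask))
}

#' Median-filter a binary mask
#'
#' Majority vote in a `kernel x kernel` window; removes isolated noise
#' pixels and minor impurities.
#'
#' @param mask Binary matrix.
#' @param kernel Odd window size >= 3.
#' @return Binary matrix.
#' @export
clean_mask <- function(mask, kernel = 3) {
  if (kernel %% 2 != 1 || kernel < 3)
    stop("kernel must be odd and >= 3", call. = FALSE)
  stopifnot_mask(mask)
  out <- EBImage::medianFilter(EBImage::Image(mask), (kernel - 1) / 2)
  as_mask(out)
}

#' Extract per-object crops from a metaphase image
#'
#' 8-connected component labelling of the final mask; one detected object
#' per component with its tight bounding box, binary mask crop, centroid and
#' an RGB crop of the original pixels with background filled to the corpus
#' background colour (the classifier consumes RGB tiles).
#'
#' @param image A `metaphase_image` or RGB array.
#' @param mask Binary matrix aligned with `image`.
#' @param background Fill value for non-object pixels inside the bbox.
#' @return List of `detected_object`s: `mask_crop`, `image_crop`,
#'   `bbox` (0-based half-open `c(r0, c0, r1, c1)`), `centroid` (0-based),
#'   `area_px`, and `WH`/`IH`/`category` left unset until triage.
#' @export
extract_objects <- function(image, mask, background = .syn$background) {
  px <- if (inherits(image, "metaphase_image")) image$pixels else image
  if (!all(dim(px)[1:2] == dim(mask)))
    stop("mask not aligned with image", call. = FALSE)
  lab <- label_components(mask)
  if (max(lab) == 0) return(list())
  lapply(seq_len(max(lab)), function(k) {
    comp <- lab == k
    bb <- mask_bbox(comp)
    mc <- matrix(as.numeric(comp[bb$r0:bb$r1, bb$c0:bb$c1]),
                 bb$r1 - bb$r0 + 1, bb$c1 - bb$c0 + 1)
    ic <- array(background, c(nrow(mc), ncol(mc), 3))
    for (ch in 1:3) {
      sl <- px[bb$r0:bb$r1, bb$c0:bb$c1, ch]
      ic[, , ch] <- ifelse(mc > 0, sl, background)
    }
    idx <- which(comp, arr.ind = TRUE)
    structure(list(
      mask_crop = mc, image_crop = ic,
      bbox = c(bb$r0 - 1L, bb$c0 - 1L, bb$r1, bb$c1),
      centroid = c(mean(idx[, 1]), mean(idx[, 2])) - 1,
      area_px = as.integer(sum(mc)),
      WH = NA_integer_, IH = NA_integer_, category = NA_character_),
      class = "detected_object")
  })
}

#' Full extraction mask pipeline
#'
#' `clean_mask(suppress_nuclei(kmeans_binarize(image)))` with defaults; the
#' result is a subset of the initial binarization.
#'
#' @inheritParams kmeans_binarize
#' @param se_radius,kernel See [suppress_nuclei()] and [clean_mask()].
#' @return Binary matrix.
#' @export
extraction_mask <- function(image, se_radius = 40, kernel = 3, seed = 1) {
  b <- kmeans_binarize(image, seed = seed)
  s <- suppress_nuclei(b, se_radius = se_radius)
  m <- clean_mask(s, kernel = kernel)
  # median filter can round outward at concavities; clip to the binarization
  matrix(as.numeric(m > 0 & b > 0), nrow(b), ncol(b))
}
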