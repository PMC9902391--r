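#' Rule-based triage and adhesive-mass segmentation
#'
#' Every detected object is categorized from two morphological features:
#' WH, the pixel length of the short side of its minimum-area enclosing
#' rectangle, and IH, the number of enclosed background holes in its mask.
#' IH is 0 for ordinary chromosomes, 1 for dicentrics, 2 for tricentrics,
#' and can gain one per crossed pair of long arms, so it stays at most 3 for
#' any real chromosome. Objects with `WH < 25` or `IH > 3` are impurities;
#' objects with `WH > 65` are adhesive chromosome masses to be split by
#' seed-filtered watershed; the rest are individual chromosomes.
#'
#' @name triage_segmentation
NULL

#' Triage rule thresholds
#'
#' @param wh_min,wh_max Width band for an individual chromosome (25-65 px).
#' @param ih_max Maximal internal-hole count of a real chromosome (3).
#' @return A `triage_rule` list.
#' @export
triage_rule <- function(wh_min = 25, wh_max = 65, ih_max = 3) {
  stopifnot(wh_min < wh_max, ih_max >= 0)
  structure(list(wh_min = wh_min, wh_max = wh_max, ih_max = ih_max),
            class = "triage_rule")
}

#' Watershed segmenter configuration
#'
#' @param min_seed_area Seed regions smaller than this (150 px) are
#'   discarded before flooding, preventing over-segmentation.
#' @param seed_fraction Seeds are the pixels of each tentative region whose
#'   distance-map value reaches this fraction of the region's maximum.
#' @param tolerance Depth tolerance (px) merging shallow distance-map
#'   maxima: catchment regions whose peak rises less than this above the
#'   saddle to a neighbour are merged. Calibrated above the depth of a
#'   centromeric constriction (so one chromosome stays whole) and below the
#'   saddle depth of a shallow inter-chromosome junction.
#' @return A `segmenter_config` list.
#' @export
segmenter_config <- function(min_seed_area = 150, seed_fraction = 0.5,
                             tolerance = 6) {
  stopifnot(min_seed_area >= 1)
  structure(list(min_seed_area = min_seed_area,
                 seed_fraction = seed_fraction, tolerance = tolerance),
            class = "segmenter_config")
}

#' Width of a mask: short side of the minimum-area enclosing rectangle
#'
#' Chromosomes lie at arbitrary angles, so width is measured on the
#' min-area rectangle: convex hull of the foreground pixel centres, then
#' the rectangle aligned with each hull edge (rotating calipers); the
#' minimum-area one is kept and its short side (+1 px for pixel extent)
#' rounded to the nearest integer.
#'
#' @param mask Binary matrix (non-empty).
#' @return Integer WH in pixels.
#' @export
measure_width <- function(mask) {
  stopifnot_mask(mask, allow_empty = FALSE)
  idx <- which(mask > 0, arr.ind = TRUE)
  pts <- cbind(idx[, 2], idx[, 1])  # x = col, y = row
  if (nrow(pts) == 1) return(1L)
  hull <- unique(pts[grDevices::chull(pts), , drop = FALSE])
  if (nrow(hull) == 1) return(1L)
  if (nrow(hull) == 2) {
    # collinear pixels: width is one pixel
    return(1L)
  }
  n <- nrow(hull)
  best_area <- Inf; best_short <- NA_real_
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    e <- hull[j, ] - hull[i, ]
    len <- sqrt(sum(e^2))
    if (len < 1e-9) next
    u <- e / len; v <- c(-u[2], u[1])
    pu <- hull %*% u; pv <- hull %*% v
    w1 <- max(pu) - min(pu) + 1
    w2 <- max(pv) - min(pv) + 1
    if (w1 * w2 < best_area) {
      best_area <- w1 * w2
      best_short <- min(w1, w2)
    }
  }
  as.integer(round(best_short))
}

#' Count enclosed internal holes of a mask
#'
#' IH is the number of background connected components fully enclosed by
#' the foreground: after 1-px background padding, background pixels
#' (4-connected) not reachable from the border are holes, counted as
#' 4-connected components. Foreground is treated 8-connected, consistent
#' with the component labelling used at extraction.
#'
#' @param mask Binary matrix (non-empty).
#' @return Integer hole count.
#' @export
count_holes <- function(mask) {
  stopifnot_mask(mask, allow_empty = FALSE)
  pad <- matrix(FALSE, nrow(mask) + 2, ncol(mask) + 2)
  pad[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- mask > 0
  bg <- !pad
  border <- matrix(FALSE, nrow(pad), ncol(pad))
  border[1, ] <- border[nrow(pad), ] <- TRUE
  border[, 1] <- border[, ncol(pad)] <- TRUE
  reach <- flood_reach4(border & bg, bg)
  holes <- bg & !reach
  if (!any(holes)) return(0L)
  max(label_components4(holes))
}

#' Triage an object by its WH and IH features
#'
#' @param WH Width in pixels (>= 1).
#' @param IH Internal-hole count (>= 0).
#' @param rule A [triage_rule()].
#' @return `"impurity"` if `WH < wh_min` or `IH > ih_max`; `"mass"` if
#'   `WH > wh_max`; `"individual"` otherwise. Boundaries are inclusive for
#'   the individual class (WH = 25 and IH = 3 are individual).
#' @export
triage <- function(WH, IH, rule = triage_rule()) {
  stopifnot(all(WH >= 1), all(IH >= 0))
  ifelse(WH < rule$wh_min | IH > rule$ih_max, "impurity",
         ifelse(WH > rule$wh_max, "mass", "individual"))
}

#' Compute WH/IH and categorize a detected object
#'
#' @param object A `detected_object` from [extract_objects()].
#' @param rule A [triage_rule()].
#' @return The object with `WH`, `IH` and `category` filled in.
#' @export
triage_object <- function(object, rule = triage_rule()) {
  object$WH <- measure_width(object$mask_crop)
  object$IH <- count_holes(object$mask_crop)
  object$category <- triage(object$WH, object$IH, rule)
  object
}

#' Split an adhesive chromosome mass by seed-filtered watershed
#'
#' Marker-controlled watershed on the Euclidean distance map of the mask.
#' Tentative catchment regions come from the distance-map maxima
#' (watershed with depth tolerance); each region's seed is its core — the
#' pixels reaching `seed_fraction` of the region's distance maximum — and
#' seeds smaller than `min_seed_area` (150 px) are discarded so tiny spurious
#' maxima cannot over-segment. Surviving seeds flood the mask by seeded
#' region growing; every mask pixel is assigned to exactly one segment, so
#' the output partitions the input (disjoint, area-conserving). With at
#' most one surviving seed the mass is returned unsplit.
#'
#' @param object A `detected_object` with `category == "mass"`, or a binary
#'   mask matrix.
#' @param config A [segmenter_config()].
#' @return List of `detected_object`s (segments), coordinates relative to
#'   the parent crop; a single-element list when unsplittable.
#' @export
segment_mass <- function(object, config = segmenter_config()) {
  mask <- if (inherits(object, "detected_object")) object$mask_crop
          else object
  stopifnot_mask(mask, allow_empty = FALSE)
  img_crop <- if (inherits(object, "detected_object")) object$image_crop
              else NULL

  dist <- EBImage::distmap(mask)
  ws <- EBImage::watershed(dist, tolerance = config$tolerance, ext = 1)
  wsd <- matrix(as.integer(round(EBImage::imageData(ws))),
                nrow(mask), ncol(mask))
  dmat <- matrix(as.numeric(EBImage::imageData(dist)),
                 nrow(mask), ncol(mask))

  seeds <- matrix(0L, nrow(mask), ncol(mask))
  nseed <- 0L
  if (max(wsd) >= 1) for (k in seq_len(max(wsd))) {
    region <- wsd == k
    if (!any(region)) next
    core <- region & dmat >= config$seed_fraction * max(dmat[region])
    if (sum(core) < config$min_seed_area) next
    nseed <- nseed + 1L
    seeds[core] <- nseed
  }
  if (nseed <= 1L) {
    out <- if (inherits(object, "detected_object")) object else
      structure(list(mask_crop = mask, image_crop = NULL,
                     bbox = c(0L, 0L, nrow(mask), ncol(mask)),
                     centroid = NULL, area_px = as.integer(sum(mask)),
                     WH = NA_integer_, IH = NA_integer_,
                     category = NA_character_), class = "detected_object")
    return(list(out))
  }

  lab <- EBImage::propagate(EBImage::Image(max(dmat) - dmat),
                            seeds = seeds, mask = mask > 0, lambda = 100)
  lab <- matrix(as.integer(round(EBImage::imageData(lab))),
                nrow(mask), ncol(mask))
  lapply(seq_len(nseed), function(k) {
    comp <- lab == k
    bb <- mask_bbox(comp)
    mc <- matrix(as.numeric(comp[bb$r0:bb$r1, bb$c0:bb$c1]),
                 bb$r1 - bb$r0 + 1, bb$c1 - bb$c0 + 1)
    ic <- NULL
    if (!is.null(img_crop)) {
      ic <- array(.syn$background, c(nrow(mc), ncol(mc), 3))
      for (ch in 1:3)
        ic[, , ch] <- ifelse(mc > 0,
                             img_crop[bb$r0:bb$r1, bb$c0:bb$c1, ch],
                             .syn$background)
    }
    idx <- which(comp, arr.ind = TRUE)
    structure(list(mask_crop = mc, image_crop = ic,
                   bbox = c(bb$r0 - 1L, bb$c0 - 1L, bb$r1, bb$c1),
                   centroid = c(mean(idx[, 1]), mean(idx[, 2])) - 1,
                   area_px = as.integer(sum(mc)),
                   WH = NA_integer_, IH = NA_integer_,
                   category = NA_character_),
              class = "detected_object")
  })
}

#' Triage all objects with one round of mass re-segmentation
#'
#' Applies [triage_object()] to every extracted object; masses are split by
#' [segment_mass()] and the segments re-enter triage once (recursion depth
#' capped at 2 so termination is guaranteed). Impurities are kept with their
#' discard category for audit.
#'
#' @param objects List of `detected_object`s.
#' @param rule A [triage_rule()].
#' @param config A [segmenter_config()].
#' @return List of triaged `detected_object`s; segments carry
#'   `parent_mass_id` (index of the mass they came from).
#' @export
triage_objects <- function(objects, rule = triage_rule(),
                           config = segmenter_config()) {
  out <- list()
  for (i in seq_along(objects)) {
    ob <- triage_object(objects[[i]], rule)
    if (!identical(ob$category, "mass")) {
      out[[length(out) + 1]] <- ob
      next
    }
    segs <- segment_mass(ob, config)
    if (length(segs) == 1L) {
      # unsplittable; keep as mass so downstream can flag it
      out[[length(out) + 1]] <- ob
      next
    }
    for (sg in segs) {
      sg <- triage_object(sg, rule)
      sg$parent_mass_id <- i
      out[[length(out) + 1]] <- sg
    }
  }
  out
}
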