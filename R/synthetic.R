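#' Synthetic Giemsa-stained microscopy generator
#'
#' Renders seeded synthetic 10x field images and 100x metaphase images with
#' per-object ground truth, emulating Giemsa contrast: dark elongated
#' chromosome bodies (25-65 px wide at 100x) on a light background, dicentric
#' chromosomes carrying one enclosed internal hole between their two
#' centromeric constrictions, tricentrics two, nuclei as large compact blobs
#' and debris as small specks. All randomness is drawn from one seeded
#' generator per call; equal seeds give pixel-identical output.
#'
#' @name synthetic_microscopy
NULL

# Intensity / geometry defaults for the synthetic corpus (Giemsa-like).
.syn <- list(
  background = 230 / 255,
  body_rgb = c(0.30, 0.23, 0.40),
  nucleus_rgb = c(0.45, 0.35, 0.55),
  noise_sd = 8 / 255,
  chrom_width_range = c(25, 65),
  chrom_width_default = c(28, 55),  # sampling range for spreads
  chrom_length_default = c(90, 160)
)

#' Construct a chromosome specification
#'
#' Builds the geometric specification of a single chromosome: a smooth
#' backbone polyline, a per-vertex half-width profile with tapered telomeric
#' ends and a constriction (pinch) at every centromere, and for polycentric
#' chromosomes the inter-centromeric gap that renders as an enclosed
#' background hole (the IH feature). A monocentric renders with 0 holes,
#' a dicentric with exactly 1, a tricentric with exactly 2.
#'
#' @param kind One of `"monocentric"`, `"dicentric"`, `"tricentric"`.
#' @param length_px Backbone arc length in pixels.
#' @param width_px Nominal full body width in pixels; must lie in
#'   `width_range` (default 25-65, the triage band for individual
#'   chromosomes).
#' @param curvature Total bend angle of the backbone in radians. Keep small
#'   (default 0.15) if measured width must track `width_px` closely.
#' @param seed Integer seed; all random jitter derives from it.
#' @param width_range Permitted width interval.
#' @return An object of class `chromosome_spec`.
#' @export
make_chromosome <- function(kind = c("monocentric", "dicentric", "tricentric"),
                            length_px = 120, width_px = 40, curvature = 0.15,
                            seed = 1,
                            width_range = c(25, 65)) {
  kind <- match.arg(kind)
  if (width_px < width_range[1] || width_px > width_range[2])
    stop("width_px ", width_px, " outside permitted range [",
         width_range[1], ", ", width_range[2], "]", call. = FALSE)
  if (length_px <= 0) stop("length_px must be positive", call. = FALSE)
  with_local_seed(seed, {
    n <- 17L
    t <- seq(0, 1, length.out = n)
    theta <- curvature * (t - 0.5) + cumsum(rnorm(n, 0, 0.004))
    step <- length_px / (n - 1)
    xs <- c(0, cumsum(cos(theta[-n]) * step))
    ys <- c(0, cumsum(sin(theta[-n]) * step))
    backbone <- cbind(xs - mean(xs), ys - mean(ys))

    centromeres <- switch(kind,
      monocentric = 0.5 + runif(1, -0.08, 0.08),
      dicentric = sort(c(runif(1, 0.22, 0.38),
                         runif(1, 0.62, 0.78))),
      tricentric = sort(c(0.20 + runif(1, -0.03, 0.03),
                          0.50 + runif(1, -0.03, 0.03),
                          0.80 + runif(1, -0.03, 0.03))))

    prof <- 1 - 0.45 * exp(-(t / 0.07)^2) - 0.45 * exp(-((1 - t) / 0.07)^2)
    # constriction kept shallow so the distance-map ridge of one chromosome
    # has no deep saddle at the centromere (watershed must not split it)
    for (cc in centromeres)
      prof <- prof * (1 - 0.20 * exp(-((t - cc) / 0.05)^2))
    halfw <- (width_px / 2) * prof

    structure(list(kind = kind, length_px = length_px, width_px = width_px,
                   curvature = curvature, backbone = backbone,
                   width_profile = halfw,
                   centromere_positions = centromeres, seed = seed),
              class = "chromosome_spec")
  })
}

# Distance field of a polyline tube: for every pixel of a grid return the
# minimal distance d to the backbone, the arc-length s of the nearest point,
# and the locally interpolated half-width. Vectorized over pixels, looped
# over the (few) backbone segments.
.tube_field <- function(backbone, halfw, px, py) {
  n <- nrow(backbone)
  seglen <- sqrt(rowSums((backbone[-1, , drop = FALSE] -
                          backbone[-n, , drop = FALSE])^2))
  s0 <- c(0, cumsum(seglen))
  best_d <- rep(Inf, length(px))
  best_s <- numeric(length(px))
  best_h <- numeric(length(px))
  for (i in seq_len(n - 1)) {
    ax <- backbone[i, 1]; ay <- backbone[i, 2]
    bx <- backbone[i + 1, 1]; by <- backbone[i + 1, 2]
    L2 <- max((bx - ax)^2 + (by - ay)^2, 1e-9)
    tt <- pmin(1, pmax(0, ((px - ax) * (bx - ax) + (py - ay) * (by - ay)) / L2))
    dx <- px - (ax + tt * (bx - ax)); dy <- py - (ay + tt * (by - ay))
    d <- sqrt(dx * dx + dy * dy)
    upd <- d < best_d
    best_d[upd] <- d[upd]
    best_s[upd] <- s0[i] + tt[upd] * seglen[i]
    best_h[upd] <- halfw[i] + tt[upd] * (halfw[i + 1] - halfw[i])
  }
  list(d = best_d, s = best_s, h = best_h, total = s0[n])
}

#' Render a chromosome specification to a binary mask
#'
#' Rasterizes the tube around the backbone and carves the inter-centromeric
#' hole(s) so the internal-hole count equals centromere count minus one.
#' The hole is an ellipse in (arc-length, transverse-distance) coordinates
#' with area at least 30 px, strictly inside the body so it stays enclosed.
#'
#' @param spec A `chromosome_spec`.
#' @param rotation Rotation angle (radians) applied to the backbone.
#' @param margin Background margin around the tight body, in pixels.
#' @return A list with `mask` (0/1 matrix) and `shade` (matrix in `[0,1]`,
#'   relative staining density used by the compositors).
#' @export
render_chromosome_mask <- function(spec, rotation = 0, margin = 4) {
  bb <- spec$backbone
  if (rotation != 0) {
    R <- matrix(c(cos(rotation), sin(rotation),
                  -sin(rotation), cos(rotation)), 2, 2)
    bb <- bb %*% R
  }
  hw <- spec$width_profile
  x0 <- floor(min(bb[, 1]) - max(hw) - margin)
  x1 <- ceiling(max(bb[, 1]) + max(hw) + margin)
  y0 <- floor(min(bb[, 2]) - max(hw) - margin)
  y1 <- ceiling(max(bb[, 2]) + max(hw) + margin)
  # rows index y, cols index x
  xs <- seq(x0, x1); ys <- seq(y0, y1)
  px <- rep(xs, each = length(ys))
  py <- rep(ys, times = length(xs))
  fld <- .tube_field(bb, hw, px, py)
  fg <- fld$d <= fld$h
  # holes are carved between consecutive anchors: the centromeres for
  # polycentric chromosomes, or explicit anchors (weakly split chromatids)
  cents <- spec$hole_anchors
  if (is.null(cents)) cents <- spec$centromere_positions
  b_factor <- spec$hole_b
  if (is.null(b_factor)) b_factor <- 0.45
  if (length(cents) >= 2) {
    for (i in seq_len(length(cents) - 1)) {
      s1 <- cents[i] * fld$total; s2 <- cents[i + 1] * fld$total
      mid <- (s1 + s2) / 2
      a <- 0.75 * (s2 - s1) / 2
      b <- b_factor * (spec$width_px / 2)
      if (pi * a * b < 30) a <- min(30 / (pi * b), 0.9 * (s2 - s1) / 2)
      hole <- ((fld$s - mid) / a)^2 + (fld$d / b)^2 <= 1
      fg <- fg & !hole
    }
  }
  mask <- matrix(as.numeric(fg), length(ys), length(xs))
  # staining density: darker toward the medial axis
  dens <- 1 - 0.5 * pmin(1, (fld$d / pmax(fld$h, 1e-6)))^2
  shade <- matrix(dens, length(ys), length(xs)) * mask
  list(mask = mask, shade = shade)
}

# Filled-ellipse mask on its own tight grid.
.ellipse_mask <- function(ra, rb, rotation = 0, margin = 2) {
  r <- ceiling(max(ra, rb)) + margin
  ys <- seq(-r, r); xs <- seq(-r, r)
  g <- expand.grid(y = ys, x = xs)
  ca <- cos(rotation); sa <- sin(rotation)
  u <- g$x * ca + g$y * sa
  v <- -g$x * sa + g$y * ca
  matrix(as.numeric((u / ra)^2 + (v / rb)^2 <= 1), length(ys), length(xs))
}

# Try to place `mask` on a canvas-sized composite. Returns top-left (r, c)
# 1-based or NULL. `want_overlap`: mask must intersect existing foreground
# (but by less than 40% of its own area); otherwise it must be disjoint.
.place_mask <- function(composite, mask, centre_r, centre_c, spread_r,
                        want_overlap, tries = 600, gap = 2) {
  H <- nrow(composite); W <- ncol(composite)
  # disjoint objects keep a small clearance so they never 8-connect
  test_mask <- if (!want_overlap && gap > 0) bin_dilate(mask, gap) else mask
  mh <- nrow(test_mask); mw <- ncol(test_mask)
  area <- sum(test_mask)
  for (k in seq_len(tries)) {
    ang <- runif(1, 0, 2 * pi)
    rad <- spread_r * sqrt(runif(1))
    cr <- round(centre_r + rad * sin(ang) - mh / 2)
    cc <- round(centre_c + rad * cos(ang) - mw / 2)
    if (cr < 1 || cc < 1 || cr + mh - 1 > H || cc + mw - 1 > W) next
    inter <- sum(composite[cr:(cr + mh - 1), cc:(cc + mw - 1)] * test_mask)
    ok <- if (want_overlap) inter > 0 && inter < 0.4 * area else inter == 0
    if (ok) return(c(cr, cc))
  }
  NULL
}

#' Render a synthetic 100x metaphase spread
#'
#' Places `n_chromosomes` rendered chromosomes (a seeded mixture of
#' monocentrics and, with probability `dic_fraction`, dicentrics) on a light
#' canvas; a fraction `overlap_fraction` of them is deliberately placed so
#' their masks intersect, forming adhesive chromosome masses. Optional nuclei
#' and debris emulate the contaminants seen around real spreads. Ground truth
#' records every individual mask even inside masses.
#'
#' @param n_chromosomes Number of chromosomes (>= 1); 46 emulates a normal
#'   human spread.
#' @param dic_fraction Per-chromosome probability of being dicentric.
#' @param overlap_fraction Fraction of chromosomes placed overlapping.
#' @param seed Integer seed.
#' @param n_nuclei,n_debris Contaminant counts.
#' @param canvas Canvas side length in pixels.
#' @param tri_fraction Per-chromosome probability of being tricentric.
#' @return List with `image` (class `metaphase_image`: `pixels`
#'   `[H,W,3]` in `[0,1]`, `magnification = "100x"`) and `truth`
#'   (class `ground_truth`): per-object kind, label
#'   (`DIC`/`non-DIC`/`impurity`/`mass-member`), bbox (0-based, half-open),
#'   centroid, mask crop + offset, plus per-kind `counts` and a full-canvas
#'   `label_mask`.
#' @export
render_metaphase <- function(n_chromosomes = 46, dic_fraction = 0,
                             overlap_fraction = 0, seed = 1,
                             n_nuclei = 0, n_debris = 0, canvas = 1200,
                             tri_fraction = 0) {
  stopifnot(n_chromosomes >= 1)
  with_local_seed(seed, {
    H <- W <- as.integer(canvas)
    composite <- matrix(0, H, W)
    labmask <- matrix(0L, H, W)
    objects <- list()
    spread_r <- canvas * 0.42

    # contaminants go down first, toward the periphery, so the spread
    # itself always fits
    contaminants <- list()
    if (n_nuclei > 0) for (j in seq_len(n_nuclei)) {
      em <- .ellipse_mask(runif(1, 70, 100), runif(1, 55, 85),
                          runif(1, 0, pi))
      pos <- .place_mask(composite, em, H / 2, W / 2, canvas * 0.46,
                         want_overlap = FALSE)
      if (is.null(pos)) next
      rr <- pos[1]:(pos[1] + nrow(em) - 1)
      cc <- pos[2]:(pos[2] + ncol(em) - 1)
      composite[rr, cc] <- composite[rr, cc] + em
      contaminants[[length(contaminants) + 1]] <-
        list(kind = "nucleus", mask = em, offset = pos)
    }
    if (n_debris > 0) for (j in seq_len(n_debris)) {
      em <- .ellipse_mask(runif(1, 2, 6), runif(1, 2, 6))
      pos <- .place_mask(composite, em, H / 2, W / 2, canvas * 0.46,
                         want_overlap = FALSE)
      if (is.null(pos)) next
      rr <- pos[1]:(pos[1] + nrow(em) - 1)
      cc <- pos[2]:(pos[2] + ncol(em) - 1)
      composite[rr, cc] <- composite[rr, cc] + em
      contaminants[[length(contaminants) + 1]] <-
        list(kind = "debris", mask = em, offset = pos)
    }

    u <- runif(n_chromosomes)
    kinds <- ifelse(u < dic_fraction, "dicentric",
                    ifelse(u < dic_fraction + tri_fraction,
                           "tricentric", "monocentric"))
    n_over <- round(overlap_fraction * n_chromosomes)
    overlap_ix <- if (n_over > 0)
      sample(seq_len(n_chromosomes)[-1], min(n_over, n_chromosomes - 1))
    else integer(0)

    specs <- lapply(seq_len(n_chromosomes), function(i)
      make_chromosome(kinds[i],
                      length_px = runif(1, .syn$chrom_length_default[1],
                                        .syn$chrom_length_default[2]),
                      width_px = runif(1, .syn$chrom_width_default[1],
                                       .syn$chrom_width_default[2]),
                      curvature = runif(1, 0.05, 0.25),
                      seed = sample.int(1e6, 1)))

    for (i in seq_len(n_chromosomes)) {
      rc <- render_chromosome_mask(specs[[i]], rotation = runif(1, 0, pi))
      pos <- .place_mask(composite, rc$mask, H / 2, W / 2, spread_r,
                         want_overlap = i %in% overlap_ix)
      if (is.null(pos))
        stop("placement error: canvas too small for requested object count",
             call. = FALSE)
      rr <- pos[1]:(pos[1] + nrow(rc$mask) - 1)
      cc <- pos[2]:(pos[2] + ncol(rc$mask) - 1)
      composite[rr, cc] <- composite[rr, cc] + rc$mask
      sel <- labmask[rr, cc] == 0L & rc$mask > 0
      labmask[rr, cc][sel] <- i
      objects[[i]] <- list(kind = kinds[i], spec = specs[[i]],
                           mask = rc$mask, shade = rc$shade,
                           offset = c(pos[1], pos[2]))
    }

    # labels: DIC iff dicentric; chromosomes inside adhesive masses that are
    # not dicentric are mass-members; contaminants are impurities
    overlaps <- rep(FALSE, n_chromosomes)
    for (i in seq_len(n_chromosomes)) {
      o <- objects[[i]]
      rr <- o$offset[1]:(o$offset[1] + nrow(o$mask) - 1)
      cc <- o$offset[2]:(o$offset[2] + ncol(o$mask) - 1)
      overlaps[i] <- any(composite[rr, cc][o$mask > 0] > 1)
    }

    pix <- array(0, c(H, W, 3))
    noise <- matrix(rnorm(H * W, 0, .syn$noise_sd), H, W)
    for (ch in 1:3) pix[, , ch] <- .syn$background + noise
    count <- matrix(0, H, W)
    shade_acc <- matrix(0, H, W)
    for (o in c(objects, contaminants)) {
      rr <- o$offset[1]:(o$offset[1] + nrow(o$mask) - 1)
      cc <- o$offset[2]:(o$offset[2] + ncol(o$mask) - 1)
      count[rr, cc] <- count[rr, cc] + o$mask
      sh <- if (!is.null(o$shade)) o$shade else o$mask
      shade_acc[rr, cc] <- pmax(shade_acc[rr, cc], sh)
    }
    body <- count > 0
    depth <- pmin(count - 1, 2) * 0.06
    for (ch in 1:3) {
      base <- ifelse(body, NA, pix[, , ch])
      tint <- matrix(0, H, W)
      for (o in c(objects, contaminants)) {
        rr <- o$offset[1]:(o$offset[1] + nrow(o$mask) - 1)
        cc <- o$offset[2]:(o$offset[2] + ncol(o$mask) - 1)
        col <- if (identical(o$kind, "nucleus")) .syn$nucleus_rgb[ch]
               else .syn$body_rgb[ch]
        tint[rr, cc][o$mask > 0] <- col
      }
      val <- tint + (1 - shade_acc) * 0.25 - depth +
        matrix(rnorm(H * W, 0, .syn$noise_sd), H, W)
      pix[, , ch] <- ifelse(body, val, base)
    }
    pix <- quantize8(pix)

    truth_objects <- lapply(seq_len(n_chromosomes), function(i) {
      o <- objects[[i]]
      bb <- mask_bbox(o$mask)
      r0 <- o$offset[1] + bb$r0 - 1; c0 <- o$offset[2] + bb$c0 - 1
      r1 <- o$offset[1] + bb$r1 - 1; c1 <- o$offset[2] + bb$c1 - 1
      idx <- which(o$mask > 0, arr.ind = TRUE)
      centroid <- c(mean(idx[, 1]) + o$offset[1] - 1,
                    mean(idx[, 2]) + o$offset[2] - 1) - 1  # 0-based
      label <- if (o$kind == "dicentric") "DIC"
               else if (overlaps[i]) "mass-member" else "non-DIC"
      list(kind = o$kind, label = label,
           bbox = c(r0 - 1, c0 - 1, r1, c1),  # 0-based half-open
           centroid = centroid,
           mask = o$mask[bb$r0:bb$r1, bb$c0:bb$c1, drop = FALSE],
           offset = c(r0, c0))
    })
    truth_cont <- lapply(contaminants, function(o) {
      bb <- mask_bbox(o$mask)
      r0 <- o$offset[1] + bb$r0 - 1; c0 <- o$offset[2] + bb$c0 - 1
      list(kind = o$kind, label = "impurity",
           bbox = c(r0 - 1, c0 - 1,
                    o$offset[1] + bb$r1 - 1, o$offset[2] + bb$c1 - 1),
           centroid = NULL,
           mask = o$mask[bb$r0:bb$r1, bb$c0:bb$c1, drop = FALSE],
           offset = c(r0, c0))
    })
    all_obj <- c(truth_objects, truth_cont)
    counts <- table(vapply(all_obj, `[[`, "", "kind"))

    img <- structure(list(pixels = pix, magnification = "100x"),
                     class = "metaphase_image")
    truth <- structure(list(objects = all_obj,
                            counts = as.list(counts),
                            label_mask = labmask,
                            n_dic = sum(kinds == "dicentric")),
                       class = "ground_truth")
    list(image = img, truth = truth)
  })
}

#' Render a synthetic 10x field image
#'
#' At low magnification metaphase spreads appear as "pore-like" clusters of
#' slim strokes while nuclei and impurities are compact "blocky" objects;
#' this contrast is what the locating algorithm exploits. Renders
#' `n_metaphases` stroke clusters, `n_nuclei` filled ellipses and
#' `n_debris` specks on a light background.
#'
#' @param n_metaphases,n_nuclei,n_debris Object counts (>= 0).
#' @param seed Integer seed.
#' @param canvas Canvas side length in pixels.
#' @return List with `image` (class `field_image`: grayscale `pixels`,
#'   `magnification = "10x"`) and `truth` (`metaphase_centroids` as a matrix
#'   of 0-based (row, col) centres, plus per-kind counts).
#' @export
render_field_10x <- function(n_metaphases = 3, n_nuclei = 5, n_debris = 10,
                             seed = 1, canvas = 700) {
  stopifnot(n_metaphases >= 0, n_nuclei >= 0, n_debris >= 0)
  with_local_seed(seed, {
    H <- W <- as.integer(canvas)
    composite <- matrix(0, H, W)
    centroids <- NULL

    render_cluster <- function() {
      R <- runif(1, 32, 45)
      side <- 2 * ceiling(R) + 10
      m <- matrix(0, side, side)
      ctr <- side / 2
      n_str <- round(runif(1, 40, 55))
      for (s in seq_len(n_str)) {
        ang <- runif(1, 0, 2 * pi); rad <- R * sqrt(runif(1)) * 0.92
        cx <- ctr + rad * cos(ang); cy <- ctr + rad * sin(ang)
        len <- runif(1, 8, 16); dir <- runif(1, 0, pi)
        hw <- runif(1, 1.0, 1.6)
        bb <- rbind(c(cx - len / 2 * cos(dir), cy - len / 2 * sin(dir)),
                    c(cx + len / 2 * cos(dir), cy + len / 2 * sin(dir)))
        g <- expand.grid(y = seq_len(side), x = seq_len(side))
        fld <- .tube_field(bb, c(hw, hw), g$x, g$y)
        m <- pmax(m, matrix(as.numeric(fld$d <= fld$h), side, side))
      }
      m
    }

    place_obj <- function(mask) {
      pos <- .place_mask(composite, mask, H / 2, W / 2, canvas * 0.44,
                         want_overlap = FALSE)
      if (is.null(pos))
        stop("placement error: field canvas too crowded", call. = FALSE)
      pos
    }

    objs <- list()
    if (n_metaphases > 0) for (i in seq_len(n_metaphases)) {
      m <- render_cluster()
      pos <- place_obj(m)
      composite[pos[1]:(pos[1] + nrow(m) - 1),
                pos[2]:(pos[2] + ncol(m) - 1)] <- pmax(
        composite[pos[1]:(pos[1] + nrow(m) - 1),
                  pos[2]:(pos[2] + ncol(m) - 1)], m)
      idx <- which(m > 0, arr.ind = TRUE)
      centroids <- rbind(centroids,
                         c(mean(idx[, 1]) + pos[1] - 1,
                           mean(idx[, 2]) + pos[2] - 1) - 1)
      objs[[length(objs) + 1]] <- list(kind = "metaphase", mask = m,
                                       offset = pos)
    }
    if (n_nuclei > 0) for (i in seq_len(n_nuclei)) {
      m <- .ellipse_mask(runif(1, 14, 26), runif(1, 12, 22), runif(1, 0, pi))
      pos <- place_obj(m)
      composite[pos[1]:(pos[1] + nrow(m) - 1),
                pos[2]:(pos[2] + ncol(m) - 1)] <- pmax(
        composite[pos[1]:(pos[1] + nrow(m) - 1),
                  pos[2]:(pos[2] + ncol(m) - 1)], m)
      objs[[length(objs) + 1]] <- list(kind = "nucleus", mask = m,
                                       offset = pos)
    }
    if (n_debris > 0) for (i in seq_len(n_debris)) {
      m <- .ellipse_mask(runif(1, 1, 3), runif(1, 1, 3))
      pos <- place_obj(m)
      composite[pos[1]:(pos[1] + nrow(m) - 1),
                pos[2]:(pos[2] + ncol(m) - 1)] <- pmax(
        composite[pos[1]:(pos[1] + nrow(m) - 1),
                  pos[2]:(pos[2] + ncol(m) - 1)], m)
      objs[[length(objs) + 1]] <- list(kind = "debris", mask = m,
                                       offset = pos)
    }

    pix <- 0.90 + matrix(rnorm(H * W, 0, .syn$noise_sd), H, W)
    pix[composite > 0] <- 0.25 +
      rnorm(sum(composite > 0), 0, .syn$noise_sd)
    pix <- quantize8(pix)

    img <- structure(list(pixels = pix, magnification = "10x"),
                     class = "field_image")
    truth <- structure(list(metaphase_centroids = centroids,
                            objects = objs,
                            counts = list(metaphase = n_metaphases,
                                          nucleus = n_nuclei,
                                          debris = n_debris)),
                       class = "ground_truth")
    list(image = img, truth = truth)
  })
}

#' Render one labelled chromosome tile
#'
#' Produces a single normalized 151x151 RGB tile of one of the object types
#' the classifier meets after extraction and triage: an ordinary monocentric,
#' a dicentric (`label = "DIC"`), a strongly bent monocentric, or the hard
#' negative the cascade exists for — two long-armed chromosomes entangled so
#' their union encloses a hole without either being dicentric.
#'
#' @param type One of `"monocentric"`, `"dicentric"`, `"bent"`,
#'   `"entangled"`, `"weak_split"` (a monocentric whose sister chromatids
#'   have partially separated, enclosing sliver holes on both sides of the
#'   centromere — hole-bearing yet non-DIC, the classic false positive).
#' @param seed Integer seed.
#' @return A `chromosome_tile` (see [normalize_tile()]) with its `label` set.
#' @export
render_tile <- function(type = c("monocentric", "dicentric", "bent",
                                 "entangled", "weak_split"), seed = 1) {
  type <- match.arg(type)
  with_local_seed(seed, {
    crop <- if (type == "weak_split") {
      spec <- make_chromosome("monocentric",
                              length_px = runif(1, 100, 160),
                              width_px = runif(1, 30, 55),
                              curvature = runif(1, 0.05, 0.3),
                              seed = sample.int(1e6, 1))
      spec$hole_anchors <- c(runif(1, 0.10, 0.16), 0.5,
                             runif(1, 0.84, 0.90))
      spec$hole_b <- runif(1, 0.25, 0.35)
      render_chromosome_mask(spec, rotation = runif(1, 0, pi))
    } else if (type == "entangled") {
      s1 <- make_chromosome("monocentric",
                            length_px = runif(1, 120, 160),
                            width_px = runif(1, 26, 40),
                            curvature = runif(1, 0.6, 1.2),
                            seed = sample.int(1e6, 1))
      s2 <- make_chromosome("monocentric",
                            length_px = runif(1, 120, 160),
                            width_px = runif(1, 26, 40),
                            curvature = runif(1, 0.6, 1.2),
                            seed = sample.int(1e6, 1))
      r1 <- render_chromosome_mask(s1, rotation = runif(1, 0, pi))
      r2 <- render_chromosome_mask(s2, rotation = runif(1, 0, pi))
      h <- max(nrow(r1$mask), nrow(r2$mask)) + 20
      w <- max(ncol(r1$mask), ncol(r2$mask)) + 20
      mask <- matrix(0, h, w); shade <- matrix(0, h, w)
      put <- function(rm, dr, dc) {
        rr <- dr:(dr + nrow(rm$mask) - 1); cc <- dc:(dc + ncol(rm$mask) - 1)
        mask[rr, cc] <<- pmax(mask[rr, cc], rm$mask)
        shade[rr, cc] <<- pmax(shade[rr, cc], rm$shade)
      }
      put(r1, floor((h - nrow(r1$mask)) / 2) + sample(-4:4, 1),
          floor((w - ncol(r1$mask)) / 2) + sample(-4:4, 1))
      put(r2, floor((h - nrow(r2$mask)) / 2) + sample(-4:4, 1),
          floor((w - ncol(r2$mask)) / 2) + sample(-4:4, 1))
      list(mask = mask, shade = shade)
    } else {
      kind <- if (type == "dicentric") "dicentric" else "monocentric"
      curv <- if (type == "bent") runif(1, 0.8, 1.5) else runif(1, 0.05, 0.3)
      spec <- make_chromosome(kind,
                              length_px = runif(1, 90, 160),
                              width_px = runif(1, 28, 55),
                              curvature = curv,
                              seed = sample.int(1e6, 1))
      render_chromosome_mask(spec, rotation = runif(1, 0, pi))
    }
    h <- nrow(crop$mask); w <- ncol(crop$mask)
    rgb <- array(0, c(h, w, 3))
    # per-tile stain and illumination jitter (slides vary)
    body_shift <- runif(1, -0.08, 0.10)
    bg_shift <- runif(1, -0.03, 0.03)
    nsd <- runif(1, 1, 1.8) * .syn$noise_sd
    noise <- matrix(rnorm(h * w, 0, nsd), h, w)
    for (ch in 1:3) {
      bgv <- .syn$background + bg_shift + noise
      fgv <- .syn$body_rgb[ch] + body_shift + (1 - crop$shade) * 0.25 +
        matrix(rnorm(h * w, 0, nsd), h, w)
      rgb[, , ch] <- ifelse(crop$mask > 0, fgv, bgv)
    }
    tile <- normalize_tile(quantize8(rgb))
    tile$label <- if (type == "dicentric") "DIC" else "nonDIC"
    tile$source_id <- paste0("synthetic/", type, "/seed", seed)
    tile
  })
}

#' Generate an in-memory labelled tile corpus
#'
#' Draws `n_tiles` tiles at a non-DIC:DIC ratio of `ratio` (the population
#' imbalance the cascade is designed for; the source data ranged from about
#' 45:1 to 70:1). Non-DIC tiles are a mixture of ordinary, strongly bent and
#' entangled chromosomes; `hard_fraction` controls the share of entangled
#' hard negatives. Tiles are packed as an 8-bit raw array to keep memory
#' bounded.
#'
#' @param n_tiles Total number of tiles.
#' @param ratio Non-DIC to DIC ratio.
#' @param seed Integer seed.
#' @param hard_fraction Fraction of non-DIC tiles that are entangled pairs.
#' @param bent_fraction Fraction of non-DIC tiles that are strongly bent.
#' @param split_fraction Fraction of non-DIC tiles that are weakly split
#'   (hole-bearing non-DIC hard negatives).
#' @return A list of class `tile_corpus`: `tiles` raw array
#'   `[151, 151, 3, n]` (values 0-255), `labels` character vector
#'   (`"DIC"`/`"nonDIC"`), `types`, `n`.
#' @export
generate_tile_corpus <- function(n_tiles = 1000, ratio = 45, seed = 1,
                                 hard_fraction = 0.10,
                                 bent_fraction = 0.10,
                                 split_fraction = 0.10) {
  with_local_seed(seed, {
    n_dic <- max(1L, round(n_tiles / (ratio + 1)))
    n_non <- n_tiles - n_dic
    types <- c(rep("dicentric", n_dic),
               sample(c("entangled", "bent", "weak_split", "monocentric"),
                      n_non, replace = TRUE,
                      prob = c(hard_fraction, bent_fraction, split_fraction,
                               1 - hard_fraction - bent_fraction -
                                 split_fraction)))
    types <- sample(types)
    seeds <- sample.int(1e7, n_tiles)
    tiles <- array(as.raw(0), c(151, 151, 3, n_tiles))
    labels <- character(n_tiles)
    for (i in seq_len(n_tiles)) {
      tl <- render_tile(types[i], seed = seeds[i])
      tiles[, , , i] <- as.raw(round(tl$pixels * 255))
      labels[i] <- tl$label
    }
    structure(list(tiles = tiles, labels = labels, types = types,
                   n = n_tiles), class = "tile_corpus")
  })
}

#' Write a synthetic corpus to disk
#'
#' Renders field images, metaphase spreads and/or classifier tiles according
#' to `config` and writes 8-bit PNGs, per-image label-mask PNGs (16-bit
#' labels packed into two 8-bit channels) and a JSON manifest mapping each
#' file to its magnification, per-object kinds/labels/bounding boxes and
#' seeds. Identical seeds give byte-identical manifests.
#'
#' @param config List with any of: `n_fields`, `field` (args for
#'   [render_field_10x()]), `n_metaphases`, `metaphase` (args for
#'   [render_metaphase()]), `n_tiles`, `non_dic_to_dic_ratio`.
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed.
#' @return The manifest, invisibly; written to `manifest.json` in `out_dir`.
#' @export
generate_corpus <- function(config = list(), out_dir, seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create out_dir", call. = FALSE)
  n_fields <- config$n_fields %||% 0L
  n_meta <- config$n_metaphases %||% 0L
  n_tiles <- config$n_tiles %||% 0L
  ratio <- config$non_dic_to_dic_ratio %||% 45
  manifest <- list(seed = seed, images = list())
  with_local_seed(seed, {
    sub_seeds <- sample.int(1e7, n_fields + n_meta + 1L)
    k <- 0L
    if (n_fields > 0) for (i in seq_len(n_fields)) {
      k <- k + 1L
      fr <- do.call(render_field_10x,
                    c(list(seed = sub_seeds[k]), config$field))
      fn <- sprintf("field_%03d.png", i)
      png::writePNG(fr$image$pixels, file.path(out_dir, fn))
      cents <- fr$truth$metaphase_centroids
      manifest$images[[length(manifest$images) + 1]] <- list(
        path = fn, magnification = "10x", seed = sub_seeds[k],
        metaphase_centroids = if (is.null(cents)) list()
          else lapply(seq_len(nrow(cents)),
                      function(j) round(unname(cents[j, ]), 1)))
    }
    if (n_meta > 0) for (i in seq_len(n_meta)) {
      k <- k + 1L
      mr <- do.call(render_metaphase,
                    c(list(seed = sub_seeds[k]), config$metaphase))
      fn <- sprintf("metaphase_%03d.png", i)
      png::writePNG(mr$image$pixels, file.path(out_dir, fn))
      mfn <- sprintf("metaphase_%03d_labels.png", i)
      write_label_png(mr$truth$label_mask, file.path(out_dir, mfn))
      manifest$images[[length(manifest$images) + 1]] <- list(
        path = fn, magnification = "100x", seed = sub_seeds[k],
        label_mask = mfn,
        objects = lapply(mr$truth$objects, function(o)
          list(kind = o$kind, label = o$label, bbox = unname(o$bbox))))
    }
    if (n_tiles > 0) {
      k <- k + 1L
      corp <- generate_tile_corpus(n_tiles, ratio = ratio,
                                   seed = sub_seeds[k])
      dir.create(file.path(out_dir, "tiles"), showWarnings = FALSE)
      tile_entries <- vector("list", corp$n)
      for (i in seq_len(corp$n)) {
        fn <- file.path("tiles", sprintf("tile_%05d.png", i))
        arr <- array(as.integer(corp$tiles[, , , i]), c(151, 151, 3)) / 255
        png::writePNG(arr, file.path(out_dir, fn))
        tile_entries[[i]] <- list(path = fn, magnification = "100x",
                                  label = corp$labels[i],
                                  kind = corp$types[i])
      }
      manifest$tiles <- tile_entries
    }
  })
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = 8, pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
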