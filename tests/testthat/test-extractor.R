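test_that("k-means binarization separates two tones and rejects constants", {
  img <- array(210 / 255, c(40, 40, 3))
  img[10:20, 10:20, ] <- 40 / 255
  b <- kmeans_binarize(img)
  expect_equal(b[15, 15], 1)
  expect_equal(b[1, 1], 0)
  expect_equal(sum(b), 11 * 11)

  expect_error(kmeans_binarize(array(0.5, c(10, 10, 3))), "degenerate")
})

test_that("k = 2 luminance clustering beats no single threshold", {
  set.seed(4)
  lum <- matrix(pmin(1, pmax(0, c(rnorm(1500, 0.25, 0.07),
                                  rnorm(2500, 0.8, 0.08)))), 40, 100)
  img <- array(rep(lum, 3), c(40, 100, 3))
  b <- kmeans_binarize(img)
  v <- as.vector(lum)
  wcss <- function(assign) {
    sum(tapply(v, assign, function(x) sum((x - mean(x))^2)))
  }
  got <- wcss(as.vector(b))
  # brute-force best threshold partition on the 1-D luminance histogram
  best <- min(vapply(seq(0.05, 0.95, by = 0.005), function(t) {
    a <- v <= t
    if (all(a) || !any(a)) return(Inf)
    wcss(a)
  }, numeric(1)))
  expect_lte(got, best + 1e-6)
})

test_that("nucleus suppression removes blobs and keeps slim structures", {
  blob <- disk_mask(60, 60, 50, 120, 120)
  left <- suppress_nuclei(blob, 12)
  expect_lt(sum(left), 0.05 * sum(blob))

  bars <- matrix(0, 120, 120)
  bars[, seq(10, 110, by = 20)] <- 1
  bars[, seq(11, 111, by = 20)] <- 1  # widen to 8 px
  for (k in 0:5) bars[, seq(12 + k, 112, by = 20)] <- 1
  kept <- suppress_nuclei(bars, 12)
  expect_gte(sum(kept), 0.95 * sum(bars))
})

test_that("nucleus suppression on a rendered spread keeps chromosomes", {
  r <- render_metaphase(20, seed = 9, n_nuclei = 2, canvas = 1000)
  bin <- kmeans_binarize(r$image)
  sup <- suppress_nuclei(bin)
  chrom <- r$truth$label_mask > 0
  nuc <- matrix(FALSE, 1000, 1000)
  for (o in r$truth$objects) {
    if (o$kind != "nucleus") next
    rr <- o$offset[1]:(o$offset[1] + nrow(o$mask) - 1)
    cc <- o$offset[2]:(o$offset[2] + ncol(o$mask) - 1)
    nuc[rr, cc][o$mask > 0] <- TRUE
  }
  expect_gt(sum(sup[chrom]) / sum(chrom), 0.9)
  expect_lt(sum(sup[nuc]) / sum(nuc), 0.05)
})

test_that("median cleaning removes specks and keeps solids", {
  m <- matrix(0, 30, 30)
  m[15, 15] <- 1
  expect_equal(sum(clean_mask(m, 3)), 0)

  sq <- matrix(0, 30, 30); sq[6:25, 6:25] <- 1
  cleaned <- clean_mask(sq, 3)
  expect_true(all(cleaned[8:23, 8:23] == 1))

  set.seed(2)
  base <- matrix(0, 100, 100); base[30:70, 30:70] <- 1
  salt <- base
  noise_at <- sample(which(base == 0), 100)
  salt[noise_at] <- 1
  cleaned <- clean_mask(salt, 3)
  expect_gte(mean(cleaned[noise_at] == 0), 0.99)

  expect_error(clean_mask(m, 4), "odd")
})

test_that("object extraction conserves components and areas", {
  mask <- matrix(0, 60, 90)
  mask[5:15, 5:15] <- 1
  mask[30:45, 20:28] <- 1
  mask[10:20, 60:80] <- 1
  img <- array(0.3, c(60, 90, 3))
  objs <- extract_objects(img, mask)
  expect_length(objs, 3)
  expect_equal(sum(vapply(objs, `[[`, integer(1), "area_px")), sum(mask))

  expect_length(extract_objects(img, matrix(0, 60, 90)), 0)
  expect_error(extract_objects(img, matrix(0, 10, 10)), "aligned")
})

test_that("extraction pipeline mask is a subset of the binarization", {
  r <- render_metaphase(15, seed = 3, canvas = 700)
  b <- kmeans_binarize(r$image)
  final <- extraction_mask(r$image)
  expect_true(all(final <= b))
})

test_that("no-overlap spreads are recovered object for object", {
  r <- render_metaphase(46, seed = 21)
  objs <- extract_objects(r$image, extraction_mask(r$image))
  expect_length(objs, 46)
  # each object matches one ground-truth mask with IoU > 0.9
  lm <- r$truth$label_mask
  ious <- vapply(objs, function(o) {
    bb <- o$bbox
    sub <- lm[(bb[1] + 1):bb[3], (bb[2] + 1):bb[4], drop = FALSE]
    ids <- sub[o$mask_crop > 0]
    dom <- as.integer(names(which.max(table(ids[ids > 0]))))
    inter <- sum(sub == dom & o$mask_crop > 0)
    union <- sum(lm == dom) + o$area_px - inter
    inter / union
  }, numeric(1))
  expect_true(all(ious > 0.9))
})
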