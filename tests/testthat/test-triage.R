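test_that("width is the short side of the minimum-area rectangle", {
  rect <- matrix(0, 60, 50)
  rect[11:50, 21:30] <- 1  # 40 x 10, axis-aligned
  expect_equal(measure_width(rect), 10L)

  # same rectangle rotated 30 degrees
  g <- expand.grid(y = 1:120, x = 1:120)
  a <- 30 * pi / 180
  u <- (g$x - 60) * cos(a) + (g$y - 60) * sin(a)
  v <- -(g$x - 60) * sin(a) + (g$y - 60) * cos(a)
  rot <- matrix(as.numeric(abs(u) <= 19.5 & abs(v) <= 4.5), 120, 120)
  expect_lte(abs(measure_width(rot) - 10), 1)

  single <- matrix(0, 5, 5); single[3, 3] <- 1
  expect_equal(measure_width(single), 1L)
  expect_error(measure_width(matrix(0, 5, 5)), "empty")
})

test_that("hole counting matches geometry and the flood-fill oracle", {
  expect_equal(count_holes(disk_mask(30, 30, 20, 60, 60)), 0L)

  ann <- disk_mask(30, 30, 20, 60, 60) - disk_mask(30, 30, 10, 60, 60)
  expect_equal(count_holes(ann), 1L)

  two <- matrix(1, 20, 40)
  two[8:12, 8:12] <- 0
  two[8:12, 28:32] <- 0
  expect_equal(count_holes(two), 2L)
  expect_equal(count_holes(two), count_holes_oracle(two))
  expect_error(count_holes(matrix(0, 4, 4)), "empty")
})

test_that("triage reproduces the WH/IH rule with inclusive boundaries", {
  expect_equal(triage(24, 0), "impurity")
  expect_equal(triage(70, 1), "mass")
  expect_equal(triage(40, 1), "individual")
  expect_equal(triage(25, 3), "individual")
  expect_equal(triage(40, 4), "impurity")
  expect_equal(triage(66, 0), "mass")
  expect_equal(triage(65, 3), "individual")
  # total function: every (WH, IH) combination gets exactly one category
  grid <- expand.grid(WH = c(1, 24, 25, 40, 65, 66, 200),
                      IH = c(0, 3, 4, 10))
  cats <- triage(grid$WH, grid$IH)
  expect_true(all(cats %in% c("impurity", "mass", "individual")))
})

test_that("watershed splits overlapping bodies and conserves area", {
  m <- pmax(disk_mask(40, 60, 30), disk_mask(80, 60, 30))
  segs <- segment_mass(m)
  expect_length(segs, 2)
  expect_equal(sum(vapply(segs, `[[`, integer(1), "area_px")), sum(m))
  # disjoint: paste segments back and compare
  canvas <- matrix(0, nrow(m), ncol(m))
  for (s in segs) {
    bb <- s$bbox
    canvas[(bb[1] + 1):bb[3], (bb[2] + 1):bb[4]] <-
      canvas[(bb[1] + 1):bb[3], (bb[2] + 1):bb[4]] + s$mask_crop
  }
  expect_true(all(canvas <= 1))
  expect_equal(sum(canvas), sum(m))
})

test_that("tiny seeds are filtered and convex blobs stay whole", {
  tiny <- pmax(disk_mask(24, 30, 6, 60, 60), disk_mask(36, 30, 6, 60, 60))
  expect_length(segment_mass(tiny), 1)
  expect_length(segment_mass(disk_mask(60, 60, 35)), 1)
})

test_that("raising the seed-area threshold never adds segments", {
  for (s in c(3, 9)) {
    m <- cross_mass_fixture(s)
    if (is.null(m)) next
    counts <- vapply(c(150, 400, 1200, 1e5), function(msa)
      length(segment_mass(m, segmenter_config(min_seed_area = msa))),
      numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("shallow crossings at 60 degrees or more split into two", {
  ns <- vapply(1:15, function(s) {
    m <- cross_mass_fixture(s)
    if (is.null(m)) return(NA_integer_)
    length(segment_mass(m))
  }, integer(1))
  ns <- ns[!is.na(ns)]
  expect_gte(length(ns), 10)
  expect_gte(mean(ns == 2), 0.8)
})

test_that("triage loop splits masses and re-triages the segments", {
  m <- cross_mass_fixture(4)
  expect_false(is.null(m))
  obj <- structure(list(mask_crop = m,
                        image_crop = array(0.3, c(dim(m), 3)),
                        bbox = c(0L, 0L, nrow(m), ncol(m)),
                        centroid = c(0, 0), area_px = as.integer(sum(m)),
                        WH = NA_integer_, IH = NA_integer_,
                        category = NA_character_),
                   class = "detected_object")
  out <- triage_objects(list(obj))
  cats <- vapply(out, `[[`, "", "category")
  expect_gte(sum(cats == "individual"), 2)
  expect_true(all(vapply(out, function(o) !is.na(o$WH), logical(1))))
  expect_true(all(vapply(out[cats == "individual"],
                         function(o) o$parent_mass_id == 1, logical(1))))
})
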