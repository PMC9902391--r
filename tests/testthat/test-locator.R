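test_that("Otsu binarization separates a bimodal image", {
  set.seed(1)
  m <- matrix(200 / 255, 100, 100)
  dark <- sample(10000, 3000)
  m[dark] <- 50 / 255
  b <- binarize_otsu(m)
  expect_equal(mean(b), 0.30)
  expect_true(all(b[dark] == 1))
})

test_that("Otsu on a constant image is a degenerate histogram error", {
  expect_error(binarize_otsu(matrix(0.5, 10, 10)), "degenerate")
})

test_that("Otsu threshold matches the exhaustive 256-level scan", {
  for (s in 1:5) {
    set.seed(s)
    m <- matrix(pmin(1, pmax(0, c(rnorm(2000, 0.3, 0.08),
                                  rnorm(3000, 0.75, 0.1)))), 50, 100)
    thr_pkg <- EBImage::otsu(EBImage::Image(m), range = c(0, 1),
                             levels = 256)
    thr_ora <- otsu_oracle(m)
    expect_lt(abs(thr_pkg - thr_ora), 1.5 / 256)
  }
})

test_that("pore-texture opening removes thin strokes, keeps blobs", {
  strokes <- matrix(0, 80, 80)
  strokes[seq(10, 70, by = 8), ] <- 1
  strokes[seq(11, 71, by = 8), ] <- 1  # 2-px-wide horizontal strokes
  expect_equal(sum(suppress_pore_texture(strokes, 3)), 0)

  d <- disk_mask(40, 40, 20, 80, 80)
  kept <- suppress_pore_texture(d, 3)
  expect_gte(sum(kept), 0.9 * sum(d))

  empty <- matrix(0, 20, 20)
  expect_equal(sum(suppress_pore_texture(empty, 3)), 0)
})

test_that("opening is anti-extensive relative to dilation", {
  for (s in 1:5) {
    m <- random_blob(s, 300)
    op <- suppress_pore_texture(m, 3)
    dil <- dicascade:::bin_dilate(m, 3)
    expect_true(all(op <= dil))
    expect_true(all(op <= dicascade:::bin_dilate(m, 0 + 3)))
  }
})

test_that("candidate mask subtraction identities hold", {
  m <- disk_mask(30, 30, 15, 60, 60)
  expect_equal(sum(candidate_mask(m, m, 2, 6)), 0)
  grown <- candidate_mask(m, matrix(0, 60, 60), 2, 6)
  expect_true(all(grown >= m))
  # empty radii give the exact set difference
  sub <- candidate_mask(m, disk_mask(30, 30, 10, 60, 60), 0, 0)
  expect_equal(sub, matrix(as.numeric(m > 0 &
                                        !(disk_mask(30, 30, 10, 60, 60) > 0)),
                           60, 60))
  expect_error(candidate_mask(m, matrix(0, 10, 10)), "dimension")
})

test_that("locator finds synthetic metaphases and nothing else", {
  f <- render_field_10x(3, 5, 10, seed = 42)
  cand <- locate_metaphases(f$image)
  expect_equal(nrow(cand), 3)
  tc <- f$truth$metaphase_centroids
  for (i in 1:3) {
    d <- sqrt((cand$row - tc[i, 1])^2 + (cand$col - tc[i, 2])^2)
    expect_lt(min(d), 15)
  }

  blank <- render_field_10x(0, 0, 0, seed = 1)
  expect_equal(nrow(locate_metaphases(blank$image)), 0)

  nuc <- render_field_10x(0, 6, 8, seed = 2)
  expect_equal(nrow(locate_metaphases(nuc$image)), 0)
})

test_that("locator recall and precision reach 0.9 on seeded fields", {
  hits <- 0; n_true <- 0; n_found <- 0
  for (s in 1:20) {
    f <- render_field_10x(3, 5, 10, seed = s)
    cand <- locate_metaphases(f$image)
    n_true <- n_true + 3
    n_found <- n_found + nrow(cand)
    tc <- f$truth$metaphase_centroids
    for (i in seq_len(nrow(tc))) {
      d <- sqrt((cand$row - tc[i, 1])^2 + (cand$col - tc[i, 2])^2)
      if (length(d) && min(d) < 30) hits <- hits + 1
    }
  }
  expect_gte(hits / n_true, 0.9)
  expect_gte(hits / n_found, 0.9)
})

test_that("spread screening accepts 46 +/- 3 inclusively", {
  expect_true(screen_spread(46))
  expect_true(screen_spread(43))
  expect_true(screen_spread(49))
  expect_false(screen_spread(42))
  expect_false(screen_spread(50))
  expect_false(screen_spread(0))
})
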