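test_that("rendered hole count matches centromere count minus one", {
  kinds <- c(monocentric = 0L, dicentric = 1L, tricentric = 2L)
  for (k in names(kinds)) {
    ih <- vapply(seq_len(100), function(s) {
      set.seed(s)
      sp <- make_chromosome(k, length_px = runif(1, 90, 160),
                            width_px = runif(1, 28, 55),
                            curvature = runif(1, 0.05, 0.25),
                            seed = s)
      count_holes(render_chromosome_mask(sp)$mask)
    }, integer(1))
    expect_gte(mean(ih == kinds[[k]]), 0.95)
  }
})

test_that("rendered width tracks the requested width within 3 px", {
  err <- vapply(seq_len(40), function(s) {
    set.seed(s)
    w <- runif(1, 26, 60)
    sp <- make_chromosome("dicentric", 130, w, 0.15, seed = s)
    measure_width(render_chromosome_mask(sp,
                                         rotation = runif(1, 0, pi))$mask) - w
  }, numeric(1))
  expect_true(all(abs(err) <= 3))
})

test_that("width outside the permitted band is rejected", {
  expect_error(make_chromosome("monocentric", 120, 20), "outside")
  expect_error(make_chromosome("monocentric", 120, 70), "outside")
  expect_silent(make_chromosome("monocentric", 120, 25))
  expect_silent(make_chromosome("monocentric", 120, 65))
})

test_that("metaphase rendering is deterministic and respects counts", {
  a <- render_metaphase(12, seed = 7, canvas = 600)
  b <- render_metaphase(12, seed = 7, canvas = 600)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$truth$label_mask, b$truth$label_mask)

  r <- render_metaphase(46, dic_fraction = 0, overlap_fraction = 0,
                        seed = 1)
  labs <- vapply(r$truth$objects, `[[`, "", "label")
  expect_length(r$truth$objects, 46)
  expect_false(any(labs == "DIC"))
  # disjoint by construction: the composite has 46 components
  expect_equal(max(dicascade:::label_components(r$truth$label_mask > 0)),
               46)
})

test_that("dicentric draw frequency follows the requested fraction", {
  frac <- 3 / 46
  n_dic <- vapply(seq_len(12), function(s)
    render_metaphase(46, dic_fraction = frac, seed = s,
                     canvas = 1200)$truth$n_dic, numeric(1))
  total <- sum(n_dic)
  # exact binomial band for 12 * 46 draws at p = 3/46
  expect_gte(total, qbinom(0.0005, 12 * 46, frac))
  expect_lte(total, qbinom(0.9995, 12 * 46, frac))
})

test_that("overlap placement produces adhesive masses", {
  r <- render_metaphase(30, overlap_fraction = 0.2, seed = 5)
  areas <- vapply(r$truth$objects,
                  function(o) sum(o$mask), numeric(1))
  comp <- dicascade:::label_components(r$truth$label_mask > 0)
  comp_areas <- tabulate(comp[comp > 0])
  expect_lt(max(comp), 30)  # some objects merged into masses
  expect_gt(max(comp_areas), max(areas))
})

test_that("10x fields record centroids and keep pore-like texture", {
  f0 <- render_field_10x(0, 3, 4, seed = 1)
  expect_null(f0$truth$metaphase_centroids)

  f <- render_field_10x(3, 5, 5, seed = 2)
  expect_equal(nrow(f$truth$metaphase_centroids), 3)

  # metaphases are pore-like: their bounding boxes hold more background
  # than a nucleus bounding box
  bg_frac <- function(o) {
    1 - sum(o$mask) / prod(dim(o$mask))
  }
  kinds <- vapply(f$truth$objects, `[[`, "", "kind")
  meta_frac <- vapply(f$truth$objects[kinds == "metaphase"], bg_frac,
                      numeric(1))
  nuc_frac <- vapply(f$truth$objects[kinds == "nucleus"], bg_frac,
                     numeric(1))
  expect_gt(min(meta_frac), max(nuc_frac))
})

test_that("corpus generation is byte-identical under a fixed seed", {
  cfg <- list(n_fields = 1, field = list(n_metaphases = 1, n_nuclei = 2,
                                         n_debris = 3, canvas = 300),
              n_metaphases = 1,
              metaphase = list(n_chromosomes = 8, canvas = 500),
              n_tiles = 4)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_corpus(cfg, d1, seed = 7)
  generate_corpus(cfg, d2, seed = 7)
  m1 <- readBin(file.path(d1, "manifest.json"), "raw",
                file.size(file.path(d1, "manifest.json")))
  m2 <- readBin(file.path(d2, "manifest.json"), "raw",
                file.size(file.path(d2, "manifest.json")))
  expect_identical(m1, m2)
  p1 <- png::readPNG(file.path(d1, "metaphase_001.png"))
  p2 <- png::readPNG(file.path(d2, "metaphase_001.png"))
  expect_identical(p1, p2)
  # label masks round-trip exactly
  lm <- read_label_png(file.path(d1, "metaphase_001_labels.png"))
  expect_true(max(lm) >= 8)
})

test_that("tile corpus hits the requested class ratio", {
  corp <- generate_tile_corpus(230, ratio = 45, seed = 3)
  expect_equal(sum(corp$labels == "DIC"), 5)
  expect_equal(sum(corp$labels == "nonDIC") / sum(corp$labels == "DIC"),
               45)
  expect_equal(dim(corp$tiles), c(151, 151, 3, 230))
})
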