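test_that("tile normalization preserves aspect ratio on a 151 canvas", {
  sq <- array(runif(151 * 151 * 3), c(151, 151, 3))
  t1 <- normalize_tile(sq)
  expect_equal(dim(t1$pixels), c(151, 151, 3))
  expect_equal(t1$pixels[76, 76, ], sq[76, 76, ], tolerance = 0.02)

  # 2:1 crop scales to 151 x 76 content, centred
  tall <- array(0, c(302, 151, 3))  # all-dark content on light canvas
  t2 <- normalize_tile(tall)
  dark <- which(t2$pixels[, , 1] < 0.5, arr.ind = TRUE)
  h <- diff(range(dark[, 1])) + 1
  w <- diff(range(dark[, 2])) + 1
  expect_equal(h, 151)
  expect_lte(abs(w - 76), 1)
  expect_lte(abs(mean(range(dark[, 2])) - 76), 1.5)

  # upscale without distortion: content sides keep ratio 0.75 within 2%
  small <- array(0, c(75, 100, 3))
  t3 <- normalize_tile(small)
  dark <- which(t3$pixels[, , 1] < 0.5, arr.ind = TRUE)
  ratio <- (diff(range(dark[, 1])) + 1) / (diff(range(dark[, 2])) + 1)
  expect_lt(abs(ratio / 0.75 - 1), 0.02)

  expect_error(normalize_tile(NULL), "empty")
})

test_that("augmentation variants are label-preserving involutions", {
  tile <- render_tile("dicentric", seed = 3)
  aug <- augment_tile(tile, seed = 1)
  expect_length(aug, 4)
  expect_true(all(vapply(aug, function(a) identical(a$label, tile$label),
                         logical(1))))
  # mirror twice recovers the original
  mm <- augment_tile(augment_tile(tile, seed = 1)[[1]], seed = 1)[[1]]
  expect_equal(mm$pixels, tile$pixels)
  # pan there and back differs only at the border fill
  p1 <- pan_tile(tile$pixels, 5, 5)
  p2 <- pan_tile(p1, -5, -5)
  expect_equal(p2[1:140, 1:140, ], tile$pixels[1:140, 1:140, ])
  # zero-variance noise is the identity
  nz <- augment_tile(tile, seed = 2, noise_sd = 0)[[4]]
  expect_equal(nz$pixels, tile$pixels)
})

test_that("the two architectures match the published layer stacks", {
  a1 <- build_architecture(1)
  a2 <- build_architecture(2)
  expect_equal(a1$layers[[1]], list(op = "conv", filters = 8, window = 5))
  expect_equal(a2$layers[[1]], list(op = "conv", filters = 16, window = 5))
  f1 <- Filter(function(l) l$op == "conv", a1$layers)
  f2 <- Filter(function(l) l$op == "conv", a2$layers)
  expect_equal(vapply(f1, `[[`, numeric(1), "filters"),
               c(8, 8, 16, 32, 64))
  expect_equal(vapply(f2, `[[`, numeric(1), "filters"),
               c(16, 24, 40, 40, 64))
  fc1 <- Filter(function(l) l$op == "fc", a1$layers)
  expect_equal(vapply(fc1, `[[`, numeric(1), "units"), c(20, 10, 2))
  dr <- Filter(function(l) l$op == "dropout", a2$layers)
  expect_equal(vapply(dr, `[[`, numeric(1), "rate"), c(0.5, 0.3))

  tr <- architecture_trace(a1)
  expect_equal(tr$spatial, c(147, 145, 48, 46, 23, 21, 4, 2))
  expect_equal(tr$flatten, 256)
  expect_equal(architecture_trace(a2)$spatial, tr$spatial)
})

test_that("forward pass of both stages yields normalized 2-class scores", {
  corp <- tiny_corpus()
  for (stage in 1:2) {
    arch <- build_architecture(stage)
    p <- dicascade:::.init_params(arch, 1)
    pr <- dicascade:::cnn_forward_cpp(dicascade:::.arch_plan(arch), p, corp$tiles,
                          c(151L, 151L, 3L), 1:6)
    expect_true(all(abs(rowSums(pr) - 1) < 1e-5))
    expect_true(all(pr >= 0 & pr <= 1))
  }
})

test_that("oversampling multiplies the DIC stream count", {
  labels <- c(rep("DIC", 4), rep("nonDIC", 20))
  st <- training_stream(1:24, labels, dic_oversample = 3, seed = 1)
  expect_equal(sum(labels[st] == "DIC"), 12)
  expect_equal(sum(labels[st] == "nonDIC"), 20)
  st2 <- training_stream(1:24, labels, dic_oversample = 2,
                         nondic_subsample = 0.5, seed = 1)
  expect_equal(sum(labels[st2] == "DIC"), 8)
  expect_equal(sum(labels[st2] == "nonDIC"), 10)
})

test_that("training is deterministic and learns separable tiles", {
  corp <- generate_tile_corpus(200, ratio = 1, seed = 2,
                               hard_fraction = 0, bent_fraction = 0)
  cfg <- training_config(epochs = 5, batch_size = 16, lr = 0.003,
                         dic_oversample = 1, seed = 3)
  m <- train_stage(build_architecture(1), corp, corp$labels, cfg)
  expect_gt(utils::tail(m$history$acc, 1), 0.9)

  cfg1 <- training_config(epochs = 1, batch_size = 16, lr = 0.003,
                          dic_oversample = 1, seed = 3)
  h1 <- train_stage(build_architecture(1), corp, corp$labels,
                    cfg1)$history$loss[1]
  h2 <- train_stage(build_architecture(1), corp, corp$labels,
                    cfg1)$history$loss[1]
  expect_identical(h1, h2)

  expect_error(train_stage(build_architecture(1), corp,
                           rep("DIC", corp$n), cfg), "both classes")
})

test_that("score semantics: 0 is DIC, 1 is non-DIC, tie is non-DIC", {
  expect_equal(score_to_label(0), "DIC")
  expect_equal(score_to_label(1), "nonDIC")
  expect_equal(score_to_label(0.5), "nonDIC")
  expect_equal(score_to_label(c(0.2, 0.8)), c("DIC", "nonDIC"))
})

test_that("cascade consults stage 2 only on stage-1 positives", {
  corp <- tiny_corpus()
  mods <- tiny_models()
  res <- cascade_predict(mods$stage1, mods$stage2, corp)
  lab1 <- score_to_label(res$stage1_score)
  # stage-1 negatives are final and never scored by stage 2
  expect_true(all(is.na(res$stage2_score[lab1 == "nonDIC"])))
  expect_true(all(res$final_label[lab1 == "nonDIC"] == "nonDIC"))
  # stage-1 positives take stage 2's verdict
  pos <- lab1 == "DIC"
  expect_true(all(!is.na(res$stage2_score[pos])))
  expect_equal(res$final_label[pos], score_to_label(res$stage2_score[pos]))
  # dominance: cascade positives are a subset of stage-1 positives
  expect_true(all(res$final_label == "nonDIC" | pos))
})

test_that("model checkpoints round-trip with a JSON sidecar", {
  mods <- tiny_models()
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(mods$stage1, path)
  back <- load_model(path)
  corp <- tiny_corpus()
  expect_equal(cnn_predict(back, corp, 1:4),
               cnn_predict(mods$stage1, corp, 1:4))
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(side$stage, 1)
  expect_equal(unlist(side$input), c(151, 151, 3))
})
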