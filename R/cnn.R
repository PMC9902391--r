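#' Two-stage CNN cascade for dicentric identification
#'
#' Dicentrics are rare (the source population ran at roughly 45:1 to 70:1
#' non-DIC:DIC), so a single classifier tuned for sensitivity drowns in
#' false positives. The cascade trains a first-stage network on the full
#' population and a second-stage network specialized on the first stage's
#' false positives plus the dicentrics; at inference, only tiles the first
#' stage calls DIC are passed to the second stage, whose verdict is final.
#' Cascade positives are therefore always a subset of stage-1 positives.
#'
#' Both networks are 8-layer CNNs (5 convolutional + 3 fully connected
#' layers) over 3x151x151 RGB tiles: valid convolutions with stride 1, max
#' pooling with stride equal to the window, ReLU after every layer except
#' the softmax head. Spatial trace for a 151-px input:
#' 151 -> 147 -> 145 -> 48 -> 46 -> 23 -> 21 -> 4 -> 2, flattening to
#' 64*2*2 = 256 features.
#'
#' @name dic_cnn
NULL

TILE_SIDE <- 151L

#' Normalize a crop to a 151x151 classifier tile
#'
#' Stretchless zoom: aspect-ratio-preserving rescale so the longer side is
#' 151 px, centred on a background-coloured square canvas, intensities in
#' `[0,1]`.
#'
#' @param crop RGB array `[h,w,3]` (values in `[0,1]`) or a
#'   `detected_object` (its `image_crop` is used).
#' @param background Canvas fill value.
#' @return A `chromosome_tile`: `pixels` `[151,151,3]`, `label` (optional),
#'   `source_id`.
#' @export
normalize_tile <- function(crop, background = .syn$background) {
  if (inherits(crop, "detected_object")) crop <- crop$image_crop
  if (is.null(crop) || length(crop) == 0) stop("empty crop", call. = FALSE)
  if (length(dim(crop)) == 2) crop <- array(rep(crop, 3), c(dim(crop), 3))
  h <- dim(crop)[1]; w <- dim(crop)[2]
  sc <- TILE_SIDE / max(h, w)
  nh <- max(1L, round(h * sc)); nw <- max(1L, round(w * sc))
  img <- EBImage::Image(crop, colormode = "Color")
  rs <- EBImage::imageData(EBImage::resize(img, w = nh, h = nw))
  if (length(dim(rs)) == 2) rs <- array(rep(rs, 3), c(dim(rs), 3))
  canvas <- array(background, c(TILE_SIDE, TILE_SIDE, 3))
  r0 <- floor((TILE_SIDE - nh) / 2) + 1L
  c0 <- floor((TILE_SIDE - nw) / 2) + 1L
  canvas[r0:(r0 + nh - 1), c0:(c0 + nw - 1), ] <- rs
  canvas[canvas < 0] <- 0; canvas[canvas > 1] <- 1
  structure(list(pixels = canvas, label = NULL, source_id = NA_character_),
            class = "chromosome_tile")
}

#' Augment a tile
#'
#' Returns label-preserving variants: horizontal and vertical mirrors,
#' translations with background fill, and a Gaussian-noise copy.
#'
#' @param tile A `chromosome_tile`.
#' @param seed Integer seed (noise and pan offsets).
#' @param pan Maximal translation in pixels.
#' @param noise_sd Gaussian noise standard deviation.
#' @param background Fill for panned-in borders.
#' @return List of `chromosome_tile`s (mirror-h, mirror-v, pan, noise).
#' @export
augment_tile <- function(tile, seed = 1, pan = 5, noise_sd = 0.02,
                         background = .syn$background) {
  px <- tile$pixels
  mk <- function(p) {
    t2 <- tile; t2$pixels <- p; t2
  }
  with_local_seed(seed, {
    mh <- px[, ncol(px[, , 1]):1, , drop = FALSE]
    mv <- px[nrow(px[, , 1]):1, , , drop = FALSE]
    dr <- sample(-pan:pan, 1); dc <- sample(-pan:pan, 1)
    pn <- pan_tile(px, dr, dc, background)
    nz <- px + array(rnorm(length(px), 0, noise_sd), dim(px))
    nz[nz < 0] <- 0; nz[nz > 1] <- 1
    list(mk(mh), mk(mv), mk(pn), mk(nz))
  })
}

#' Translate tile pixels with background fill
#' @param px RGB array.
#' @param dr,dc Row/column shift.
#' @param background Fill value.
#' @return Shifted array.
#' @export
pan_tile <- function(px, dr, dc, background = .syn$background) {
  out <- array(background, dim(px))
  H <- dim(px)[1]; W <- dim(px)[2]
  sr <- max(1, 1 + dr):min(H, H + dr)
  sc <- max(1, 1 + dc):min(W, W + dc)
  out[sr, sc, ] <- px[sr - dr, sc - dc, , drop = FALSE]
  out
}

#' Build one of the two cascade architectures
#'
#' Stage 1: conv(8,5x5)-conv(8,3x3)-pool(3)-conv(16,3x3)-pool(2)-
#' conv(32,3x3)-pool(5)-conv(64,3x3)-fc(20)-fc(10)-fc(2,softmax).
#' Stage 2: conv(16,5x5)-conv(24,3x3)-pool(3)-conv(40,3x3)-pool(2)-
#' conv(40,3x3)-pool(5)-conv(64,3x3)-drop(0.5)-fc(20)-drop(0.3)-fc(10)-
#' fc(2,softmax). Convolutions are valid with stride 1; pool stride equals
#' the window, which is the unique reading under which all printed layer
#' sizes stay positive end-to-end for a 151-px input.
#'
#' @param stage 1 or 2.
#' @return A `cnn_architecture`: `layers` (descriptor list), `stage`,
#'   `input` (c(151,151,3)).
#' @export
build_architecture <- function(stage) {
  stopifnot(stage %in% c(1, 2))
  conv <- function(f, w) list(op = "conv", filters = f, window = w)
  pool <- function(w) list(op = "pool", window = w)
  fc <- function(u, relu = TRUE) list(op = "fc", units = u, relu = relu)
  drop <- function(r) list(op = "dropout", rate = r)
  layers <- if (stage == 1) list(
    conv(8, 5), conv(8, 3), pool(3), conv(16, 3), pool(2),
    conv(32, 3), pool(5), conv(64, 3),
    fc(20), fc(10), fc(2, relu = FALSE)
  ) else list(
    conv(16, 5), conv(24, 3), pool(3), conv(40, 3), pool(2),
    conv(40, 3), pool(5), conv(64, 3),
    drop(0.5), fc(20), drop(0.3), fc(10), fc(2, relu = FALSE)
  )
  arch <- structure(list(layers = layers, stage = stage,
                         input = c(TILE_SIDE, TILE_SIDE, 3L)),
                    class = "cnn_architecture")
  tr <- architecture_trace(arch)
  if (any(tr$spatial <= 0)) stop("architecture trace not positive")
  arch
}

#' Spatial trace of an architecture
#'
#' @param arch A `cnn_architecture`.
#' @return List: `spatial` (side length after each conv/pool layer) and
#'   `flatten` (feature count entering the first fully connected layer).
#' @export
architecture_trace <- function(arch) {
  s <- arch$input[1]
  ch <- arch$input[3]
  spatial <- integer(0)
  for (L in arch$layers) {
    if (L$op == "conv") {
      s <- s - L$window + 1
      ch <- L$filters
      spatial <- c(spatial, s)
    } else if (L$op == "pool") {
      s <- s %/% L$window
      spatial <- c(spatial, s)
    }
  }
  list(spatial = spatial, flatten = s * s * ch)
}

# Internal: plan vectors consumed by the C++ engine.
.arch_plan <- function(arch) {
  lapply(arch$layers, function(L) switch(L$op,
    conv = c(1, L$window, L$filters),
    pool = c(2, L$window),
    fc = c(3, L$units, as.numeric(L$relu)),
    dropout = c(4, L$rate)))
}

# Internal: He-initialized parameters for the parametric layers.
.init_params <- function(arch, seed) {
  with_local_seed(seed, {
    s <- arch$input[1]; ch <- arch$input[3]
    params <- list()
    for (L in arch$layers) {
      if (L$op == "conv") {
        fanin <- L$window^2 * ch
        W <- matrix(rnorm(L$filters * fanin, 0, sqrt(2 / fanin)),
                    L$filters, fanin)
        params[[length(params) + 1]] <- list(W = W, b = rep(0, L$filters))
        s <- s - L$window + 1; ch <- L$filters
      } else if (L$op == "pool") {
        s <- s %/% L$window
      } else if (L$op == "fc") {
        fanin <- if (is.na(s)) prev_units else s * s * ch
        W <- matrix(rnorm(L$units * fanin, 0, sqrt(2 / fanin)),
                    L$units, fanin)
        params[[length(params) + 1]] <- list(W = W, b = rep(0, L$units))
        s <- NA; ch <- NA; prev_units <- L$units
      }
    }
    params
  })
}

#' Training configuration
#'
#' Defaults follow the published recipe: SGD, learning rate 0.001 reduced
#' by a factor of 10 after half the epochs, momentum 0.9, weight decay
#' 0.0001, batch size 256, 50 epochs, train/validation/test split 7:2:1,
#' DIC oversampling 3x (stage 1) or 2x (stage 2) in train and validation
#' only.
#'
#' @param lr,lr_drop_factor,momentum,weight_decay,batch_size,epochs SGD
#'   hyper-parameters.
#' @param dic_oversample Duplication factor for DIC tiles in the training
#'   stream.
#' @param split Train/validation/test proportions summing to 10.
#' @param nondic_subsample Fraction of non-DIC tiles used for training
#'   (stage 1 subsamples the majority class; 1 = use all).
#' @param seed Integer seed for init, split and shuffling.
#' @return A `training_config` list.
#' @export
training_config <- function(lr = 0.001, lr_drop_factor = 10, momentum = 0.9,
                            weight_decay = 1e-4, batch_size = 256,
                            epochs = 50, dic_oversample = 3,
                            split = c(7, 2, 1), nondic_subsample = 1,
                            seed = 1) {
  stopifnot(lr > 0, momentum >= 0, batch_size >= 1, epochs >= 1,
            sum(split) == 10)
  structure(list(lr = lr, lr_drop_factor = lr_drop_factor,
                 momentum = momentum, weight_decay = weight_decay,
                 batch_size = batch_size, epochs = epochs,
                 dic_oversample = dic_oversample, split = split,
                 nondic_subsample = nondic_subsample, seed = seed),
            class = "training_config")
}

# Internal: coerce tiles to the raw [151,151,3,n] container.
.as_tile_raw <- function(tiles) {
  if (inherits(tiles, "tile_corpus")) return(tiles$tiles)
  if (is.raw(tiles)) return(tiles)
  if (inherits(tiles, "chromosome_tile"))
    tiles <- list(tiles)
  if (is.list(tiles)) {
    n <- length(tiles)
    out <- array(as.raw(0), c(TILE_SIDE, TILE_SIDE, 3, n))
    for (i in seq_len(n))
      out[, , , i] <- as.raw(round(tiles[[i]]$pixels * 255))
    return(out)
  }
  if (is.array(tiles) && length(dim(tiles)) == 4)
    return(array(as.raw(round(tiles * 255)), dim(tiles)))
  stop("unsupported tile container", call. = FALSE)
}

.tile_count <- function(tiles_raw) dim(tiles_raw)[4]

#' Split indices 7:2:1 into train/validation/test
#'
#' @param n Number of tiles.
#' @param split Proportions summing to 10.
#' @param seed Integer seed.
#' @return List of integer index vectors `train`, `val`, `test`.
#' @export
split_tiles <- function(n, split = c(7, 2, 1), seed = 1) {
  with_local_seed(seed, {
    ix <- sample.int(n)
    n_tr <- round(n * split[1] / 10)
    n_va <- round(n * split[2] / 10)
    list(train = ix[seq_len(n_tr)],
         val = ix[n_tr + seq_len(n_va)],
         test = if (n_tr + n_va < n) ix[(n_tr + n_va + 1):n]
                else integer(0))
  })
}

#' Build a training stream with minority oversampling
#'
#' DIC tiles are literally duplicated `dic_oversample` times; the non-DIC
#' majority may be subsampled (the source pipeline trained its first stage
#' on a random subsample of the majority class).
#'
#' @param idx Tile indices available.
#' @param labels Labels for all tiles.
#' @param dic_oversample Duplication factor for DIC indices.
#' @param nondic_subsample Fraction of non-DIC indices kept.
#' @param seed Integer seed for the subsample draw.
#' @return Integer vector of tile indices (unshuffled).
#' @export
training_stream <- function(idx, labels, dic_oversample = 1,
                            nondic_subsample = 1, seed = 1) {
  with_local_seed(seed, {
    non <- idx[labels[idx] == "nonDIC"]
    dic <- idx[labels[idx] == "DIC"]
    if (nondic_subsample < 1)
      non <- sample(non, max(1L, round(length(non) * nondic_subsample)))
    c(non, rep(dic, dic_oversample))
  })
}

#' Train one cascade stage
#'
#' SGD with momentum and weight decay on softmax cross-entropy. DIC tiles
#' are duplicated `dic_oversample` times in the training and validation
#' streams (literal duplication before shuffling); optionally the non-DIC
#' majority is subsampled. The learning rate drops by `lr_drop_factor`
#' after half the epochs. All randomness (parameter init, subsampling,
#' shuffling, dropout) derives from `cfg$seed`.
#'
#' @param arch A `cnn_architecture`.
#' @param tiles A `tile_corpus`, raw tile array, or list of
#'   `chromosome_tile`s.
#' @param labels Character vector `"DIC"`/`"nonDIC"`, one per tile.
#' @param cfg A [training_config()].
#' @param train_idx,val_idx Tile indices for the train and validation
#'   streams; defaults to a seeded 7:2:1 split of all tiles.
#' @param verbose Print per-epoch progress.
#' @return A `trained_model`: `architecture`, `params`, `history`
#'   (per-epoch loss/accuracy), `classes = c("DIC", "nonDIC")`.
#' @export
train_stage <- function(arch, tiles, labels, cfg = training_config(),
                        train_idx = NULL, val_idx = NULL, verbose = FALSE) {
  raw <- .as_tile_raw(tiles)
  n <- .tile_count(raw)
  stopifnot(length(labels) == n)
  if (length(unique(labels)) < 2)
    stop("training data must contain both classes", call. = FALSE)
  if (is.null(train_idx) || is.null(val_idx)) {
    sp <- split_tiles(n, cfg$split, seed = cfg$seed)
    if (is.null(train_idx)) train_idx <- sp$train
    if (is.null(val_idx)) val_idx <- sp$val
  }

  stream <- training_stream(train_idx, labels, cfg$dic_oversample,
                            cfg$nondic_subsample, cfg$seed + 101L)
  vstream <- training_stream(val_idx, labels, cfg$dic_oversample,
                             cfg$nondic_subsample, cfg$seed + 202L)

  plan <- .arch_plan(arch)
  params <- .init_params(arch, cfg$seed)
  vel <- lapply(params, function(p)
    list(W = matrix(0, nrow(p$W), ncol(p$W)), b = rep(0, length(p$b))))
  y <- ifelse(labels == "DIC", 0L, 1L)  # class 0 = DIC, class 1 = nonDIC
  dims <- c(TILE_SIDE, TILE_SIDE, 3L)
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        acc = numeric(0), val_acc = numeric(0))

  for (ep in seq_len(cfg$epochs)) {
    lr <- if (ep > cfg$epochs / 2) cfg$lr / cfg$lr_drop_factor else cfg$lr
    ord <- with_local_seed(cfg$seed * 1000L + ep, sample(stream))
    ep_loss <- 0; ep_acc <- 0; nb <- 0
    for (b0 in seq(1, length(ord), by = cfg$batch_size)) {
      bidx <- ord[b0:min(b0 + cfg$batch_size - 1, length(ord))]
      res <- cnn_batch_grad_cpp(plan, params, raw, dims,
                                as.integer(bidx), y[bidx],
                                as.integer((cfg$seed + ep * 131L + b0) %%
                                             .Machine$integer.max))
      for (k in seq_along(params)) {
        gW <- res$grads[[k]]$W + cfg$weight_decay * params[[k]]$W
        gb <- res$grads[[k]]$b
        vel[[k]]$W <- cfg$momentum * vel[[k]]$W - lr * gW
        vel[[k]]$b <- cfg$momentum * vel[[k]]$b - lr * gb
        params[[k]]$W <- params[[k]]$W + vel[[k]]$W
        params[[k]]$b <- params[[k]]$b + vel[[k]]$b
      }
      ep_loss <- ep_loss + res$loss; ep_acc <- ep_acc + res$acc
      nb <- nb + 1
    }
    vp <- cnn_forward_cpp(plan, params, raw, dims, as.integer(vstream))
    val_acc <- mean((vp[, 2] < 0.5) == (y[vstream] == 0L))
    history <- rbind(history, data.frame(
      epoch = ep, loss = ep_loss / nb, acc = ep_acc / nb,
      val_acc = val_acc))
    if (verbose)
      message(sprintf("epoch %d loss %.4f acc %.3f val %.3f",
                      ep, ep_loss / nb, ep_acc / nb, val_acc))
  }
  structure(list(architecture = arch, params = params, history = history,
                 classes = c("DIC", "nonDIC")),
            class = "trained_model")
}

#' Per-tile non-DIC score
#'
#' Softmax probability of the non-DIC class, between 0 (DIC) and 1
#' (non-DIC). The decision label is DIC iff score < 0.5 (a tie is
#' conservatively non-DIC).
#'
#' @param model A `trained_model`.
#' @param tiles Tile container (see [train_stage()]).
#' @param idx Tile indices to score (default all).
#' @return Numeric vector of scores in `[0,1]`.
#' @export
cnn_predict <- function(model, tiles, idx = NULL) {
  raw <- .as_tile_raw(tiles)
  if (is.null(idx)) idx <- seq_len(.tile_count(raw))
  if (length(idx) == 0) return(numeric(0))
  p <- cnn_forward_cpp(.arch_plan(model$architecture), model$params, raw,
                       c(TILE_SIDE, TILE_SIDE, 3L), as.integer(idx))
  p[, 2]
}

#' Decision label from a non-DIC score
#' @param score Numeric scores.
#' @return Character vector `"DIC"`/`"nonDIC"`.
#' @export
score_to_label <- function(score) ifelse(score < 0.5, "DIC", "nonDIC")

#' Cascade inference
#'
#' Tiles the first stage labels non-DIC are final non-DIC; tiles it labels
#' DIC are re-screened by the second stage, whose label is final. The
#' cascade's positive set is therefore a subset of stage 1's.
#'
#' @param stage1,stage2 `trained_model`s sharing tile geometry.
#' @param tiles Tile container.
#' @param idx Tile indices (default all).
#' @return Data frame: `idx`, `stage1_score`, `stage2_score` (NA where
#'   stage 2 was not consulted), `final_label`.
#' @export
cascade_predict <- function(stage1, stage2, tiles, idx = NULL) {
  raw <- .as_tile_raw(tiles)
  if (is.null(idx)) idx <- seq_len(.tile_count(raw))
  s1 <- cnn_predict(stage1, raw, idx)
  lab1 <- score_to_label(s1)
  s2 <- rep(NA_real_, length(idx))
  final <- lab1
  pos <- which(lab1 == "DIC")
  if (length(pos) > 0) {
    s2[pos] <- cnn_predict(stage2, raw, idx[pos])
    final[pos] <- score_to_label(s2[pos])
  }
  data.frame(idx = idx, stage1_score = s1, stage2_score = s2,
             final_label = final, stringsAsFactors = FALSE)
}

#' Train the full cascade
#'
#' Trains stage 1 on the corpus (majority class optionally subsampled, DIC
#' oversampled 3x), collects stage-1 false positives on its training and
#' validation tiles, and trains stage 2 on those false positives plus all
#' DIC tiles (oversampled 2x).
#'
#' @param tiles Tile container.
#' @param labels Character labels.
#' @param cfg1,cfg2 [training_config()]s for the two stages.
#' @param train_idx,val_idx Optional index vectors delimiting the tiles
#'   available for training (e.g. to hold out a test split).
#' @param verbose Print progress.
#' @return List with `stage1`, `stage2` (`trained_model`s).
#' @export
train_cascade <- function(tiles, labels,
                          cfg1 = training_config(dic_oversample = 3),
                          cfg2 = training_config(dic_oversample = 2),
                          train_idx = NULL, val_idx = NULL,
                          verbose = FALSE) {
  raw <- .as_tile_raw(tiles)
  n <- .tile_count(raw)
  if (is.null(train_idx) || is.null(val_idx)) {
    sp <- split_tiles(n, cfg1$split, seed = cfg1$seed)
    if (is.null(train_idx)) train_idx <- sp$train
    if (is.null(val_idx)) val_idx <- sp$val
  }
  m1 <- train_stage(build_architecture(1), raw, labels, cfg1,
                    train_idx = train_idx, val_idx = val_idx,
                    verbose = verbose)
  seen <- c(train_idx, val_idx)
  s1 <- cnn_predict(m1, raw, seen)
  fp <- seen[score_to_label(s1) == "DIC" & labels[seen] == "nonDIC"]
  dic <- seen[labels[seen] == "DIC"]
  if (length(fp) == 0) fp <- seen[labels[seen] == "nonDIC"][1]
  if (length(fp) > 200)
    fp <- with_local_seed(cfg2$seed + 13L, sample(fp, 200))
  # balance the specialist's stream: at desk scale the mined
  # false-positive pool can be far smaller than the DIC pool, so
  # replicate it up toward the (2x-oversampled) DIC count
  rep_fp <- max(1L, min(8L, floor(cfg2$dic_oversample * length(dic) /
                                    length(fp))))
  pool <- c(rep(fp, rep_fp), dic)
  sp2 <- with_local_seed(cfg2$seed + 7L, {
    ix <- sample(pool)
    ntr <- max(2L, round(length(ix) * 0.8))
    list(train = ix[seq_len(ntr)],
         val = ix[(ntr + 1):length(ix)])
  })
  m2 <- train_stage(build_architecture(2), raw, labels, cfg2,
                    train_idx = sp2$train, val_idx = sp2$val,
                    verbose = verbose)
  list(stage1 = m1, stage2 = m2)
}

#' Save / load a trained model
#'
#' The checkpoint is an RDS of the parameter store; an architecture JSON
#' sidecar (`<path>.json`) documents the layer stack.
#'
#' @param model A `trained_model`.
#' @param path Checkpoint path (`.rds`).
#' @return `save_model` the path, invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  jsonlite::write_json(
    list(stage = model$architecture$stage,
         input = model$architecture$input,
         layers = model$architecture$layers,
         classes = model$classes),
    paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
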