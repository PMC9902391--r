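# Shared fixtures, all generated in code.

# Filled disk mask.
disk_mask <- function(cx, cy, r, H = 120, W = 120) {
  g <- expand.grid(y = seq_len(H), x = seq_len(W))
  matrix(as.numeric((g$x - cx)^2 + (g$y - cy)^2 <= r^2), H, W)
}

# Two chromosomes forming an adhesive mass: chromosome 2 crosses
# chromosome 1 at an angle of at least 60 degrees and is slid into contact
# until their masks overlap by min_ov..max_ov pixels (a shallow junction,
# the regime the seed-filtered watershed is designed for).
cross_mass_fixture <- function(s, min_ov = 60, max_ov = 400) {
  set.seed(s)
  s1 <- make_chromosome("monocentric", runif(1, 120, 160),
                        runif(1, 30, 50), runif(1, 0.05, 0.25), seed = s)
  s2 <- make_chromosome("monocentric", runif(1, 120, 160),
                        runif(1, 30, 50), runif(1, 0.05, 0.25),
                        seed = s + 1000)
  th <- runif(1, pi / 3, pi / 2)
  r1 <- render_chromosome_mask(s1, rotation = 0)
  r2 <- render_chromosome_mask(s2, rotation = th)
  H <- 600; W <- 600
  m1 <- matrix(0, H, W)
  dr1 <- round(330 - nrow(r1$mask) / 2)
  dc1 <- round(300 - ncol(r1$mask) / 2)
  m1[dr1:(dr1 + nrow(r1$mask) - 1), dc1:(dc1 + ncol(r1$mask) - 1)] <-
    r1$mask
  colc <- round(dc1 + runif(1, 0.3, 0.7) * ncol(r1$mask))
  dc2 <- colc - round(ncol(r2$mask) / 2)
  if (dc2 < 1 || dc2 + ncol(r2$mask) - 1 > W) return(NULL)
  for (dr2 in seq_len(330)) {
    if (dr2 + nrow(r2$mask) - 1 > H) break
    sub <- m1[dr2:(dr2 + nrow(r2$mask) - 1),
              dc2:(dc2 + ncol(r2$mask) - 1)]
    ov <- sum(sub * r2$mask)
    if (ov >= min_ov) {
      if (ov > max_ov) return(NULL)
      m <- m1
      m[dr2:(dr2 + nrow(r2$mask) - 1), dc2:(dc2 + ncol(r2$mask) - 1)] <-
        pmax(sub, r2$mask)
      if (max(dicascade:::label_components(m)) > 1) return(NULL)
      return(m)
    }
  }
  NULL
}

# Random connected blob ("polyomino") grown by seeded random walk;
# optionally with extra thickness so it can contain holes.
random_blob <- function(seed, n_steps = 250, H = 60, W = 60) {
  set.seed(seed)
  m <- matrix(0, H, W)
  r <- H %/% 2; c <- W %/% 2
  for (i in seq_len(n_steps)) {
    m[r, c] <- 1
    dd <- sample(1:4, 1)
    r <- min(max(r + c(-1, 1, 0, 0)[dd], 2), H - 1)
    c <- min(max(c + c(0, 0, -1, 1)[dd], 2), W - 1)
  }
  m
}

# Independent hole-count oracle: breadth-first flood fill over the
# background from the border (4-connected), then count remaining
# background components by repeated BFS.
count_holes_oracle <- function(mask) {
  H <- nrow(mask) + 2; W <- ncol(mask) + 2
  fg <- matrix(FALSE, H, W)
  fg[2:(H - 1), 2:(W - 1)] <- mask > 0
  visited <- fg  # never visit foreground
  bfs <- function(starts) {
    queue <- starts
    comp <- integer(0)
    while (length(queue) > 0) {
      p <- queue[1]; queue <- queue[-1]
      if (visited[p]) next
      visited[p] <<- TRUE
      comp <- c(comp, p)
      r <- (p - 1) %% H + 1; c <- (p - 1) %/% H + 1
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        rr <- r + d[1]; cc <- c + d[2]
        if (rr >= 1 && rr <= H && cc >= 1 && cc <= W) {
          q <- (cc - 1) * H + rr
          if (!visited[q]) queue <- c(queue, q)
        }
      }
    }
    comp
  }
  border <- c(seq_len(H), (W - 1) * H + seq_len(H),
              ((2:(W - 1)) - 1) * H + 1, ((2:(W - 1)) - 1) * H + H)
  bfs(border)
  holes <- 0
  repeat {
    left <- which(!visited)
    if (length(left) == 0) break
    holes <- holes + 1
    bfs(left[1])
  }
  holes
}

# Independent minimum-width oracle: brute-force scan over rectangle
# orientations; at each angle the enclosing rectangle of the rotated pixel
# centres is measured and the minimum-area rectangle's short side is kept.
measure_width_oracle <- function(mask, step_deg = 0.25) {
  idx <- which(mask > 0, arr.ind = TRUE)
  pts <- cbind(idx[, 2], idx[, 1])
  if (nrow(pts) == 1) return(1)
  best_area <- Inf; best_short <- NA
  for (a in seq(0, 90 - step_deg, by = step_deg) * pi / 180) {
    u <- c(cos(a), sin(a)); v <- c(-sin(a), cos(a))
    pu <- pts %*% u; pv <- pts %*% v
    w1 <- max(pu) - min(pu) + 1; w2 <- max(pv) - min(pv) + 1
    if (w1 * w2 < best_area) {
      best_area <- w1 * w2
      best_short <- min(w1, w2)
    }
  }
  best_short
}

# Independent Otsu oracle: exhaustive scan over all cut positions of a
# 256-bin histogram on [0, 1] (right-closed bins, as hist() builds them),
# computing the between-class variance of each split from scratch and
# returning the mid of the best bin.
otsu_oracle <- function(m, levels = 256) {
  v <- as.vector(m)
  idx <- pmin(levels, pmax(1, ceiling(v * levels)))
  h <- tabulate(idx, nbins = levels)
  mids <- (seq_len(levels) - 0.5) / levels
  var_b <- rep(NA_real_, levels - 1)
  for (t in seq_len(levels - 1)) {
    n0 <- sum(h[1:t]); n1 <- sum(h[(t + 1):levels])
    if (n0 == 0 || n1 == 0) next
    mu0 <- sum(h[1:t] * mids[1:t]) / n0
    mu1 <- sum(h[(t + 1):levels] * mids[(t + 1):levels]) / n1
    var_b[t] <- n0 * n1 * (mu0 - mu1)^2
  }
  # empty gap bins produce exact ties; split them down the middle
  tied <- which(var_b == max(var_b, na.rm = TRUE))
  (mids[tied[1]] + mids[tied[length(tied)]]) / 2
}

# Small tile corpus cached across test files (trained models are reused).
tiny_corpus <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_tile_corpus(60, ratio = 1, seed = 99,
                                     hard_fraction = 0, bent_fraction = 0)
    cache
  }
})

tiny_models <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      corp <- tiny_corpus()
      cfg <- training_config(epochs = 3, batch_size = 16, lr = 0.003,
                             dic_oversample = 1, seed = 5)
      m1 <- train_stage(build_architecture(1), corp, corp$labels, cfg)
      m2 <- train_stage(build_architecture(2), corp, corp$labels,
                        training_config(epochs = 2, batch_size = 16,
                                        lr = 0.003, dic_oversample = 1,
                                        seed = 6))
      cache <<- list(stage1 = m1, stage2 = m2)
    }
    cache
  }
})
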