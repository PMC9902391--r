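# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed without touching global RNG state.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Round half away from zero
#'
#' Base `round()` rounds half to even; reported percentages use
#' conventional half-up rounding so printed tables match hand arithmetic.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 0) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

as_mask <- function(x) {
  m <- EBImage::imageData(x)
  if (length(dim(m)) > 2) m <- m[, , 1]
  matrix(as.numeric(m > 0.5), nrow(m), ncol(m))
}

stopifnot_mask <- function(mask, allow_empty = TRUE) {
  if (!is.matrix(mask)) stop("mask must be a 2-D matrix", call. = FALSE)
  if (!allow_empty && sum(mask > 0) == 0) stop("mask is empty", call. = FALSE)
  invisible(TRUE)
}

disc_kernel <- function(radius) {
  EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
}

# Binary morphology with an exact Euclidean disc, via distance transforms
# (O(n) regardless of radius). Erosion keeps pixels farther than r from the
# background; dilation adds pixels within r of the foreground.
bin_erode <- function(mask, r) {
  d <- EBImage::imageData(EBImage::distmap(mask))
  matrix(as.numeric(d > r), nrow(mask), ncol(mask))
}

bin_dilate <- function(mask, r) {
  if (sum(mask) == 0) return(mask * 0)
  d <- EBImage::imageData(EBImage::distmap(1 - mask))
  matrix(as.numeric(mask > 0 | d <= r), nrow(mask), ncol(mask))
}

bin_open <- function(mask, r) bin_dilate(bin_erode(mask, r), r)

bin_close <- function(mask, r) bin_erode(bin_dilate(mask, r), r)

# Tight bounding box of a binary matrix: list(r0, r1, c0, c1), 1-based inclusive.
mask_bbox <- function(mask) {
  idx <- which(mask > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) return(NULL)
  list(r0 = min(idx[, 1]), r1 = max(idx[, 1]),
       c0 = min(idx[, 2]), c1 = max(idx[, 2]))
}

# Connected-component labelling (8-connected) returning an integer matrix.
label_components <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  matrix(as.integer(round(EBImage::imageData(lab))), nrow(mask), ncol(mask))
}

# 4-connected flood reachability within `region` from the TRUE pixels of `from`.
# Implemented as iterated 4-neighbour dilation (morphological reconstruction).
flood_reach4 <- function(from, region) {
  cur <- from & region
  repeat {
    nb <- cur
    nb[-1, ] <- nb[-1, ] | cur[-nrow(cur), ]
    nb[-nrow(cur), ] <- nb[-nrow(cur), ] | cur[-1, ]
    nb[, -1] <- nb[, -1] | cur[, -ncol(cur)]
    nb[, -ncol(cur)] <- nb[, -ncol(cur)] | cur[, -1]
    nb <- nb & region
    if (identical(nb, cur)) return(cur)
    cur <- nb
  }
}

# Label a logical matrix into 4-connected components.
label_components4 <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  remaining <- mask
  k <- 0L
  while (any(remaining)) {
    k <- k + 1L
    seedpix <- which(remaining)[1]
    seed <- matrix(FALSE, nrow(mask), ncol(mask))
    seed[seedpix] <- TRUE
    comp <- flood_reach4(seed, remaining)
    lab[comp] <- k
    remaining <- remaining & !comp
  }
  lab
}

# Write an integer label matrix (0 = background) as an RGB PNG with the
# label split across two 8-bit channels (R = high byte, G = low byte), so
# values up to 65535 round-trip exactly.
write_label_png <- function(labels, path) {
  stopifnot(max(labels) <= 65535L)
  hi <- labels %/% 256L
  lo <- labels %% 256L
  arr <- array(0, c(nrow(labels), ncol(labels), 3))
  arr[, , 1] <- hi / 255
  arr[, , 2] <- lo / 255
  png::writePNG(arr, path)
  invisible(path)
}

#' Read a label mask written by the corpus generator
#'
#' Label masks are stored as RGB PNGs with the integer object label encoded
#' across the red (high byte) and green (low byte) channels.
#'
#' @param path Path to a label-mask PNG.
#' @return Integer matrix of per-pixel object labels (0 = background).
#' @export
read_label_png <- function(path) {
  arr <- png::readPNG(path)
  matrix(as.integer(round(arr[, , 1] * 255)) * 256L +
           as.integer(round(arr[, , 2] * 255)),
         dim(arr)[1], dim(arr)[2])
}

# Quantize [0,1] image data to 8 bits.
quantize8 <- function(x) {
  x[x < 0] <- 0; x[x > 1] <- 1
  round(x * 255) / 255
}
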