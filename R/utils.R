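# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code under a local, restorable RNG seed; NULL leaves the stream alone.
with_seed_ <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}

stop_input <- function(msg, class) {
  rlang::abort(msg, class = c(class, "cytosynth_error"))
}

check_image_batch <- function(images, arg = "images") {
  if (!is.array(images) || length(dim(images)) != 4L) {
    stop_input(sprintf("`%s` must be a 4-d array (n, height, width, channel)", arg),
               "cytosynth_shape_error")
  }
  if (dim(images)[4L] != 3L) {
    stop_input(sprintf("`%s` must have 3 colour channels, got %d", arg, dim(images)[4L]),
               "cytosynth_channel_error")
  }
  invisible(images)
}

# Batches carry images in [-1, 1] (n, h, w, 3) plus 0-based integer labels.
new_batch <- function(images, labels) {
  check_image_batch(images)
  stopifnot(dim(images)[1L] == length(labels))
  structure(list(images = images, labels = as.integer(labels)), class = "cyto_batch")
}

# (n,h,w,c) user layout <-> (h,w,c,n) internal layout used by the nn kernels
to_nn <- function(images) aperm(images, c(2L, 3L, 4L, 1L))
from_nn <- function(x) aperm(x, c(4L, 1L, 2L, 3L))

clip01 <- function(x) pmin(pmax(x, 0), 1)

# [0,1] pixel scale <-> [-1,1] tanh scale
to_tanh_range <- function(x) 2 * x - 1
from_tanh_range <- function(x) clip01((x + 1) / 2)

# hue in degrees -> rgb (s, v in [0,1]); vectorised over h
hsv_to_rgb <- function(h, s = 1, v = 1) {
  h <- (h %% 360) / 60
  i <- floor(h)
  f <- h - i
  p <- v * (1 - s)
  q <- v * (1 - s * f)
  t <- v * (1 - s * (1 - f))
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  cbind(r, g, b)
}

# rgb matrix (n x 3 in [0,1]) -> hue degrees and saturation
rgb_to_hs <- function(rgb) {
  mx <- pmax(rgb[, 1], rgb[, 2], rgb[, 3])
  mn <- pmin(rgb[, 1], rgb[, 2], rgb[, 3])
  d <- mx - mn
  h <- numeric(nrow(rgb))
  nz <- d > 0
  r <- rgb[, 1]; g <- rgb[, 2]; b <- rgb[, 3]
  idx <- nz & mx == r
  h[idx] <- 60 * (((g[idx] - b[idx]) / d[idx]) %% 6)
  idx <- nz & mx == g & mx != r
  h[idx] <- 60 * (((b[idx] - r[idx]) / d[idx]) + 2)
  idx <- nz & mx == b & mx != r & mx != g
  h[idx] <- 60 * (((r[idx] - g[idx]) / d[idx]) + 4)
  s <- ifelse(mx > 0, d / mx, 0)
  cbind(hue = h, sat = s)
}

# smallest angular distance between two hues, degrees
hue_distance <- function(a, b) {
  d <- abs((a - b) %% 360)
  pmin(d, 360 - d)
}

# circular mean of hues in degrees, optionally weighted
circular_mean_hue <- function(h, w = NULL) {
  if (length(h) == 0) return(NA_real_)
  if (is.null(w)) w <- rep(1, length(h))
  rad <- h * pi / 180
  (atan2(sum(w * sin(rad)), sum(w * cos(rad))) * 180 / pi) %% 360
}

# average-pool an (h,w) matrix or (h,w,c) array down to s x s
downsample_image <- function(img, s) {
  d <- dim(img)
  if (length(d) == 2L) dim(img) <- c(d, 1L)
  h <- dim(img)[1L]; w <- dim(img)[2L]; ch <- dim(img)[3L]
  ry <- ceiling(seq_len(h) / (h / s))
  rx <- ceiling(seq_len(w) / (w / s))
  out <- array(0, c(s, s, ch))
  counts <- tcrossprod(tabulate(ry, s), tabulate(rx, s))
  for (k in seq_len(ch)) {
    out[, , k] <- t(as.matrix(rowsum(t(as.matrix(rowsum(img[, , k], ry))), rx))) / counts
  }
  if (length(d) == 2L) out[, , 1L] else out
}
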