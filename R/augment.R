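#' Augmentation recipes
#'
#' Three named recipes combine geometric and photometric transforms:
#' `augmentation-1` = scaling, rotation, colour (hue) jitter;
#' `augmentation-2` = translation, contrast, scaling;
#' `augmentation-3` = saturation, scaling, rotation; `none` is the identity.
#' Parameter ranges default to mild, label-preserving magnitudes (scale
#' 0.8-1.2, rotation +/-30 degrees, translation +/-10%, contrast/saturation
#' +/-20%, hue +/-10 degrees) and are configurable per op.
#'
#' @param name Recipe name.
#' @param ops Optional explicit op list overriding the recipe: each element
#'   `list(op = <name>, range = c(lo, hi))` with op one of `scaling`,
#'   `rotation`, `color-jitter`, `translation`, `contrast`, `saturation`.
#' @param seed Integer seed used when the spec is applied.
#' @return An `augmentation_spec`.
#' @export
augmentation_spec <- function(name = c("none", "augmentation-1", "augmentation-2",
                                       "augmentation-3"),
                              ops = NULL, seed = 1L) {
  name <- if (is.null(ops)) match.arg(name) else if (length(name) == 1) name else "custom"
  defaults <- list(
    "none" = list(),
    "augmentation-1" = list(list(op = "scaling", range = c(0.8, 1.2)),
                            list(op = "rotation", range = c(-30, 30)),
                            list(op = "color-jitter", range = c(-10, 10))),
    "augmentation-2" = list(list(op = "translation", range = c(-0.1, 0.1)),
                            list(op = "contrast", range = c(0.8, 1.2)),
                            list(op = "scaling", range = c(0.8, 1.2))),
    "augmentation-3" = list(list(op = "saturation", range = c(0.8, 1.2)),
                            list(op = "scaling", range = c(0.8, 1.2)),
                            list(op = "rotation", range = c(-30, 30)))
  )
  if (is.null(ops)) ops <- defaults[[name]]
  known <- c("scaling", "rotation", "color-jitter", "translation", "contrast",
             "saturation")
  for (o in ops) {
    if (!o$op %in% known) {
      stop_input(paste0("unknown augmentation op: ", o$op), "cytosynth_config_error")
    }
  }
  structure(list(name = name, ops = ops, seed = as.integer(seed)),
            class = "augmentation_spec")
}

# bilinear sampling of img (h,w,c) at source coordinate matrices ys, xs
# (h x w, 1-based, clamped to the image)
warp_bilinear <- function(img, ys, xs) {
  h <- dim(img)[1]; w <- dim(img)[2]; ch <- dim(img)[3]
  ys <- pmin(pmax(ys, 1), h)
  xs <- pmin(pmax(xs, 1), w)
  y0 <- floor(ys); x0 <- floor(xs)
  y1 <- pmin(y0 + 1, h); x1 <- pmin(x0 + 1, w)
  fy <- ys - y0; fx <- xs - x0
  out <- array(0, dim(img))
  for (k in seq_len(ch)) {
    m <- img[, , k]
    v00 <- m[cbind(as.vector(y0), as.vector(x0))]
    v01 <- m[cbind(as.vector(y0), as.vector(x1))]
    v10 <- m[cbind(as.vector(y1), as.vector(x0))]
    v11 <- m[cbind(as.vector(y1), as.vector(x1))]
    out[, , k] <- (1 - fy) * (1 - fx) * v00 + (1 - fy) * fx * v01 +
      fy * (1 - fx) * v10 + fy * fx * v11
  }
  out
}

# combined scale / rotation / translation via one inverse warp
tf_affine <- function(img, scale = 1, angle_deg = 0, dx = 0, dy = 0) {
  h <- dim(img)[1]; w <- dim(img)[2]
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  yy <- matrix(rep(seq_len(h), times = w), h, w) - cy
  xx <- matrix(rep(seq_len(w), each = h), h, w) - cx
  th <- -angle_deg * pi / 180
  xs <- (cos(th) * xx - sin(th) * yy) / scale + cx - dx * w
  ys <- (sin(th) * xx + cos(th) * yy) / scale + cy - dy * h
  warp_bilinear(img, ys, xs)
}

tf_contrast <- function(img, f) {
  mu <- mean(img)
  clip01((img - mu) * f + mu)
}

tf_saturation <- function(img, f) {
  gray <- (img[, , 1] + img[, , 2] + img[, , 3]) / 3
  g <- array(rep(gray, 3), dim(img))
  clip01(g + f * (img - g))
}

tf_hue <- function(img, deg) {
  m <- matrix(img, ncol = 3)
  hs <- rgb_to_hs(m)
  v <- pmax(m[, 1], m[, 2], m[, 3])
  out <- hsv_to_rgb(hs[, "hue"] + deg, s = hs[, "sat"], v = v)
  array(out, dim(img))
}

apply_one_op <- function(img, op, par) {
  switch(op,
    "scaling" = tf_affine(img, scale = par),
    "rotation" = tf_affine(img, angle_deg = par),
    "translation" = tf_affine(img, dx = par, dy = par),
    "contrast" = tf_contrast(img, par),
    "saturation" = tf_saturation(img, par),
    "color-jitter" = tf_hue(img, par))
}

#' Apply an augmentation recipe to an image batch
#'
#' Every transform of the recipe is applied to every image with parameters
#' drawn independently per image from the configured ranges. Deterministic
#' given the spec's seed; labels are untouched.
#'
#' @param images Array (n, h, w, 3) in `[0, 1]`.
#' @param spec An [augmentation_spec()].
#' @return The augmented array, same shape.
#' @export
augment_images <- function(images, spec) {
  stopifnot(inherits(spec, "augmentation_spec"))
  check_image_batch(images)
  if (length(spec$ops) == 0) return(images)
  n <- dim(images)[1L]
  out <- images
  with_seed_(spec$seed, {
    for (i in seq_len(n)) {
      img <- images[i, , , ]
      for (o in spec$ops) {
        par <- runif(1, o$range[1], o$range[2])
        img <- apply_one_op(img, o$op, par)
      }
      out[i, , , ] <- img
    }
  })
  out
}
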