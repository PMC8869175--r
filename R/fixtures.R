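#' Toy single-cell fixture specification
#'
#' Describes a synthetic "toy cell" dataset: each class renders as an
#' elliptical nucleus of a class-specific hue and size on a tinted
#' background with band-limited texture. Classes are separable in mean
#' colour by construction (default hues 90 degrees apart), so conditional
#' generation and downstream classification have recoverable signal. One
#' class is deliberately a small minority to exercise the balancing
#' workflow.
#'
#' @param n_classes Number of classes (at least 2).
#' @param per_class_counts Integer vector of images per class (imbalance
#'   allowed); recycled to `n_classes`.
#' @param image_size Image side in pixels (at least 16).
#' @param seed Integer seed; the whole dataset is deterministic given it.
#' @param class_params Optional list (length `n_classes`) of per-class
#'   parameter lists; see [render_cell()] for fields. Defaults place class
#'   hues uniformly on the colour wheel.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_classes = 4, per_class_counts = c(200, 200, 200, 10),
                         image_size = 64, seed = 7L, class_params = NULL) {
  if (n_classes < 2) stop_input("need at least 2 classes", "cytosynth_config_error")
  if (image_size < 16) stop_input("image_size must be >= 16", "cytosynth_config_error")
  per_class_counts <- rep_len(as.integer(per_class_counts), n_classes)
  if (any(per_class_counts < 0)) stop_input("counts must be >= 0", "cytosynth_config_error")
  if (is.null(class_params)) {
    hues <- (seq_len(n_classes) - 1) * (360 / n_classes)
    r_scale <- image_size / 64
    class_params <- lapply(seq_len(n_classes), function(k) {
      list(hue = hues[k],
           nucleus_radius_mean = (8 + 2 * ((k - 1) %% 4)) * r_scale,
           nucleus_radius_sd = 1 * r_scale,
           texture_freq = 4 + 2 * ((k - 1) %% 3),
           texture_amp = 0.05,
           noise_sd = 0.02,
           background_tint = 0.82 + 0.02 * ((k - 1) %% 3) * c(1, 1, 1))
    })
  }
  structure(list(n_classes = n_classes, per_class_counts = per_class_counts,
                 image_size = as.integer(image_size), seed = as.integer(seed),
                 class_params = class_params, class_labels = paste0("class", seq_len(n_classes))),
            class = "fixture_spec")
}

#' Render one toy cell image
#'
#' Draws an elliptical nucleus with hue `params$hue`, radius drawn from a
#' normal distribution (`nucleus_radius_mean`, `nucleus_radius_sd`), over a
#' tinted background with sinusoidal band-limited texture at
#' `params$texture_freq` cycles per image and iid pixel noise. Fully
#' deterministic given the seed.
#'
#' @param params Per-class parameter list (see [fixture_spec()]).
#' @param image_size Image side in pixels.
#' @param seed Integer seed.
#' @return An RGB array (h, w, 3) in `[0, 1]`.
#' @export
render_cell <- function(params, image_size = 64, seed = 1L) {
  s <- image_size
  with_seed_(seed, {
    radius <- stats::rnorm(1, params$nucleus_radius_mean, params$nucleus_radius_sd)
    radius <- max(radius, 2)
    if (radius > s / 2) {
      stop_input(sprintf("nucleus radius %.1f exceeds half the image size", radius),
                 "cytosynth_parameter_error")
    }
    cx <- s / 2 + stats::runif(1, -s / 10, s / 10)
    cy <- s / 2 + stats::runif(1, -s / 10, s / 10)
    aspect <- stats::runif(1, 0.7, 1)
    theta <- stats::runif(1, 0, pi)
    phase <- stats::runif(1, 0, 2 * pi)
    tex_dir <- stats::runif(1, 0, pi)
    hue_jit <- stats::rnorm(1, 0, 2)

    xs <- matrix(rep(seq_len(s), each = s), s, s)   # column index
    ys <- matrix(rep(seq_len(s), times = s), s, s)  # row index
    dx <- xs - cx; dy <- ys - cy
    u <- cos(theta) * dx + sin(theta) * dy
    v <- -sin(theta) * dx + cos(theta) * dy
    inside <- (u / radius)^2 + (v / (radius * aspect))^2 <= 1

    tint <- rep_len(params$background_tint, 3L)
    nuc_rgb <- hsv_to_rgb(params$hue + hue_jit, s = 0.85, v = 0.75)
    tex <- (params$texture_amp %||% 0.05) *
      sin(2 * pi * params$texture_freq * (cos(tex_dir) * xs + sin(tex_dir) * ys) / s + phase)
    noise_sd <- params$noise_sd %||% 0.02

    img <- array(0, c(s, s, 3L))
    for (k in 1:3) {
      base <- ifelse(inside, nuc_rgb[k], tint[k])
      img[, , k] <- base + tex + stats::rnorm(s * s, 0, noise_sd)
    }
    clip01(img)
  })
}

#' Generate a toy-cell image dataset on disk
#'
#' Renders every image of the spec to PNG files under `out_dir` (one
#' subdirectory per class) and returns the corresponding manifest with
#' per-class counts exactly as specified.
#'
#' @param spec A [fixture_spec()].
#' @param out_dir Writable output directory (created if needed).
#' @return A manifest tibble with `source = "fixture"`.
#' @export
generate_fixture_dataset <- function(spec, out_dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (k in seq_len(spec$n_classes)) {
    n_k <- spec$per_class_counts[k]
    if (n_k == 0) next
    lab <- spec$class_labels[k]
    cls_dir <- file.path(out_dir, lab)
    dir.create(cls_dir, showWarnings = FALSE)
    paths <- character(n_k)
    for (i in seq_len(n_k)) {
      img <- render_cell(spec$class_params[[k]], spec$image_size,
                         seed = spec$seed + 10000L * k + i)
      paths[i] <- file.path(cls_dir, sprintf("%s_%04d.png", lab, i))
      png::writePNG(img, paths[i])
    }
    rows[[lab]] <- tibble(path = paths, label = lab, source = "fixture")
  }
  if (length(rows) == 0) {
    return(as_manifest(tibble(path = character(), label = character(),
                              source = character())))
  }
  as_manifest(dplyr::bind_rows(rows))
}

#' Estimate the dominant hue of a cell image
#'
#' Returns the saturation-weighted circular mean hue over pixels with
#' saturation above `sat_min` — the nucleus, for fixture-style images with
#' near-neutral backgrounds. Used as the measurement oracle for
#' class-conditional generation.
#'
#' @param img RGB array (h, w, 3) in `[0, 1]`.
#' @param sat_min Minimum saturation for a pixel to count as nucleus.
#' @return Hue in degrees, or `NA` if no pixel passes the threshold.
#' @export
measure_nucleus_hue <- function(img, sat_min = 0.2) {
  hs <- rgb_to_hs(matrix(img, ncol = 3L))
  keep <- hs[, "sat"] >= sat_min
  if (!any(keep)) return(NA_real_)
  circular_mean_hue(hs[keep, "hue"], w = hs[keep, "sat"])
}
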