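#' Tidy the training history of a GAN fit
#'
#' One row per (iteration, loss term), ready for faceting.
#'
#' @param x A `wgan_gp_ac` fit from [train_gan()].
#' @param ... Unused.
#' @return A long tibble with `epoch`, `iteration`, `term`, `value`.
#' @export
tidy.wgan_gp_ac <- function(x, ...) {
  tidyr::pivot_longer(x$history, cols = -c("epoch", "iteration"),
                      names_to = "term", values_to = "value")
}

#' One-row summary of a GAN fit
#'
#' @param x A `wgan_gp_ac` fit.
#' @param ... Unused.
#' @return A tibble with final loss terms, auxiliary accuracy, and run size.
#' @export
glance.wgan_gp_ac <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  tibble(epochs = x$train_cfg$epochs,
         iterations = nrow(x$history),
         n_classes = x$gan_cfg$n_classes,
         image_size = x$gan_cfg$image_size,
         final_wasserstein = last$critic_wasserstein,
         final_gradient_penalty = last$gradient_penalty,
         final_class_loss_real = last$class_loss_real,
         final_aux_accuracy = last$aux_accuracy_real)
}

#' @export
tidy.comparison_report <- function(x, ...) x$summary

#' @export
glance.comparison_report <- function(x, ...) {
  dplyr::summarise(x$summary,
                   n_conditions = dplyr::n(),
                   best_condition = .data$condition[which.max(.data$f1)],
                   best_f1 = max(.data$f1))
}

#' Plot GAN training curves
#'
#' Loss terms and auxiliary-classifier accuracy over iterations, one facet
#' per term.
#'
#' @param object A `wgan_gp_ac` fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.wgan_gp_ac <- function(object, ...) {
  df <- tidy(object)
  df$step <- (df$epoch - 1) * max(df$iteration) + df$iteration
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$value)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_wrap(~term, scales = "free_y") +
    ggplot2::labs(x = "iteration", y = NULL, title = "Training history") +
    ggplot2::theme_minimal()
}

#' Plot a dataset-condition comparison
#'
#' Macro precision/recall/F1 per training condition, plus per-class
#' sensitivity when available.
#'
#' @param object A `comparison_report` from [compare_conditions()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.comparison_report <- function(object, ...) {
  df <- tidyr::pivot_longer(object$summary,
                            cols = c("precision", "recall", "f1"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$condition, y = .data$value,
                                   fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, title = "Classifier performance by training data") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot a grid of images from a batch or array
#'
#' @param images An (n, h, w, 3) array in `[0, 1]` or a batch in `[-1, 1]`.
#' @param labels Optional facet labels.
#' @param max_images Cap on the number of panels.
#' @return A ggplot object.
#' @export
plot_image_grid <- function(images, labels = NULL, max_images = 16) {
  if (is.list(images) && !is.null(images$images)) {
    labels <- labels %||% images$labels
    images <- from_tanh_range(images$images)
  }
  n <- min(dim(images)[1L], max_images)
  h <- dim(images)[2L]; w <- dim(images)[3L]
  dfs <- lapply(seq_len(n), function(i) {
    img <- images[i, , , ]
    tibble(panel = if (is.null(labels)) paste0("img ", i) else
             paste0(i, ": ", labels[i]),
           y = rep(h:1, times = w), x = rep(1:w, each = h),
           fill = grDevices::rgb(clip01(as.vector(img[, , 1])),
                                 clip01(as.vector(img[, , 2])),
                                 clip01(as.vector(img[, , 3]))))
  })
  df <- dplyr::bind_rows(dfs)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$fill)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_identity() +
    ggplot2::facet_wrap(~panel) +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}
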