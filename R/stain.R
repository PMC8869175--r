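#' Reinhard stain normalization
#'
#' Standardizes slide staining appearance across acquisition sources by
#' matching per-channel mean and standard deviation to a reference image in
#' CIE Lab space (Reinhard colour transfer): each Lab channel is centred,
#' rescaled by the ratio of reference to source standard deviation, and
#' shifted to the reference mean, then converted back to sRGB.
#'
#' @param images An RGB image (h, w, 3) or image batch (n, h, w, 3) with
#'   values in `[0, 1]`.
#' @param reference The reference RGB image (h, w, 3) in `[0, 1]` whose
#'   staining statistics are to be matched.
#' @param clip Clip the result into `[0, 1]` (default). With `clip = FALSE`
#'   the moment match is exact but values may leave the valid range.
#' @return Normalized image(s), same shape as `images`.
#' @export
stain_normalize <- function(images, reference, clip = TRUE) {
  single <- length(dim(images)) == 3L
  if (single) dim(images) <- c(1L, dim(images))
  if (length(dim(images)) != 4L || dim(images)[4L] != 3L) {
    stop_input("stain normalization requires RGB input with 3 channels",
               "cytosynth_channel_error")
  }
  if (length(dim(reference)) != 3L || dim(reference)[3L] != 3L) {
    stop_input("reference must be an RGB image (h, w, 3)", "cytosynth_channel_error")
  }
  ref_lab <- rgb_to_lab(matrix(reference, ncol = 3L))
  ref_mu <- colMeans(ref_lab)
  ref_sd <- apply(ref_lab, 2, stats::sd)
  out <- images
  for (i in seq_len(dim(images)[1L])) {
    img <- images[i, , , , drop = TRUE]
    lab <- rgb_to_lab(matrix(img, ncol = 3L))
    mu <- colMeans(lab)
    s <- apply(lab, 2, stats::sd)
    scale <- ifelse(s > 1e-12, ref_sd / s, 0)
    lab <- sweep(sweep(lab, 2, mu), 2, scale, `*`)
    lab <- sweep(lab, 2, ref_mu, `+`)
    rgb <- lab_to_rgb(lab)
    if (clip) rgb <- clip01(rgb)
    out[i, , , ] <- array(rgb, dim(img))
  }
  if (single) out[1, , , , drop = TRUE] else out
}

rgb_to_lab <- function(rgb) {
  grDevices::convertColor(rgb, from = "sRGB", to = "Lab")
}

lab_to_rgb <- function(lab) {
  grDevices::convertColor(lab, from = "Lab", to = "sRGB", clip = FALSE)
}
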