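#' Feature backbones for distribution-level metrics
#'
#' The Frechet distance, inception score and perceptual distance all need a
#' feature extractor. No pretrained network ships with the package, so
#' backbones are pluggable: `backbone_pixel()` uses multi-scale
#' average-pooled pixels (deterministic, weight-free — the default for
#' tests and desk-scale runs); `backbone_aux_critic()` uses a trained
#' critic's residual-block activations as learned features and its auxiliary
#' class head for class probabilities. Any object with the same fields can
#' be supplied by the user.
#'
#' @param scales Downsampling side lengths, one feature layer per scale.
#' @return A `feature_backbone`: list with `id`, `extract(images)` returning
#'   a list of N x d feature matrices (one per layer), and optionally
#'   `class_probs(images)` returning an N x K probability matrix.
#' @export
backbone_pixel <- function(scales = c(16, 8, 4)) {
  structure(list(
    id = paste0("pixel-", paste(scales, collapse = "/")),
    extract = function(images) {
      lapply(scales, function(s) {
        n <- dim(images)[1L]
        t(vapply(seq_len(n),
                 function(i) as.numeric(downsample_image(images[i, , , ], s)),
                 numeric(s * s * dim(images)[4L])))
      })
    },
    class_probs = NULL
  ), class = "feature_backbone")
}

#' @rdname backbone_pixel
#' @param critic A trained [build_critic()] object (e.g. from a checkpoint).
#' @export
backbone_aux_critic <- function(critic) {
  stopifnot(inherits(critic, "cyto_critic"))
  structure(list(
    id = "aux-critic",
    extract = function(images) {
      fwd <- critic_forward(critic, to_nn(images), collect_features = TRUE)
      feats <- lapply(fwd$features, function(f) {
        n <- dim(f)[4L]
        t(matrix(f, ncol = n))
      })
      c(feats, list(fwd$pooled))
    },
    class_probs = function(images) {
      softmax_rows(critic_scores(critic, images)$class_logits)
    }
  ), class = "feature_backbone")
}

#' Perceptual distance between paired images
#'
#' An LPIPS-style distance: for every backbone layer, per-image feature
#' vectors are unit-normalized and the squared difference energy of each
#' pair is averaged; layers are then averaged. Zero on identical pairs,
#' symmetric in the pair order.
#'
#' @param pairs A [pair_images()] result.
#' @param backbone A feature backbone (default pixel).
#' @return Mean perceptual distance over pairs.
#' @export
perceptual_distance <- function(pairs, backbone = backbone_pixel()) {
  if (is.null(backbone$extract)) {
    stop_input("backbone lacks an extract() function", "cytosynth_config_error")
  }
  fr <- backbone$extract(pairs$real)
  fs <- backbone$extract(pairs$synthetic)
  unit_rows <- function(m) m / pmax(sqrt(rowSums(m^2)), 1e-12)
  layer_d <- vapply(seq_along(fr), function(l) {
    mean(rowSums((unit_rows(fr[[l]]) - unit_rows(fs[[l]]))^2))
  }, numeric(1))
  mean(layer_d)
}

#' Full evaluation report for a synthetic image set
#'
#' Computes the complete metric suite against a real manifest: Frechet
#' distance and (when the backbone or `class_probs` provides class
#' probabilities) inception score at the distribution level; l1/l2, MSE,
#' PSNR, SSIM and perceptual distance on within-class pairs. Provenance
#' (backbone id, pairing strategy, sample sizes, seed) is recorded in the
#' report.
#'
#' @param real,synthetic Manifests of real and synthetic images.
#' @param backbone A feature backbone (default pixel).
#' @param pairing Pairing strategy for the paired metrics.
#' @param class_probs Optional N x K probability matrix (or function of the
#'   synthetic images) for the inception score; defaults to the backbone's.
#' @param seed Seed for pairing.
#' @param size Optional resize at load time.
#' @return A one-row tibble (`metric_report`).
#' @export
evaluate_synthesis <- function(real, synthetic, backbone = backbone_pixel(),
                               pairing = "nn-within-class", class_probs = NULL,
                               seed = 1L, size = NULL) {
  pairs <- pair_images(real, synthetic, strategy = pairing, seed = seed, size = size)
  feat_r <- backbone$extract(pairs$real)
  feat_s <- backbone$extract(pairs$synthetic)
  last <- length(feat_r)
  fid_val <- fid(gaussian_moments(feat_r[[last]]), gaussian_moments(feat_s[[last]]))
  probs <- NULL
  if (!is.null(class_probs)) {
    probs <- if (is.function(class_probs)) class_probs(pairs$synthetic) else class_probs
  } else if (!is.null(backbone$class_probs)) {
    probs <- backbone$class_probs(pairs$synthetic)
  }
  is_res <- if (is.null(probs)) list(mean = NA_real_, sd = NA_real_) else
    inception_score(probs)
  err <- l1_l2(pairs)
  mp <- mse_psnr(pairs)
  rep <- tibble(
    is_mean = is_res$mean, is_sd = is_res$sd, fid = fid_val,
    lpips = perceptual_distance(pairs, backbone),
    l1 = err$l1_per_pixel, l2 = err$l2_per_pixel,
    mse = mp$mse, psnr = mp$psnr,
    ssim = ssim(pairs),
    backbone = backbone$id, pairing = pairing,
    n_real = dim(pairs$real)[1L], n_synthetic = dim(pairs$synthetic)[1L],
    seed = as.integer(seed))
  class(rep) <- c("metric_report", class(rep))
  rep
}
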