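#' Inception score from class-conditional probabilities
#'
#' `exp` of the mean per-sample Kullback-Leibler divergence between the
#' conditional class distribution `p(y|x)` and the marginal `p(y)` (the
#' column mean). Computed over `splits` contiguous subsets, reporting the
#' mean and standard deviation of the per-split scores (the standard
#' protocol uses 10 splits). Bounded in `[1, K]`.
#'
#' @param cond_probs N x K matrix; each row a probability vector.
#' @param splits Number of contiguous splits (capped at N).
#' @return A list with `mean` and `sd`.
#' @export
inception_score <- function(cond_probs, splits = 10) {
  cond_probs <- as.matrix(cond_probs)
  if (any(cond_probs < -1e-12) || any(abs(rowSums(cond_probs) - 1) > 1e-6)) {
    stop_input("rows of cond_probs must be probability vectors",
               "cytosynth_input_error")
  }
  n <- nrow(cond_probs)
  splits <- max(1L, min(as.integer(splits), n))
  bounds <- floor(seq(0, n, length.out = splits + 1))
  scores <- vapply(seq_len(splits), function(s) {
    p <- cond_probs[(bounds[s] + 1):bounds[s + 1], , drop = FALSE]
    marginal <- colMeans(p)
    lr <- log(pmax(p, 1e-300)) - matrix(log(pmax(marginal, 1e-300)),
                                        nrow(p), ncol(p), byrow = TRUE)
    kl <- rowSums(ifelse(p > 0, p * lr, 0))
    exp(mean(kl))
  }, numeric(1))
  list(mean = mean(scores), sd = if (splits > 1) stats::sd(scores) else 0)
}

#' Gaussian moments of a feature matrix
#'
#' Sample mean and maximum-likelihood covariance (divisor N) of row
#' features, the inputs of the Frechet distance. The ML convention is used
#' because the Frechet-distance literature varies and it makes `fid()` exact
#' for point masses.
#'
#' @param features N x d numeric matrix, N >= 2.
#' @return A list with `mu` (length d) and `sigma` (d x d).
#' @export
gaussian_moments <- function(features) {
  features <- as.matrix(features)
  if (nrow(features) < 2) {
    stop_input("need at least 2 feature rows", "cytosynth_input_error")
  }
  mu <- colMeans(features)
  centered <- sweep(features, 2, mu)
  sigma <- crossprod(centered) / nrow(features)
  list(mu = mu, sigma = sigma)
}

#' Frechet distance between two Gaussian feature distributions
#'
#' `||mu_a - mu_b||^2 + tr(S_a + S_b - 2 (S_a S_b)^(1/2))`, evaluated with
#' the principal square root computed as the symmetric eigendecomposition of
#' `S_a^(1/2) S_b S_a^(1/2)`; small negative eigenvalues from floating-point
#' noise are clipped to zero, so the result is always non-negative.
#'
#' @param a,b Lists with `mu` and `sigma` (see [gaussian_moments()]).
#' @return The (squared) Frechet distance, >= 0.
#' @export
fid <- function(a, b) {
  if (length(a$mu) != length(b$mu)) {
    stop_input("moment dimensions differ", "cytosynth_input_error")
  }
  sym_sqrt <- function(s) {
    e <- eigen((s + t(s)) / 2, symmetric = TRUE)
    e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
  }
  ra <- sym_sqrt(a$sigma)
  m <- ra %*% b$sigma %*% ra
  ev <- pmax(eigen((m + t(m)) / 2, symmetric = TRUE, only.values = TRUE)$values, 0)
  val <- sum((a$mu - b$mu)^2) + sum(diag(a$sigma)) + sum(diag(b$sigma)) -
    2 * sum(sqrt(ev))
  max(val, 0)
}

#' Absolute and squared reconstruction error of paired images
#'
#' `l1` is the sum of absolute differences, `l2` the sum of squared
#' differences over all pixels of all pairs; per-pixel means are reported
#' alongside.
#'
#' @param pairs A [pair_images()] result (or any list with equal-shaped
#'   `real` and `synthetic` arrays).
#' @return A list with `l1`, `l2`, `l1_per_pixel`, `l2_per_pixel`.
#' @export
l1_l2 <- function(pairs) {
  d <- pairs$real - pairs$synthetic
  if (!identical(dim(pairs$real), dim(pairs$synthetic))) {
    stop_input("paired arrays must have identical shapes", "cytosynth_input_error")
  }
  list(l1 = sum(abs(d)), l2 = sum(d^2),
       l1_per_pixel = mean(abs(d)), l2_per_pixel = mean(d^2))
}

#' Mean squared error and peak signal-to-noise ratio
#'
#' MSE averages squared differences over all pixels; PSNR is
#' `10 log10(R^2 / MSE)` dB where `R` is the maximum possible pixel value.
#' Identical pairs report `psnr = Inf` (a sentinel, not a cap).
#'
#' @param pairs A [pair_images()] result.
#' @param R Maximum pixel value (1 for unit-scaled arrays, 255 for 8-bit).
#' @return A list with `mse` and `psnr` (dB).
#' @export
mse_psnr <- function(pairs, R = 1) {
  if (R <= 0) stop_input("R must be positive", "cytosynth_parameter_error")
  mse <- mean((pairs$real - pairs$synthetic)^2)
  list(mse = mse, psnr = if (mse == 0) Inf else 10 * log10(R^2 / mse))
}

# uniform box filter of valid windows, via cumulative sums; x is a matrix
box_filter_valid <- function(x, win) {
  cs <- apply(apply(x, 2, cumsum), 1, cumsum)  # transposed cumulative sum
  cs <- t(cs)
  pad <- rbind(0, cbind(0, matrix(0, nrow(cs), ncol(cs))))
  pad[2:(nrow(cs) + 1), 2:(ncol(cs) + 1)] <- cs
  h <- nrow(x) - win + 1
  w <- ncol(x) - win + 1
  (pad[(win + 1):(win + h), (win + 1):(win + w)] -
     pad[1:h, (win + 1):(win + w)] -
     pad[(win + 1):(win + h), 1:w] + pad[1:h, 1:w]) / win^2
}

#' Structural similarity of paired images
#'
#' Mean SSIM over all valid `window`-sized local neighbourhoods: the product
#' of luminance, contrast and structure comparisons with stabilizers
#' `C1 = (K1 R)^2`, `C2 = (K2 R)^2`, `C3 = C2 / 2`, using a uniform window
#' and sample (unbiased) local variances. Multi-channel images are averaged
#' across per-channel SSIM. Result lies in `[-1, 1]`, with 1 exactly on
#' identical pairs.
#'
#' @param pairs A [pair_images()] result.
#' @param window Odd window side (default 7); must not exceed the image.
#' @param K1,K2 Stabilizer constants.
#' @param R Dynamic range of the pixel values.
#' @return Mean SSIM over pairs.
#' @export
ssim <- function(pairs, window = 7, K1 = 0.01, K2 = 0.03, R = 1) {
  dr <- dim(pairs$real)
  if (window > dr[2] || window > dr[3]) {
    stop_input("window larger than image", "cytosynth_parameter_error")
  }
  c1 <- (K1 * R)^2
  c2 <- (K2 * R)^2
  n_win <- window^2
  cov_norm <- n_win / (n_win - 1)
  vals <- numeric(dr[1])
  n_ch <- if (length(dr) == 4) dr[4] else 1
  for (i in seq_len(dr[1])) {
    ch_vals <- numeric(n_ch)
    for (k in seq_len(n_ch)) {
      x <- if (length(dr) == 4) pairs$real[i, , , k] else pairs$real[i, , ]
      y <- if (length(dr) == 4) pairs$synthetic[i, , , k] else pairs$synthetic[i, , ]
      ux <- box_filter_valid(x, window)
      uy <- box_filter_valid(y, window)
      uxx <- box_filter_valid(x * x, window)
      uyy <- box_filter_valid(y * y, window)
      uxy <- box_filter_valid(x * y, window)
      vx <- cov_norm * (uxx - ux^2)
      vy <- cov_norm * (uyy - uy^2)
      vxy <- cov_norm * (uxy - ux * uy)
      num <- (2 * ux * uy + c1) * (2 * vxy + c2)
      den <- (ux^2 + uy^2 + c1) * (vx + vy + c2)
      ch_vals[k] <- mean(num / den)
    }
    vals[i] <- mean(ch_vals)
  }
  mean(vals)
}

#' Pair synthetic images with real images of the same class
#'
#' Generated images are unpaired by nature; the paired error metrics
#' (l1/l2, PSNR, SSIM) need a correspondence. Strategy `"nn-within-class"`
#' pairs each synthetic image with its MSE-nearest real image of the same
#' class; `"random-within-class"` pairs uniformly at random (seeded).
#'
#' @param real,synthetic Manifests sharing a class set (real must cover every
#'   synthetic class).
#' @param strategy `"nn-within-class"` (default) or `"random-within-class"`.
#' @param seed Seed for the random strategy.
#' @param size Optional resize applied when loading.
#' @return A `paired_batch`: list with `real` and `synthetic` image arrays in
#'   1-1 correspondence, `labels`, and a `pairs` tibble recording ids and the
#'   strategy.
#' @export
pair_images <- function(real, synthetic, strategy = c("nn-within-class",
                                                      "random-within-class"),
                        seed = 1L, size = NULL) {
  strategy <- match.arg(strategy)
  real <- as_manifest(real)
  synthetic <- as_manifest(synthetic)
  missing_cls <- setdiff(unique(synthetic$label), unique(real$label))
  if (length(missing_cls) > 0) {
    stop_input(paste0("class(es) absent from real manifest: ",
                      paste(missing_cls, collapse = ", ")), "cytosynth_pairing_error")
  }
  rdat <- load_images(real, size = size)
  sdat <- load_images(synthetic, size = size)
  n <- nrow(synthetic)
  pick <- integer(n)
  with_seed_(seed, {
    for (lab in unique(synthetic$label)) {
      s_idx <- which(synthetic$label == lab)
      r_idx <- which(real$label == lab)
      if (strategy == "random-within-class") {
        pick[s_idx] <- r_idx[sample.int(length(r_idx), length(s_idx), replace = TRUE)]
      } else {
        rmat <- matrix(rdat$images[r_idx, , , , drop = FALSE], length(r_idx))
        for (j in s_idx) {
          sv <- as.numeric(sdat$images[j, , , ])
          d2 <- rowSums(sweep(rmat, 2, sv)^2)
          pick[j] <- r_idx[which.min(d2)]
        }
      }
    }
  })
  structure(list(real = rdat$images[pick, , , , drop = FALSE],
                 synthetic = sdat$images,
                 labels = synthetic$label,
                 pairs = tibble(synthetic_id = synthetic$id,
                                real_id = real$id[pick],
                                label = synthetic$label,
                                strategy = strategy, seed = seed)),
            class = "paired_batch")
}

#' Macro precision, recall and F1 from a confusion matrix
#'
#' Rows are true classes, columns predicted. Macro averaging over classes;
#' per-class one-vs-rest accuracy, sensitivity (= recall) and specificity
#' are returned alongside. Classes never predicted contribute precision 0.
#'
#' @param confusion K x K non-negative count matrix.
#' @return A list with `precision`, `recall`, `f1` and a `per_class` tibble.
#' @export
prf <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (any(confusion < 0) || sum(confusion) == 0) {
    stop_input("confusion matrix must be non-negative and non-empty",
               "cytosynth_input_error")
  }
  k <- nrow(confusion)
  total <- sum(confusion)
  tp <- unname(diag(confusion))
  fp <- unname(colSums(confusion)) - tp
  fn <- unname(rowSums(confusion)) - tp
  tn <- total - tp - fp - fn
  precision_c <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  recall_c <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  precision <- mean(precision_c)
  recall <- mean(recall_c)
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  labels <- rownames(confusion) %||% paste0("class", seq_len(k) - 1)
  list(precision = precision, recall = recall, f1 = f1,
       per_class = tibble(label = labels,
                          accuracy = (tp + tn) / total,
                          sensitivity = recall_c,
                          specificity = ifelse(tn + fp > 0, tn / (tn + fp), 0),
                          precision = precision_c))
}
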