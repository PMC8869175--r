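#' Wasserstein critic loss
#'
#' The quantity the critic minimizes: `mean(fake_scores) - mean(real_scores)`.
#' Invariant to adding a constant to all scores; zero when the two score
#' distributions have equal means.
#'
#' @param real_scores,fake_scores Non-empty numeric vectors of critic source
#'   scores on real and generated images.
#' @return A single number.
#' @export
critic_wasserstein_loss <- function(real_scores, fake_scores) {
  if (length(real_scores) == 0 || length(fake_scores) == 0) {
    stop_input("score vectors must be non-empty", "cytosynth_input_error")
  }
  mean(fake_scores) - mean(real_scores)
}

#' Interpolate between real and generated batches
#'
#' Element-wise convex combination `eps * real + (1 - eps) * fake` with one
#' uniform draw per sample — the random points at which the gradient penalty
#' is evaluated.
#'
#' @param real,fake Image arrays (n, h, w, 3) of equal shape.
#' @param eps Per-sample coefficients in `[0, 1]`; drawn uniformly under
#'   `seed` when omitted.
#' @param seed Optional seed for the draw.
#' @return An array of the same shape.
#' @export
interpolate_images <- function(real, fake, eps = NULL, seed = NULL) {
  if (!identical(dim(real), dim(fake))) {
    stop_input("real and fake batches must have identical shapes",
               "cytosynth_input_error")
  }
  n <- dim(real)[1L]
  if (is.null(eps)) eps <- with_seed_(seed, runif(n))
  if (any(eps < 0 | eps > 1)) {
    stop_input("eps must lie in [0, 1]", "cytosynth_input_error")
  }
  e <- array(rep(eps, times = prod(dim(real)[-1L])), dim(real))
  e * real + (1 - e) * fake
}

# per-sample gradient of the source score wrt the input, internal layout
critic_input_grads <- function(critic, x_nn) {
  fwd <- critic_forward(critic, x_nn)
  n <- dim(x_nn)[4L]
  bwd <- critic_backward(fwd$critic, fwd$cache, d_source = rep(1, n))
  g <- bwd$gx
  norms <- sqrt(colSums(matrix(g, ncol = n)^2))
  list(g = g, norms = norms, fwd = fwd)
}

#' Gradient penalty of the Wasserstein critic
#'
#' `sigma * mean((||grad_x D(x)||_2 - 1)^2)` over the batch, where the
#' gradient of the source score with respect to the input image is computed
#' analytically by backpropagation. Softly enforces the 1-Lipschitz
#' condition the Wasserstein objective requires.
#'
#' @param critic A [build_critic()] object.
#' @param x_hat Interpolated images, (n, h, w, 3) in user layout.
#' @param sigma Penalty coefficient (default 10).
#' @return The penalty value (non-negative).
#' @export
gradient_penalty <- function(critic, x_hat, sigma = 10) {
  check_image_batch(x_hat, "x_hat")
  gi <- critic_input_grads(critic, to_nn(x_hat))
  if (any(!is.finite(gi$norms))) {
    stop_input("non-finite critic gradients in penalty", "cytosynth_numerical_error")
  }
  sigma * mean((gi$norms - 1)^2)
}

# Penalty value plus its gradient wrt the critic weights.
#
# d||g||/dtheta = v' dg/dtheta at v = g/||g|| (envelope theorem), and the
# directional derivative v' grad_x D is differentiated wrt the weights via a
# central finite difference in input space: two extra first-order backward
# passes, truncation error O(eps_fd^2).
gp_value_and_grads <- function(critic, x_hat_nn, sigma, eps_fd = 1e-3) {
  n <- dim(x_hat_nn)[4L]
  gi <- critic_input_grads(critic, x_hat_nn)
  norms <- pmax(gi$norms, 1e-12)
  value <- sigma * mean((gi$norms - 1)^2)
  v <- gi$g / array(rep(norms, each = prod(dim(x_hat_nn)[1:3])), dim(x_hat_nn))
  a <- 2 * sigma * (gi$norms - 1) / n      # d penalty / d (v' g) per sample
  w <- a / (2 * eps_fd)
  fp <- critic_forward(critic, x_hat_nn + eps_fd * v)
  gp_plus <- critic_backward(fp$critic, fp$cache, d_source = w)$grads
  fm <- critic_forward(critic, x_hat_nn - eps_fd * v)
  gp_minus <- critic_backward(fm$critic, fm$cache, d_source = -w)$grads
  list(value = value, grads = grad_tree_add(gp_plus, gp_minus))
}

# numerically stable log(sigmoid(x))
log_sigmoid <- function(x) ifelse(x > 0, -log1p(exp(-x)), x - log1p(exp(x)))

# cross-entropy from logits; labels 0-based. Returns mean -log p and the
# gradient of that mean wrt the logits.
ce_from_logits <- function(logits, labels) {
  labels <- check_labels(labels, ncol(logits))
  p <- softmax_rows(logits)
  idx <- cbind(seq_len(nrow(logits)), labels + 1L)
  nll <- -log(pmax(p[idx], 1e-300))
  onehot <- matrix(0, nrow(logits), ncol(logits))
  onehot[idx] <- 1
  list(loss = mean(nll), dlogits = (p - onehot) / nrow(logits), prob = p)
}

#' Source and class log-likelihoods of the auxiliary-classifier objective
#'
#' The class term `C_L` is the mean log-probability the auxiliary classifier
#' assigns to the true class on real images plus the same on generated
#' images (whose "true" class is the label the generator was conditioned
#' on). The source term of the adversarial game is carried by the
#' Wasserstein scores, which are unbounded, so `S_L` is reported for
#' monitoring only, through a logistic map of the source score.
#'
#' @param critic_out_real,critic_out_fake Lists with `source_score` and
#'   `class_logits` as returned by [critic_scores()].
#' @param labels_real,labels_fake 0-based class labels of the real batch and
#'   of the generator conditioning.
#' @return A list with `S_L` and `C_L` (both log-likelihoods, `<= 0`).
#' @export
source_class_loglik <- function(critic_out_real, critic_out_fake,
                                labels_real, labels_fake) {
  ce_r <- ce_from_logits(critic_out_real$class_logits, labels_real)
  ce_f <- ce_from_logits(critic_out_fake$class_logits, labels_fake)
  s_l <- mean(log_sigmoid(critic_out_real$source_score)) +
    mean(log_sigmoid(-critic_out_fake$source_score))
  list(S_L = s_l, C_L = -(ce_r$loss + ce_f$loss))
}

#' Evaluate every loss term of the hybrid objective on a pair of batches
#'
#' Computes the Wasserstein critic loss, the gradient penalty at random
#' interpolates, the class cross-entropies on real and generated images, and
#' the generator-side terms, together with the combined critic and generator
#' objectives: `critic_total = wasserstein + penalty +
#' lambda_cls * (class_real + class_fake)` and `generator_total =
#' -mean(D(fake)) + lambda_cls * class_fake`.
#'
#' @param real,fake Batches (lists with `images` in `[-1, 1]` and 0-based
#'   `labels`), e.g. from [generate_images()].
#' @param critic A [build_critic()] object.
#' @param cfg A [train_config()]; `sigma` and `lambda_cls` are used.
#' @param seed Seed for the interpolation draw.
#' @return A one-row tibble of loss terms.
#' @export
total_losses <- function(real, fake, critic, cfg = train_config(), seed = NULL) {
  out_r <- critic_scores(critic, real$images)
  out_f <- critic_scores(critic, fake$images)
  w <- critic_wasserstein_loss(out_r$source_score, out_f$source_score)
  x_hat <- interpolate_images(real$images, fake$images, seed = seed)
  gp <- gradient_penalty(critic, x_hat, sigma = cfg$sigma)
  ce_r <- ce_from_logits(out_r$class_logits, real$labels)
  ce_f <- ce_from_logits(out_f$class_logits, fake$labels)
  tibble(
    critic_wasserstein = w,
    gradient_penalty = gp,
    class_loss_real = ce_r$loss,
    class_loss_fake = ce_f$loss,
    generator_adversarial = -mean(out_f$source_score),
    generator_class = ce_f$loss,
    critic_total = w + gp + cfg$lambda_cls * (ce_r$loss + ce_f$loss),
    generator_total = -mean(out_f$source_score) + cfg$lambda_cls * ce_f$loss
  )
}
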