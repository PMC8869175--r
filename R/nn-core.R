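# Parameter-tree utilities and the Adam optimizer.
#
# Networks are nested named lists whose leaves are layers (lists carrying a
# `par` list of numeric arrays). Gradient trees produced by the backward
# passes mirror the network structure, so a single recursive walk applies
# optimizer updates.

is_layer <- function(x) is.list(x) && !is.null(x$kind) && !is.null(x$par)

is_layer_container <- function(x) {
  is.list(x) && !is_layer(x) && !inherits(x, "gan_config")
}

# f(layer, gradlist, statelist) -> list(layer, state); walks net and grads
# in lockstep, building/consuming an optimizer state tree of the same shape.
tree_walk <- function(net, grads, state, f) {
  if (is_layer(net)) {
    if (is.null(state)) state <- list()
    out <- f(net, grads, state)
    return(out)
  }
  if (is.null(state)) {
    state <- vector("list", length(net))
    names(state) <- names(net)
  }
  keys <- if (!is.null(names(net)) && all(names(net) != "")) names(net) else seq_along(net)
  for (k in keys) {
    child <- net[[k]]
    g <- tryCatch(grads[[k]], error = function(e) NULL)
    if (!is.null(g) && (is_layer_container(child) || is_layer(child))) {
      out <- tree_walk(child, g, state[[k]], f)
      net[[k]] <- out$net
      state[[k]] <- out$state
    }
  }
  list(net = net, state = state)
}

# sum of squares over all gradient leaves; NA/NaN propagates
grad_global_norm <- function(grads) {
  total <- 0
  walk <- function(g) {
    if (is.numeric(g)) {
      total <<- total + sum(g^2)
    } else if (is.list(g)) {
      lapply(g, walk)
    }
  }
  walk(grads)
  sqrt(total)
}

adam_new <- function(lr = 1e-3, beta1 = 0.5, beta2 = 0.9, eps = 1e-8) {
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L, state = NULL)
}

# One Adam step over every parameter leaf; returns updated net + optimizer.
adam_step <- function(net, grads, opt) {
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  corr1 <- 1 - b1^opt$t
  corr2 <- 1 - b2^opt$t
  lr <- opt$lr; eps <- opt$eps
  f <- function(layer, g, st) {
    for (nm in names(layer$par)) {
      gv <- g[[nm]]
      if (is.null(gv)) next
      if (is.null(st[[nm]])) st[[nm]] <- list(m = gv * 0, v = gv * 0)
      st[[nm]]$m <- b1 * st[[nm]]$m + (1 - b1) * gv
      st[[nm]]$v <- b2 * st[[nm]]$v + (1 - b2) * gv^2
      mhat <- st[[nm]]$m / corr1
      vhat <- st[[nm]]$v / corr2
      layer$par[[nm]] <- layer$par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
    list(net = layer, state = st)
  }
  out <- tree_walk(net, grads, opt$state, f)
  opt$state <- out$state
  list(net = out$net, opt = opt)
}

# elementwise sum of two gradient trees of identical shape
grad_tree_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (is.numeric(a)) return(a + b)
  for (i in seq_along(a)) a[[i]] <- grad_tree_add(a[[i]], b[[i]])
  a
}

grad_tree_scale <- function(a, s) {
  if (is.null(a)) return(NULL)
  if (is.numeric(a)) return(a * s)
  lapply(a, grad_tree_scale, s = s)
}
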