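# A small feed-forward network for tabular regression/classification:
# ReLU hidden layers, linear (regression) or sigmoid (binary
# classification) output, full-batch Adam, early stopping on a 10%
# validation split. Written in plain matrix algebra; problem sizes here are
# a few hundred rows by a few dozen columns, where this trains in well
# under a second.

#' The thirteen multilayer-perceptron hidden-layer layouts
#'
#' Layouts indexed 1-13, from (20, 10, 5) up to the deepest
#' (160, 80, 40, 40, 40, 40, 20, 10).
#'
#' @param variant Integer 1-13.
#' @return Integer vector of hidden-layer widths.
#' @export
mlp_layout <- function(variant) {
  layouts <- list(
    c(20, 10, 5), c(40, 20, 10, 5), c(60, 30, 15, 7),
    c(80, 40, 20, 10, 5), c(100, 50, 25, 12, 6), c(120, 60, 30, 15, 7),
    c(140, 70, 35, 17, 8), c(160, 80, 40, 20, 10),
    c(80, 40, 20, 20, 20, 20, 10, 5), c(100, 50, 25, 25, 25, 25, 12, 6),
    c(120, 60, 30, 30, 30, 30, 15, 7), c(140, 70, 35, 35, 35, 35, 17, 8),
    c(160, 80, 40, 40, 40, 40, 20, 10))
  if (!variant %in% seq_along(layouts)) {
    abort("MLP variant must be an integer in 1..13")
  }
  layouts[[variant]]
}

mlp_init <- function(sizes, seed) {
  with_seed(seed, {
    lapply(seq_len(length(sizes) - 1), function(i) {
      fan_in <- sizes[i]
      list(W = matrix(stats::rnorm(fan_in * sizes[i + 1], 0,
                                   sqrt(2 / fan_in)),
                      fan_in, sizes[i + 1]),
           b = rep(0, sizes[i + 1]))
    })
  })
}

mlp_forward <- function(layers, X, classification) {
  acts <- vector("list", length(layers) + 1)
  acts[[1]] <- X
  for (i in seq_along(layers)) {
    z <- acts[[i]] %*% layers[[i]]$W +
      matrix(layers[[i]]$b, nrow(X), length(layers[[i]]$b), byrow = TRUE)
    acts[[i + 1]] <- if (i < length(layers)) pmax(z, 0) else z
  }
  out <- acts[[length(acts)]]
  if (classification) out <- 1 / (1 + exp(-out))
  list(acts = acts, out = out)
}

mlp_backward <- function(layers, acts, out, y, classification) {
  n <- nrow(out)
  # dL/dz_out: identical form for MSE/linear and log-loss/sigmoid
  delta <- (out - y) / n
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    grads[[i]] <- list(W = crossprod(acts[[i]], delta),
                       b = colSums(delta))
    if (i > 1) {
      delta <- (delta %*% t(layers[[i]]$W)) * (acts[[i]] > 0)
    }
  }
  grads
}

# full-batch Adam with early stopping; X scaled beforehand by the caller
mlp_train <- function(X, y, hidden, classification = FALSE, seed = 1,
                      max_iter = 2000, lr = 0.01, patience = 40,
                      val_fraction = 0.1, l2 = 1e-4) {
  sizes <- c(ncol(X), hidden, 1L)
  layers <- mlp_init(sizes, seed)
  n <- nrow(X)
  n_val <- max(1L, floor(val_fraction * n))
  idx <- with_seed(child_seed(seed, "val"), sample.int(n))
  vi <- idx[seq_len(n_val)]; ti <- idx[-seq_len(n_val)]
  Xt <- X[ti, , drop = FALSE]; yt <- y[ti]
  Xv <- X[vi, , drop = FALSE]; yv <- y[vi]
  m <- lapply(layers, function(l) list(W = l$W * 0, b = l$b * 0))
  v <- m
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  best <- Inf; best_layers <- layers; wait <- 0L
  for (it in seq_len(max_iter)) {
    fw <- mlp_forward(layers, Xt, classification)
    grads <- mlp_backward(layers, fw$acts, fw$out, yt, classification)
    for (i in seq_along(layers)) {
      for (nm in c("W", "b")) {
        g <- grads[[i]][[nm]] + l2 * layers[[i]][[nm]]
        m[[i]][[nm]] <- b1 * m[[i]][[nm]] + (1 - b1) * g
        v[[i]][[nm]] <- b2 * v[[i]][[nm]] + (1 - b2) * g^2
        mh <- m[[i]][[nm]] / (1 - b1^it)
        vh <- v[[i]][[nm]] / (1 - b2^it)
        layers[[i]][[nm]] <- layers[[i]][[nm]] - lr * mh / (sqrt(vh) + eps)
      }
    }
    vo <- mlp_forward(layers, Xv, classification)$out
    val_loss <- if (classification) {
      p <- pmin(pmax(vo, 1e-12), 1 - 1e-12)
      -mean(yv * log(p) + (1 - yv) * log(1 - p))
    } else mean((vo - yv)^2)
    if (val_loss < best - 1e-9) {
      best <- val_loss; best_layers <- layers; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }
  list(layers = best_layers, classification = classification,
       val_loss = best, n_iter = it)
}

mlp_predict <- function(fit, X) {
  as.numeric(mlp_forward(fit$layers, X, fit$classification)$out)
}
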