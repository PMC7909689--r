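# Multilayer perceptron for binary text classification. The network is
# authored directly in matrix code: fully-connected ReLU hidden layers
# with optional (inverted) dropout, a single sigmoid output unit,
# binary cross-entropy loss, ADAM updates, and best-epoch weight
# restoration keyed on internal-validation accuracy. Keeping the
# forward/backward pass in-package is what makes exact input gradients
# (saliency) and leakage-style audits straightforward.

#' Specify an MLP architecture
#'
#' @param hidden Integer vector of hidden-layer widths (at least one).
#' @param dropout Per-hidden-layer dropout rates in `[0, 1)`, recycled to
#'   the number of hidden layers. Dropout is applied to hidden
#'   activations during training only (inverted dropout, so inference
#'   needs no rescaling).
#' @param id Label for the architecture; defaults to a string such as
#'   `"mlp_128x64_d0.5"`.
#' @return A list of class `"mlp_spec"`.
#' @export
mlp_spec <- function(hidden = 64L, dropout = 0, id = NULL) {
  hidden <- as.integer(hidden)
  if (length(hidden) < 1L || any(hidden < 1L)) {
    stop("`hidden` must list at least one positive layer width", call. = FALSE)
  }
  dropout <- rep_len(as.numeric(dropout), length(hidden))
  if (any(dropout < 0) || any(dropout >= 1)) {
    stop("`dropout` rates must lie in [0, 1)", call. = FALSE)
  }
  id <- id %||% sprintf("mlp_%s_d%s", paste(hidden, collapse = "x"),
                        paste(unique(dropout), collapse = "/"))
  structure(list(id = id, hidden = hidden, dropout = dropout),
            class = "mlp_spec")
}

#' Default architecture grid
#'
#' Eight architectures spanning one and two hidden layers with and
#' without dropout: widths `{64}, {128}, {64,32}, {128,64}` crossed with
#' dropout `{0, 0.5}`. This is the configurable stand-in for a published
#' hyperparameter table; all widths and rates can be overridden by
#' constructing [mlp_spec()]s directly.
#'
#' @return A named list of `"mlp_spec"` objects.
#' @export
default_architectures <- function() {
  widths <- list(64L, 128L, c(64L, 32L), c(128L, 64L))
  specs <- list()
  for (w in widths) {
    for (d in c(0, 0.5)) {
      s <- mlp_spec(hidden = w, dropout = d)
      specs[[s$id]] <- s
    }
  }
  specs
}

#' Training parameters
#'
#' @param epochs Number of training epochs (default 25, the setting used
#'   for bag-of-words and rules-based encodings; word-embedding inputs
#'   typically need 50).
#' @param batch_size Minibatch size (default 32).
#' @param learning_rate ADAM step size (default 1e-3, the ADAM default).
#' @param val_fraction Fraction of the training rows held out as the
#'   internal validation set used to pick the best epoch (default 0.10);
#'   must be strictly inside (0, 1).
#' @param seed Integer seed controlling the validation split, weight
#'   initialization, minibatch order and dropout masks.
#' @return A list of class `"mlp_control"`.
#' @export
mlp_control <- function(epochs = 25L, batch_size = 32L, learning_rate = 1e-3,
                        val_fraction = 0.10, seed = 1L) {
  epochs <- assert_count(epochs, "epochs", min = 1L)
  batch_size <- assert_count(batch_size, "batch_size", min = 1L)
  if (!is.finite(val_fraction) || val_fraction <= 0 || val_fraction >= 1) {
    stop("`val_fraction` must lie strictly inside (0, 1)", call. = FALSE)
  }
  stopifnot(is.finite(learning_rate), learning_rate > 0)
  structure(list(epochs = epochs, batch_size = batch_size,
                 learning_rate = learning_rate, val_fraction = val_fraction,
                 seed = as.integer(seed)),
            class = "mlp_control")
}

sigmoid <- function(z) 1 / (1 + exp(-z))

init_weights <- function(dims) {
  lapply(seq_len(length(dims) - 1L), function(l) {
    fan_in <- dims[l]; fan_out <- dims[l + 1L]
    lim <- sqrt(6 / (fan_in + fan_out))
    list(W = matrix(runif(fan_in * fan_out, -lim, lim), fan_in, fan_out),
         b = numeric(fan_out))
  })
}

# Forward pass. Returns the output probabilities and, when `keep = TRUE`,
# the pre-activations and activations needed for backprop.
mlp_forward <- function(weights, x, dropout = NULL, keep = FALSE) {
  L <- length(weights)
  a <- x
  zs <- vector("list", L)
  as <- vector("list", L + 1L)
  masks <- vector("list", L - 1L)
  as[[1L]] <- a
  for (l in seq_len(L)) {
    z <- sweep(a %*% weights[[l]]$W, 2L, weights[[l]]$b, "+")
    zs[[l]] <- z
    if (l < L) {
      a <- pmax(z, 0)
      if (!is.null(dropout) && dropout[l] > 0) {
        mask <- matrix(runif(length(a)) >= dropout[l], nrow(a), ncol(a))
        a <- a * mask / (1 - dropout[l])
        masks[[l]] <- mask
      }
      as[[l + 1L]] <- a
    } else {
      a <- sigmoid(z)
    }
  }
  p <- as.vector(a)
  if (!keep) return(p)
  list(p = p, zs = zs, as = as, masks = masks, dropout = dropout)
}

bce_loss <- function(p, y) {
  eps <- 1e-12
  -mean(y * log(pmax(p, eps)) + (1 - y) * log(pmax(1 - p, eps)))
}

accuracy_at <- function(p, y, threshold = 0.5) mean((p >= threshold) == y)

# Single ADAM step over one minibatch; returns updated weights and state.
mlp_backward <- function(weights, fw, y) {
  L <- length(weights)
  n <- length(y)
  grads <- vector("list", L)
  delta <- matrix((fw$p - y) / n, ncol = 1L)   # dL/dz at the sigmoid unit
  for (l in rev(seq_len(L))) {
    a_prev <- fw$as[[l]]
    grads[[l]] <- list(W = crossprod(a_prev, delta),
                       b = colSums(delta))
    if (l > 1L) {
      delta <- delta %*% t(weights[[l]]$W)
      if (!is.null(fw$dropout) && fw$dropout[l - 1L] > 0 &&
          !is.null(fw$masks[[l - 1L]])) {
        delta <- delta * fw$masks[[l - 1L]] / (1 - fw$dropout[l - 1L])
      }
      delta <- delta * (fw$zs[[l - 1L]] > 0)
    }
  }
  grads
}

adam_init <- function(weights) {
  lapply(weights, function(w) list(
    mW = w$W * 0, vW = w$W * 0, mb = w$b * 0, vb = w$b * 0))
}

adam_step <- function(weights, grads, state, t, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (l in seq_along(weights)) {
    g <- grads[[l]]
    s <- state[[l]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$W
    s$vW <- beta2 * s$vW + (1 - beta2) * g$W^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    mW_hat <- s$mW / (1 - beta1^t); vW_hat <- s$vW / (1 - beta2^t)
    mb_hat <- s$mb / (1 - beta1^t); vb_hat <- s$vb / (1 - beta2^t)
    weights[[l]]$W <- weights[[l]]$W - lr * mW_hat / (sqrt(vW_hat) + eps)
    weights[[l]]$b <- weights[[l]]$b - lr * mb_hat / (sqrt(vb_hat) + eps)
    state[[l]] <- s
  }
  list(weights = weights, state = state)
}

# Earliest index of the maximum validation accuracy (ties -> earliest).
pick_best_epoch <- function(val_accuracy) which.max(val_accuracy)

new_trained_mlp <- function(weights, spec, control, best_epoch, history,
                            val_idx, input_dim) {
  n_par <- sum(vapply(weights, function(w) length(w$W) + length(w$b),
                      numeric(1)))
  structure(list(weights = weights, spec = spec, control = control,
                 best_epoch = best_epoch, history = history,
                 val_idx = val_idx, input_dim = input_dim,
                 n_parameters = n_par),
            class = "trained_mlp")
}

#' Train an MLP classifier
#'
#' Holds out `val_fraction` of the rows as an internal validation set
#' (drawn once, fixed across epochs), trains for exactly
#' `control$epochs` epochs with minibatch ADAM on binary cross-entropy,
#' and restores the weights from the epoch with the highest internal
#' validation accuracy (earliest epoch on ties). Training past the
#' overfitting inflection and then selecting the best validation epoch
#' is the overfitting guard used throughout the package's protocols.
#'
#' @param x Numeric feature matrix (rows = records).
#' @param y Binary labels (0/1), aligned with the rows of `x`.
#' @param spec An [mlp_spec()].
#' @param control An [mlp_control()].
#' @return An object of class `"trained_mlp"` with the restored weights,
#'   `best_epoch`, a per-epoch `history` tibble (train/validation loss
#'   and accuracy), the validation row indices and the parameter count.
#' @export
train_mlp <- function(x, y, spec = mlp_spec(), control = mlp_control()) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  stopifnot(nrow(x) == length(y), all(y %in% c(0, 1)))
  if (length(unique(y)) < 2L) {
    stop("training data contain a single class", call. = FALSE)
  }
  stopifnot(inherits(spec, "mlp_spec"), inherits(control, "mlp_control"))
  n <- nrow(x)
  withr::local_seed(control$seed)
  n_val <- max(1L, round(control$val_fraction * n))
  if (n_val >= n) stop("validation split leaves no training rows", call. = FALSE)
  val_idx <- sort(sample.int(n, n_val))
  tr_idx <- setdiff(seq_len(n), val_idx)
  if (length(unique(y[tr_idx])) < 2L) {
    stop("internal training portion contains a single class", call. = FALSE)
  }
  dims <- c(ncol(x), spec$hidden, 1L)
  weights <- init_weights(dims)
  state <- adam_init(weights)
  t_step <- 0L
  hist <- vector("list", control$epochs)
  best_acc <- -Inf
  best_weights <- weights
  best_epoch <- 1L
  x_tr <- x[tr_idx, , drop = FALSE]; y_tr <- y[tr_idx]
  x_val <- x[val_idx, , drop = FALSE]; y_val <- y[val_idx]
  for (epoch in seq_len(control$epochs)) {
    ord <- sample(length(tr_idx))
    batches <- split(ord, ceiling(seq_along(ord) / control$batch_size))
    for (b in batches) {
      fw <- mlp_forward(weights, x_tr[b, , drop = FALSE],
                        dropout = spec$dropout, keep = TRUE)
      grads <- mlp_backward(weights, fw, y_tr[b])
      t_step <- t_step + 1L
      upd <- adam_step(weights, grads, state, t_step, control$learning_rate)
      weights <- upd$weights
      state <- upd$state
    }
    p_tr <- mlp_forward(weights, x_tr)
    p_val <- mlp_forward(weights, x_val)
    tr_loss <- bce_loss(p_tr, y_tr); val_loss <- bce_loss(p_val, y_val)
    if (!is.finite(tr_loss) || !is.finite(val_loss)) {
      stop(sprintf(
        "non-finite loss at epoch %d (train %.4g, val %.4g); lower the learning rate or rescale the features",
        epoch, tr_loss, val_loss), call. = FALSE)
    }
    val_acc <- accuracy_at(p_val, y_val)
    hist[[epoch]] <- tibble(
      epoch = epoch, train_loss = tr_loss,
      train_accuracy = accuracy_at(p_tr, y_tr),
      val_loss = val_loss, val_accuracy = val_acc)
    if (val_acc > best_acc) {
      best_acc <- val_acc
      best_weights <- weights
      best_epoch <- epoch
    }
  }
  history <- bind_rows(hist)
  stopifnot(best_epoch == pick_best_epoch(history$val_accuracy))
  new_trained_mlp(best_weights, spec, control, best_epoch, history,
                  val_idx, ncol(x))
}

#' Predict abuse probabilities from a trained MLP
#'
#' Deterministic given the stored weights: dropout is inactive at
#' inference and no randomness is consumed.
#'
#' @param object A `"trained_mlp"`.
#' @param newdata Numeric feature matrix with the width the model was
#'   trained on.
#' @param ... Unused.
#' @return Numeric vector of probabilities in (0, 1), one per row.
#' @export
predict.trained_mlp <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$input_dim) {
    stop(sprintf("feature width %d does not match model input width %d",
                 ncol(newdata), object$input_dim), call. = FALSE)
  }
  storage.mode(newdata) <- "double"
  mlp_forward(object$weights, newdata)
}

#' Gradient of the predicted probability with respect to the input
#'
#' Exact analytic backpropagation of the positive-class probability to
#' the input features, the quantity behind word-saliency analyses.
#'
#' @param model A `"trained_mlp"`.
#' @param x Numeric feature matrix (rows = records).
#' @return A matrix of the same shape as `x`: `d p / d x` evaluated at
#'   each row.
#' @export
input_gradient <- function(model, x) {
  stopifnot(inherits(model, "trained_mlp"))
  x <- as.matrix(x)
  if (ncol(x) != model$input_dim) {
    stop(sprintf("feature width %d does not match model input width %d",
                 ncol(x), model$input_dim), call. = FALSE)
  }
  storage.mode(x) <- "double"
  weights <- model$weights
  fw <- mlp_forward(weights, x, keep = TRUE)
  L <- length(weights)
  delta <- matrix(fw$p * (1 - fw$p), ncol = 1L)   # d p / d z_out
  for (l in rev(seq_len(L))) {
    delta <- delta %*% t(weights[[l]]$W)
    if (l > 1L) delta <- delta * (fw$zs[[l - 1L]] > 0)
  }
  dimnames(delta) <- dimnames(x)
  delta
}

#' @export
print.trained_mlp <- function(x, ...) {
  cat(sprintf(
    "<trained_mlp> %s: input %d, %s parameters; best epoch %d/%d (val acc %.3f)\n",
    x$spec$id, x$input_dim, format(x$n_parameters, big.mark = ","),
    x$best_epoch, nrow(x$history), x$history$val_accuracy[x$best_epoch]))
  invisible(x)
}
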