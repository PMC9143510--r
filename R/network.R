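# Deep feedforward classifier: ELU hidden layers with optional dropout,
# softmax output, Adam on the cross-entropy loss. Implemented directly with
# matrix algebra so the whole training path is seeded and reproducible.

#' Network architecture and training hyperparameters
#'
#' Defaults are the tool's shipped settings: 10 hidden layers of 25 neurons,
#' dropout enabled at rate 0.5, learning rate 3e-5, weight decay 0, batch
#' size 50, 20 epochs.
#'
#' @param n_layers number of hidden linear layers (the output layer is
#'   additional).
#' @param n_neurons width of every hidden layer.
#' @param dropout_enabled place a dropout layer after each hidden
#'   activation?
#' @param dropout_rate dropout probability in (0, 1).
#' @param learning_rate Adam learning rate.
#' @param weight_decay L2 penalty coupled into the gradient.
#' @param batch_size mini-batch size (the last batch of an epoch may be
#'   smaller).
#' @param epochs number of training epochs.
#' @param seed integer seed for initialization, shuffling and dropout.
#' @return A `network_config` list.
#' @export
network_config <- function(n_layers = 10L, n_neurons = 25L,
                           dropout_enabled = TRUE, dropout_rate = 0.5,
                           learning_rate = 0.00003, weight_decay = 0.0,
                           batch_size = 50L, epochs = 20L, seed = 1L) {
  stopifnot(n_layers >= 1, n_neurons >= 1,
            dropout_rate > 0, dropout_rate < 1,
            learning_rate > 0, weight_decay >= 0,
            batch_size >= 1, epochs >= 1)
  structure(list(n_layers = as.integer(n_layers),
                 n_neurons = as.integer(n_neurons),
                 dropout_enabled = isTRUE(dropout_enabled),
                 dropout_rate = dropout_rate,
                 learning_rate = learning_rate,
                 weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 seed = as.integer(seed)),
            class = "network_config")
}

#' Build an untrained network
#'
#' Architecture: `linear(n_features -> n_neurons)`, then `n_layers - 1`
#' square hidden linears, each hidden linear followed by an ELU activation
#' and (when enabled) a dropout layer, then a final
#' `linear(n_neurons -> n_classes)` whose softmax is applied at prediction
#' time. Hidden weights draw from a seeded He-scaled normal
#' (sd = sqrt(2/fan_in)); the output layer starts at zero so an untrained
#' network predicts uniform class probabilities.
#'
#' @param config a [network_config()].
#' @param n_features input width (number of retained taxa).
#' @param n_classes number of classes (>= 2).
#' @return A `phenodnn_network`: layer list (`W`, `b`) plus dimensions.
#' @export
build_network <- function(config, n_features, n_classes) {
  stopifnot(n_features >= 1)
  if (n_classes < 2) stop("need at least 2 classes", call. = FALSE)
  dims <- c(n_features, rep(config$n_neurons, config$n_layers), n_classes)
  n_lin <- length(dims) - 1L
  layers <- withr::with_seed(config$seed, {
    lapply(seq_len(n_lin), function(i) {
      W <- if (i == n_lin) {
        matrix(0, dims[i], dims[i + 1L])
      } else {
        matrix(stats::rnorm(dims[i] * dims[i + 1L], 0, sqrt(2 / dims[i])),
               dims[i], dims[i + 1L])
      }
      list(W = W, b = numeric(dims[i + 1L]))
    })
  })
  structure(list(layers = layers, config = config,
                 n_features = as.integer(n_features),
                 n_classes = as.integer(n_classes)),
            class = "phenodnn_network")
}

#' Number of trainable parameters
#' @param network a `phenodnn_network` (or trained model).
#' @return Integer: sum over layers of `(fan_in + 1) * fan_out`.
#' @export
count_parameters <- function(network) {
  layers <- if (inherits(network, "phenodnn_model")) network$network$layers
            else network$layers
  sum(vapply(layers, function(l) length(l$W) + length(l$b), 0))
}

elu <- function(z) ifelse(z > 0, z, expm1(pmin(z, 0)))

# forward pass; when training = TRUE dropout masks are drawn from the
# current RNG stream and the per-layer cache for backprop is returned
forward_pass <- function(layers, X, config, training = FALSE) {
  n_lin <- length(layers)
  acts <- vector("list", n_lin + 1L); acts[[1L]] <- X
  masks <- vector("list", n_lin)
  a <- X
  for (i in seq_len(n_lin)) {
    z <- a %*% layers[[i]]$W
    z <- sweep(z, 2, layers[[i]]$b, "+")
    if (i < n_lin) {
      a <- elu(z)
      if (training && config$dropout_enabled) {
        keep <- 1 - config$dropout_rate
        m <- matrix((stats::runif(length(a)) < keep) / keep,
                    nrow(a), ncol(a))
        a <- a * m
        masks[[i]] <- m
      }
    } else {
      a <- z
    }
    acts[[i + 1L]] <- a
  }
  list(logits = a, acts = acts, masks = masks)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

log_softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  z - log(rowSums(exp(z)))
}

#' Train a network with Adam on the cross-entropy loss
#'
#' Mini-batch gradient descent (seeded per-epoch shuffling, last batch may
#' be smaller) with the Adam optimizer at the configured learning rate and
#' weight decay. Dropout is active only during training. The returned
#' weights are those of the best epoch by validation accuracy (ties broken
#' toward the earliest epoch); with no validation data the final epoch's
#' weights are kept.
#'
#' @param network an untrained [build_network()] result.
#' @param train_features,train_labels training matrix and 0-based integer
#'   labels.
#' @param val_features,val_labels optional validation data (NULL for none).
#' @param config a [network_config()]; defaults to the network's own.
#' @return List with `network` (trained) and `history` (a
#'   `training_history`: per-epoch `train_loss`, `train_accuracy`,
#'   `validation_accuracy`, plus `best_epoch`).
#' @export
train_network <- function(network, train_features, train_labels,
                          val_features = NULL, val_labels = NULL,
                          config = network$config) {
  n <- nrow(train_features)
  if (n == 0L) stop("empty training set", call. = FALSE)
  stopifnot(length(train_labels) == n)
  if (ncol(train_features) != network$n_features) {
    stop("feature width mismatch: expected ", network$n_features,
         ", got ", ncol(train_features), call. = FALSE)
  }
  if (any(train_labels < 0 | train_labels >= network$n_classes)) {
    stop("label index out of range", call. = FALSE)
  }
  layers <- network$layers
  n_lin <- length(layers)
  # Adam state
  mW <- lapply(layers, function(l) l$W * 0); vW <- mW
  mb <- lapply(layers, function(l) l$b * 0); vb <- mb
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; t_step <- 0L
  has_val <- !is.null(val_features) && nrow(val_features) > 0L
  hist <- data.frame(epoch = seq_len(config$epochs), train_loss = NA_real_,
                     train_accuracy = NA_real_,
                     validation_accuracy = NA_real_)
  best <- list(acc = -Inf, epoch = NA_integer_, layers = NULL)
  withr::with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      perm <- sample.int(n)
      starts <- seq(1L, n, by = config$batch_size)
      batch_losses <- numeric(length(starts))
      for (bi in seq_along(starts)) {
        idx <- perm[starts[bi]:min(starts[bi] + config$batch_size - 1L, n)]
        X <- train_features[idx, , drop = FALSE]
        y <- train_labels[idx]
        fw <- forward_pass(layers, X, config, training = TRUE)
        lsm <- log_softmax_rows(fw$logits)
        loss <- -mean(lsm[cbind(seq_along(y), y + 1L)])
        if (!is.finite(loss)) {
          stop("diverged (non-finite loss) at epoch ", epoch, call. = FALSE)
        }
        batch_losses[bi] <- loss
        # backprop
        g <- exp(lsm)
        g[cbind(seq_along(y), y + 1L)] <- g[cbind(seq_along(y), y + 1L)] - 1
        g <- g / length(y)
        t_step <- t_step + 1L
        for (i in rev(seq_len(n_lin))) {
          gW <- crossprod(fw$acts[[i]], g)
          gb <- colSums(g)
          if (config$weight_decay > 0) {
            gW <- gW + config$weight_decay * layers[[i]]$W
          }
          if (i > 1L) {
            g <- g %*% t(layers[[i]]$W)
            a_prev <- fw$acts[[i]]
            g <- g * ifelse(a_prev > 0, 1, a_prev + 1)  # ELU'
            if (!is.null(fw$masks[[i - 1L]])) g <- g * fw$masks[[i - 1L]]
          }
          mW[[i]] <- b1 * mW[[i]] + (1 - b1) * gW
          vW[[i]] <- b2 * vW[[i]] + (1 - b2) * gW * gW
          mb[[i]] <- b1 * mb[[i]] + (1 - b1) * gb
          vb[[i]] <- b2 * vb[[i]] + (1 - b2) * gb * gb
          mhW <- mW[[i]] / (1 - b1^t_step); vhW <- vW[[i]] / (1 - b2^t_step)
          mhb <- mb[[i]] / (1 - b1^t_step); vhb <- vb[[i]] / (1 - b2^t_step)
          layers[[i]]$W <- layers[[i]]$W -
            config$learning_rate * mhW / (sqrt(vhW) + eps)
          layers[[i]]$b <- layers[[i]]$b -
            config$learning_rate * mhb / (sqrt(vhb) + eps)
        }
      }
      hist$train_loss[epoch] <- mean(batch_losses)
      tr_pred <- max.col(forward_pass(layers, train_features, config)$logits,
                         ties.method = "first") - 1L
      hist$train_accuracy[epoch] <- mean(tr_pred == train_labels)
      if (has_val) {
        va_pred <- max.col(forward_pass(layers, val_features, config)$logits,
                           ties.method = "first") - 1L
        acc <- mean(va_pred == val_labels)
        hist$validation_accuracy[epoch] <- acc
        if (acc > best$acc) best <- list(acc = acc, epoch = epoch,
                                         layers = layers)
      }
    }
  })
  if (has_val) {
    layers <- best$layers
    best_epoch <- best$epoch
  } else {
    best_epoch <- config$epochs
  }
  network$layers <- layers
  history <- structure(list(epochs = hist, best_epoch = best_epoch),
                       class = "training_history")
  list(network = network, history = history)
}

#' Class probabilities for new samples
#'
#' Softmax over the network's logits; dropout inactive. Rows sum to 1.
#'
#' @param model a `phenodnn_network` or trained `phenodnn_model`.
#' @param features matrix whose width equals the model's input width.
#' @return M x N probability matrix (N = number of classes).
#' @export
predict_proba <- function(model, features) {
  net <- if (inherits(model, "phenodnn_model")) model$network else model
  features <- as.matrix(features)
  if (ncol(features) != net$n_features) {
    stop("feature width mismatch: expected ", net$n_features, ", got ",
         ncol(features), call. = FALSE)
  }
  p <- softmax_rows(forward_pass(net$layers, features, net$config)$logits)
  colnames(p) <- if (inherits(model, "phenodnn_model")) model$labels$label_order
  p
}

#' Predicted class labels
#'
#' Argmax of [predict_proba()], ties broken toward the lowest class index;
#' indices are mapped through the stored label encoding when the model
#' carries one.
#'
#' @inheritParams predict_proba
#' @return Character vector of labels (or 0-based integer indices for a
#'   bare network).
#' @export
predict_label <- function(model, features) {
  p <- predict_proba(model, features)
  idx <- max.col(p, ties.method = "first") - 1L
  if (inherits(model, "phenodnn_model")) {
    model$labels$label_order[idx + 1L]
  } else {
    idx
  }
}

#' @export
print.phenodnn_network <- function(x, ...) {
  cat("<phenodnn_network> ", x$n_features, " -> ",
      paste(rep(x$config$n_neurons, x$config$n_layers), collapse = " -> "),
      " -> ", x$n_classes, " (", count_parameters(x), " parameters)\n",
      sep = "")
  invisible(x)
}

#' @export
print.training_history <- function(x, ...) {
  cat("<training_history> ", nrow(x$epochs), " epochs, best epoch ",
      x$best_epoch, "\n", sep = "")
  print(utils::tail(x$epochs, 3))
  invisible(x)
}
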