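# Randomized hyperparameter search over bounded ranges with
# validation-accuracy early stopping.

#' Hyperparameter search space
#'
#' Default bounds: layers 5-75, neurons 5-75, dropout on/off with rate
#' 0.1-0.9, learning rate 5e-6 to 5e-4 (sampled log-uniformly), weight
#' decay 0-0.1.
#'
#' @param n_layers,n_neurons integer ranges `c(lo, hi)`, inclusive.
#' @param dropout_enabled candidate values for the dropout switch.
#' @param dropout_rate,learning_rate,weight_decay real ranges `c(lo, hi)`.
#' @return A `search_space` list.
#' @export
search_space <- function(n_layers = c(5L, 75L), n_neurons = c(5L, 75L),
                         dropout_enabled = c(TRUE, FALSE),
                         dropout_rate = c(0.1, 0.9),
                         learning_rate = c(0.000005, 0.0005),
                         weight_decay = c(0, 0.1)) {
  ranges <- list(n_layers = n_layers, n_neurons = n_neurons,
                 dropout_rate = dropout_rate,
                 learning_rate = learning_rate,
                 weight_decay = weight_decay)
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2L || r[1] > r[2]) {
      stop("empty range for ", nm, call. = FALSE)
    }
  }
  structure(c(ranges[c("n_layers", "n_neurons")],
              list(dropout_enabled = dropout_enabled),
              ranges[c("dropout_rate", "learning_rate", "weight_decay")]),
            class = "search_space")
}

#' Draw one configuration from a search space
#'
#' Integers are sampled uniformly (inclusive bounds); the learning rate is
#' sampled log-uniformly (its range spans two orders of magnitude); other
#' reals uniformly. The dropout rate is drawn only when the dropout switch
#' comes up true, otherwise it keeps the default. Non-searched fields
#' (batch size, epochs, seed) are taken from `base`.
#'
#' @param space a [search_space()].
#' @param base a [network_config()] supplying the non-searched fields.
#' @return A [network_config()]. Consumes the current RNG stream; seed it
#'   (or use [random_search()]) for reproducible draws.
#' @export
sample_config <- function(space, base = network_config()) {
  stopifnot(inherits(space, "search_space"))
  runi <- function(r) r[1] + floor(stats::runif(1) * (r[2] - r[1] + 1L))
  dropout_enabled <- space$dropout_enabled[
    sample.int(length(space$dropout_enabled), 1L)]
  dropout_rate <- if (dropout_enabled) {
    stats::runif(1, space$dropout_rate[1], space$dropout_rate[2])
  } else {
    base$dropout_rate
  }
  network_config(
    n_layers = runi(space$n_layers),
    n_neurons = runi(space$n_neurons),
    dropout_enabled = dropout_enabled,
    dropout_rate = dropout_rate,
    learning_rate = exp(stats::runif(1, log(space$learning_rate[1]),
                                     log(space$learning_rate[2]))),
    weight_decay = stats::runif(1, space$weight_decay[1],
                                space$weight_decay[2]),
    batch_size = base$batch_size, epochs = base$epochs, seed = base$seed
  )
}

#' Randomized grid search with early stopping
#'
#' Draws configurations from `space`, evaluates each by a full train +
#' validate cycle, and stops after `max_iterations` trials or once
#' `patience` consecutive trials fail to strictly improve the best
#' validation accuracy. Trial i uses seed `seed + i` so trials are
#' independent but the whole search replays exactly. A trial that diverges
#' is recorded with accuracy 0 and the search continues; if every trial
#' diverges the search errors.
#'
#' @param space a [search_space()].
#' @param train_features,train_labels,val_features,val_labels the fixed
#'   split all trials share.
#' @param max_iterations maximum number of trials (>= 1).
#' @param patience consecutive non-improving trials tolerated (default 10).
#' @param seed integer seed for the draw sequence.
#' @param base a [network_config()] supplying non-searched fields.
#' @param evaluator function(config) -> validation accuracy; the default
#'   trains the network on the supplied split. Injectable so the stopping
#'   rule can be exercised with stubs.
#' @return A `search_result`: `trials` (data.frame of sampled parameters +
#'   `validation_accuracy`), `configs`, `best_trial`, `best_config`,
#'   `stopped_early`, `iterations_run`.
#' @export
random_search <- function(space, train_features = NULL, train_labels = NULL,
                          val_features = NULL, val_labels = NULL,
                          max_iterations = 25L, patience = 10L, seed = 1L,
                          base = network_config(), evaluator = NULL) {
  stopifnot(max_iterations >= 1, patience >= 1)
  if (is.null(evaluator)) {
    if (is.null(train_features) || is.null(val_features)) {
      stop("supply train/validation data or an evaluator", call. = FALSE)
    }
    evaluator <- function(config) {
      net <- build_network(config, ncol(train_features),
                           max(train_labels, val_labels) + 1L)
      fit <- train_network(net, train_features, train_labels,
                           val_features, val_labels, config)
      max(fit$history$epochs$validation_accuracy, na.rm = TRUE)
    }
  }
  configs <- list()
  accs <- numeric()
  failed <- logical()
  best_acc <- -Inf
  best_trial <- NA_integer_
  stall <- 0L
  stopped_early <- FALSE
  for (i in seq_len(max_iterations)) {
    cfg <- withr::with_seed(seed + i, sample_config(space, base))
    cfg$seed <- as.integer(seed + i)
    acc <- tryCatch(evaluator(cfg), error = function(e) NA_real_)
    failed[i] <- is.na(acc)
    if (failed[i]) acc <- 0
    configs[[i]] <- cfg
    accs[i] <- acc
    if (acc > best_acc) {
      best_acc <- acc
      best_trial <- i
      stall <- 0L
    } else {
      stall <- stall + 1L
    }
    if (stall >= patience && i < max_iterations) {
      stopped_early <- TRUE
      break
    }
  }
  if (all(failed)) stop("every search trial diverged", call. = FALSE)
  trials <- data.frame(
    trial = seq_along(configs),
    n_layers = vapply(configs, `[[`, 0L, "n_layers"),
    n_neurons = vapply(configs, `[[`, 0L, "n_neurons"),
    dropout_enabled = vapply(configs, `[[`, TRUE, "dropout_enabled"),
    dropout_rate = vapply(configs, `[[`, 0, "dropout_rate"),
    learning_rate = vapply(configs, `[[`, 0, "learning_rate"),
    weight_decay = vapply(configs, `[[`, 0, "weight_decay"),
    validation_accuracy = accs,
    diverged = failed
  )
  structure(list(trials = trials, configs = configs,
                 best_trial = best_trial,
                 best_config = configs[[best_trial]],
                 stopped_early = stopped_early,
                 iterations_run = length(configs)),
            class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  cat("<search_result> ", x$iterations_run, " trials",
      if (x$stopped_early) " (stopped early)", ", best trial ",
      x$best_trial, " (validation accuracy ",
      sprintf("%.3f", x$trials$validation_accuracy[x$best_trial]), ")\n",
      sep = "")
  invisible(x)
}
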