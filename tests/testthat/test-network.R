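test_that("architecture has the closed-form parameter count", {
  cfg <- network_config(n_layers = 3L, n_neurons = 10L)
  net <- build_network(cfg, n_features = 50L, n_classes = 2L)
  expect_identical(count_parameters(net), 752)
  expect_length(net$layers, 4L)  # 3 hidden linears + output
  minimal <- build_network(network_config(n_layers = 1L, n_neurons = 4L),
                           10L, 3L)
  expect_length(minimal$layers, 2L)
  expect_identical(count_parameters(minimal), (10 + 1) * 4 + (4 + 1) * 3)
  expect_error(build_network(cfg, 5L, 1L), "2 classes")
})

test_that("initialization is seed-deterministic", {
  cfg <- network_config(seed = 123L)
  a <- build_network(cfg, 20L, 2L)
  b <- build_network(cfg, 20L, 2L)
  expect_identical(a$layers, b$layers)
  c <- build_network(network_config(seed = 124L), 20L, 2L)
  expect_false(identical(a$layers[[1]]$W, c$layers[[1]]$W))
})

test_that("probabilities are a valid softmax: rows sum to one, untrained is uniform", {
  for (seed in 1:5) {
    net <- build_network(network_config(n_layers = 3L, n_neurons = 8L,
                                        seed = seed), 12L, 3L)
    X <- matrix(rnorm(7 * 12, sd = 5), 7, 12)
    p <- predict_proba(net, X)
    expect_identical(dim(p), c(7L, 3L))
    expect_true(all(p >= 0 & p <= 1))
    expect_equal(unname(rowSums(p)), rep(1, 7), tolerance = 1e-6)
  }
  # the output layer starts at zero, so an untrained net is exactly uniform
  net <- build_network(network_config(seed = 1L), 6L, 4L)
  p <- predict_proba(net, matrix(rnorm(18), 3, 6))
  expect_equal(unname(p), matrix(0.25, 3, 4))
  # duplicate rows get identical outputs (dropout inactive at prediction)
  X <- matrix(rnorm(6), 1, 6)
  p2 <- predict_proba(net, rbind(X, X))
  expect_identical(p2[1, ], p2[2, ])
  expect_error(predict_proba(net, matrix(0, 2, 5)), "expected 6")
})

test_that("label prediction maps argmax through the encoding with low-index ties", {
  gen <- synth_generate(synth_config(n_per_class = c(6L, 6L), n_taxa = 15L,
                                     n_informative = 4L, seed = 2))
  model <- fit_phenodnn(gen$table, gen$meta,
                        preprocess_config(seed = 2),
                        network_config(n_layers = 1L, n_neurons = 4L,
                                       epochs = 1L, seed = 2))
  feats <- preprocess_apply(gen$table, model$retained_taxa,
                            model$pre_config, model$normalization)
  labs <- predict_label(model, feats)
  expect_length(labs, 12L)
  expect_true(all(labs %in% c("class_0", "class_1")))
  p <- predict_proba(model, feats)
  expect_identical(labs, model$labels$label_order[
    max.col(p, ties.method = "first")])
  # an exactly uniform row resolves to the first label
  untrained <- build_network(network_config(seed = 3L), 5L, 2L)
  expect_identical(predict_label(untrained, matrix(1, 1, 5)), 0L)
})

test_that("training is deterministic and records history per epoch", {
  set.seed(31)
  X <- matrix(rnorm(60 * 8), 60, 8)
  y <- rep(0:1, 30)
  cfg <- network_config(n_layers = 2L, n_neurons = 6L, epochs = 5L,
                        batch_size = 16L, learning_rate = 1e-3, seed = 77L)
  net <- build_network(cfg, 8L, 2L)
  f1 <- train_network(net, X, y, X[1:10, ], y[1:10], cfg)
  f2 <- train_network(net, X, y, X[1:10, ], y[1:10], cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$network$layers, f2$network$layers)
  expect_identical(nrow(f1$history$epochs), 5L)
  expect_true(all(is.finite(f1$history$epochs$train_loss)))
  # best epoch maximizes validation accuracy, earliest on ties
  acc <- f1$history$epochs$validation_accuracy
  expect_identical(f1$history$best_epoch,
                   which(acc == max(acc))[1])
})

test_that("validation checkpointing returns the best epoch's weights", {
  gen <- synth_generate(synth_config(n_per_class = c(30L, 30L),
                                     n_taxa = 40L, n_informative = 10L,
                                     seed = 4))
  model <- fit_phenodnn(gen$table, gen$meta, preprocess_config(seed = 4),
                        convergent_net(seed = 4, epochs = 40L))
  hist <- model$history
  feats <- preprocess_apply(gen$table, model$retained_taxa,
                            model$pre_config, model$normalization)
  va <- feats[model$split$validation_ids, , drop = FALSE]
  truth <- unname(model$labels$label_index[
    gen$meta$mapping[model$split$validation_ids]])
  acc_now <- mean(predict_label(model, va) ==
                    model$labels$label_order[truth + 1L])
  expect_equal(acc_now,
               max(hist$epochs$validation_accuracy, na.rm = TRUE))
})

test_that("the network fits separable synthetic data", {
  gen <- synth_generate(synth_config(n_per_class = c(50L, 50L),
                                     n_taxa = 100L, n_informative = 15L,
                                     log_fold_change = 3, seed = 21))
  model <- fit_phenodnn(gen$table, gen$meta, preprocess_config(seed = 21),
                        convergent_net(seed = 21))
  expect_gte(tail(model$history$epochs$train_accuracy, 1), 0.95)
  feats <- preprocess_apply(gen$table, model$retained_taxa,
                            model$pre_config, model$normalization)
  te <- model$split$test_ids
  truth <- unname(model$labels$label_index[gen$meta$mapping[te]])
  acc <- mean(predict_label(model, feats[te, , drop = FALSE]) ==
                model$labels$label_order[truth + 1L])
  # comfortably above the majority-class rate
  expect_gte(acc, 0.8)
})

test_that("a wide one-layer network matches a multinomial logistic oracle", {
  skip_if_not_installed("nnet")
  set.seed(8)
  n <- 80L; p <- 10L
  X <- matrix(rnorm(n * p), n, p)
  beta <- rnorm(p)
  y <- as.integer(runif(n) < plogis(X %*% beta))
  cfg <- network_config(n_layers = 1L, n_neurons = 2L * p,
                        dropout_enabled = FALSE, learning_rate = 3e-3,
                        epochs = 400L, batch_size = 80L, seed = 8L)
  net <- build_network(cfg, p, 2L)
  fit <- train_network(net, X, y, config = cfg)
  dnn_loss <- tail(fit$history$epochs$train_loss, 1)
  oracle <- nnet::multinom(y ~ X, decay = 1e-4, maxit = 500, trace = FALSE)
  pr <- stats::fitted(oracle)
  oracle_loss <- -mean(log(ifelse(y == 1, pr, 1 - pr)))
  expect_lte(dnn_loss, oracle_loss + 0.05)
})

test_that("divergence raises an error naming the epoch", {
  set.seed(5)
  X <- matrix(rnorm(40) * 1e150, 20, 2)
  y <- rep(0:1, 10)
  cfg <- network_config(n_layers = 2L, n_neurons = 4L, epochs = 3L,
                        learning_rate = 1e260, dropout_enabled = FALSE,
                        seed = 5L)
  net <- build_network(cfg, 2L, 2L)
  expect_error(train_network(net, X, y, config = cfg), "diverged")
})

test_that("models round-trip through the archive bit-for-bit", {
  gen <- synth_generate(synth_config(n_per_class = c(8L, 8L), n_taxa = 20L,
                                     seed = 6))
  model <- fit_phenodnn(gen$table, gen$meta, preprocess_config(seed = 6),
                        network_config(n_layers = 2L, n_neurons = 6L,
                                       epochs = 2L, seed = 6L))
  path <- tempfile(fileext = ".tar.gz")
  save_model(model, path)
  back <- load_model(path)
  feats <- preprocess_apply(gen$table, model$retained_taxa,
                            model$pre_config, model$normalization)
  expect_identical(predict_proba(back, feats), predict_proba(model, feats))
  expect_identical(back$retained_taxa, model$retained_taxa)
  expect_identical(back$labels$label_order, model$labels$label_order)
  expect_equal(back$normalization$reference_scale,
               model$normalization$reference_scale)
  # whole-table prediction path agrees too
  expect_identical(predict_table(back, gen$table),
                   predict_table(model, gen$table))
})

test_that("corrupted or truncated archives raise descriptive errors", {
  gen <- synth_generate(synth_config(n_per_class = c(5L, 5L), n_taxa = 10L,
                                     n_informative = 3L, seed = 7))
  model <- fit_phenodnn(gen$table, gen$meta, preprocess_config(seed = 7),
                        network_config(n_layers = 1L, n_neurons = 3L,
                                       epochs = 1L, seed = 7L))
  path <- tempfile(fileext = ".tar.gz")
  save_model(model, path)
  truncated <- tempfile(fileext = ".tar.gz")
  blob <- readBin(path, "raw", file.size(path))
  writeBin(blob[seq_len(floor(length(blob) / 3))], truncated)
  expect_error(load_model(truncated), "archive")
  garbage <- tempfile(fileext = ".tar.gz")
  writeBin(as.raw(sample(0:255, 200, replace = TRUE)), garbage)
  expect_error(load_model(garbage), "archive")
  expect_error(load_model(tempfile()), "not found")
})
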