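# End-to-end model fitting: preprocessing + network training bundled into
# one trained-model object that can be saved, reloaded and applied to raw
# profiles of unknown samples.

#' Fit the full phenotype classifier on a labeled abundance table
#'
#' Runs the fixed preprocessing pipeline (rank restriction, relative
#' percent, abundance filtering on the training partition, CSS
#' normalization), builds the network, trains it on the training partition
#' with best-epoch checkpointing on the validation partition, and bundles
#' the weights with everything needed to replay preprocessing on unknown
#' samples.
#'
#' @param table raw `abundance_table`.
#' @param meta `sample_metadata` with the class labels.
#' @param pre_config a [preprocess_config()].
#' @param net_config a [network_config()].
#' @param split optional precomputed `data_split`.
#' @return A `phenodnn_model`: `network`, `history`, `retained_taxa`,
#'   `normalization`, `labels`, `pre_config`, `split`, `n_features`,
#'   `n_classes`.
#' @export
fit_phenodnn <- function(table, meta, pre_config = preprocess_config(),
                         net_config = network_config(), split = NULL) {
  prep <- preprocess_fit(table, meta, pre_config, split)
  split <- prep$split
  tr <- prep$features[prep$split$train_ids, , drop = FALSE]
  tr_y <- prep$labels[match(prep$split$train_ids, rownames(prep$features))]
  has_val <- length(prep$split$validation_ids) > 0L
  va <- if (has_val) prep$features[prep$split$validation_ids, , drop = FALSE]
  va_y <- if (has_val) {
    prep$labels[match(prep$split$validation_ids, rownames(prep$features))]
  }
  aligned_meta <- align_table_metadata(table, meta, "intersect")$meta
  net <- build_network(net_config, ncol(prep$features),
                       length(aligned_meta$label_order))
  fit <- train_network(net, tr, tr_y, va, va_y, net_config)
  structure(list(
    network = fit$network,
    history = fit$history,
    retained_taxa = prep$retained_taxa,
    normalization = prep$normalization,
    labels = aligned_meta[c("label_order", "label_index")],
    pre_config = pre_config,
    split = split,
    n_features = ncol(prep$features),
    n_classes = length(aligned_meta$label_order)
  ), class = "phenodnn_model")
}

#' Predict raw profiles with a trained model
#'
#' Replays the stored preprocessing (rank restriction, percent conversion,
#' retained-taxa projection with zero-fill, CSS with the stored reference
#' scale) and returns labels and class probabilities.
#'
#' @param model a `phenodnn_model`.
#' @param table raw `abundance_table` of unknown samples.
#' @return data.frame with `sample_id`, `predicted_label`, and one
#'   probability column per class label.
#' @export
predict_table <- function(model, table) {
  feats <- preprocess_apply(table, model$retained_taxa, model$pre_config,
                            model$normalization)
  p <- predict_proba(model, feats)
  out <- data.frame(sample_id = table$sample_ids,
                    predicted_label = predict_label(model, feats),
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(p, optional = TRUE))
}

#' @export
print.phenodnn_model <- function(x, ...) {
  cat("<phenodnn_model> ", x$n_features, " taxa -> ",
      paste(x$labels$label_order, collapse = "/"), "\n", sep = "")
  cat("  layers: ", x$network$config$n_layers, " x ",
      x$network$config$n_neurons, ", dropout ",
      if (x$network$config$dropout_enabled)
        x$network$config$dropout_rate else "off",
      ", ", count_parameters(x), " parameters\n", sep = "")
  cat("  normalization: ",
      if (is.null(x$normalization)) "none" else
        sprintf("CSS(q = %g, ref = %.4g)", x$normalization$css_quantile,
                x$normalization$reference_scale), "\n", sep = "")
  invisible(x)
}
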