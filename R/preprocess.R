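# Feature preparation: rank restriction -> relative percent -> abundance
# filter -> cumulative sum scaling -> split / feature assembly. The order is
# fixed; preprocess_fit()/preprocess_apply() enforce it.

#' Preprocessing configuration
#'
#' Defaults follow the tool's shipped settings: species-level filter with a
#' 0.03 abundance threshold (percent scale, i.e. 0.03%), CSS normalization
#' at the median quantile, and a 15% stratified test split with 15% of the
#' remainder held out for validation.
#'
#' @param rank taxonomic rank the features are restricted to.
#' @param abundance_threshold minimum per-taxon maximum relative abundance
#'   (percent scale) required to retain a taxon.
#' @param normalize apply CSS normalization?
#' @param css_quantile CSS quantile in (0, 1).
#' @param test_fraction fraction of samples held out for testing.
#' @param validation_fraction fraction of the non-test remainder held out
#'   for validation.
#' @param seed integer seed driving the stratified shuffles.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(rank = "species", abundance_threshold = 0.03,
                              normalize = TRUE, css_quantile = 0.5,
                              test_fraction = 0.15,
                              validation_fraction = 0.15, seed = 1L) {
  rank <- match.arg(rank, RANKS)
  stopifnot(abundance_threshold >= 0,
            css_quantile > 0, css_quantile < 1,
            test_fraction > 0, test_fraction < 1,
            validation_fraction >= 0, validation_fraction < 1)
  if (test_fraction + (1 - test_fraction) * validation_fraction >= 1) {
    stop("test and validation fractions leave no training data", call. = FALSE)
  }
  structure(list(rank = rank, abundance_threshold = abundance_threshold,
                 normalize = normalize, css_quantile = css_quantile,
                 test_fraction = test_fraction,
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed)),
            class = "preprocess_config")
}

#' Restrict a table to one taxonomic rank
#'
#' Keeps only taxa whose terminal rank equals `rank`, preserving order.
#' Sub-rank entries (e.g. Kraken2 `S1` strata) never match any rank.
#'
#' @param table an `abundance_table`.
#' @param rank one of [taxonomic_ranks()].
#' @return The restricted `abundance_table`.
#' @export
restrict_to_rank <- function(table, rank) {
  rank <- match.arg(rank, RANKS)
  keep <- !is.na(table$taxa$rank) & table$taxa$rank == rank
  if (!any(keep)) stop("no taxa at rank '", rank, "'", call. = FALSE)
  abundance_table(table$values[, keep, drop = FALSE], table$sample_ids,
                  table$taxa$display_id[keep], table$value_kind)
}

#' Convert a single-rank table to relative percent
#'
#' Counts are closed to 100 per sample; percent input is returned unchanged.
#'
#' @param table an `abundance_table` restricted to a single rank.
#' @return An `abundance_table` with `value_kind = "relative_percent"`.
#' @export
to_relative_percent <- function(table) {
  if (table$value_kind == "relative_percent") return(table)
  totals <- rowSums(table$values)
  if (any(totals <= 0)) {
    stop("sample '", table$sample_ids[which(totals <= 0)[1]],
         "' has no positive abundance", call. = FALSE)
  }
  vals <- if (table$value_kind == "relative_fraction") {
    table$values * 100
  } else {
    sweep(table$values, 1, totals, "/") * 100
  }
  abundance_table(vals, table$sample_ids, table$taxa$display_id,
                  "relative_percent")
}

#' Filter taxa by maximum relative abundance
#'
#' Retains exactly the taxa whose maximum relative abundance across
#' `reference_ids` (default: all samples) is greater than or equal to
#' `threshold` (boundary inclusive, percent scale). The retained taxon list
#' is returned so the same filter can be replayed on unknown samples.
#'
#' @param table a `relative_percent` `abundance_table`.
#' @param threshold non-negative threshold on the percent scale.
#' @param reference_ids optional sample subset the maxima are computed over
#'   (the training partition, to avoid test-set leakage).
#' @return List with `table` (filtered) and `retained_taxa` (character).
#' @export
filter_abundance <- function(table, threshold, reference_ids = NULL) {
  stopifnot(threshold >= 0)
  if (table$value_kind != "relative_percent") {
    stop("filter_abundance expects a relative_percent table", call. = FALSE)
  }
  ref <- if (is.null(reference_ids)) table$sample_ids else reference_ids
  stopifnot(all(ref %in% table$sample_ids))
  maxima <- apply(table$values[ref, , drop = FALSE], 2, max)
  keep <- maxima >= threshold
  if (!any(keep)) {
    stop(sprintf(
      "no taxon passes the %g%% abundance threshold (max observed %g%%)",
      threshold, max(maxima)), call. = FALSE)
  }
  list(
    table = abundance_table(table$values[, keep, drop = FALSE],
                            table$sample_ids, table$taxa$display_id[keep],
                            table$value_kind),
    retained_taxa = table$taxa$display_id[keep]
  )
}

#' Cumulative sum scaling normalization
#'
#' For each sample j the scaling factor is
#' \eqn{s_j = \sum_i v_{ij} [v_{ij} \le q_l(j)]}, the sum of that sample's
#' values no larger than the l-th quantile of its positive values
#' (linear-interpolation quantile). At fit time the reference scale is the
#' median of the factors and the output is \eqn{v'_{ij} = v_{ij}/s_j \times
#' \mathrm{ref}}. At prediction time a stored `normalization_state` supplies
#' the reference scale and only the per-sample factors are recomputed, so a
#' sample's normalized row never depends on which other samples accompany
#' it.
#'
#' @param table an `abundance_table` with non-negative values, every sample
#'   having at least one positive value.
#' @param quantile CSS quantile in (0, 1).
#' @param state optional `normalization_state` from a previous fit.
#' @return List with `table` (normalized) and `state`
#'   (a `normalization_state`: `css_quantile`, `reference_scale`,
#'   `per_sample_factors`).
#' @export
css_normalize <- function(table, quantile = 0.5, state = NULL) {
  if (!is.null(state)) {
    stopifnot(inherits(state, "normalization_state"))
    quantile <- state$css_quantile
  }
  if (quantile <= 0 || quantile >= 1) {
    stop("css quantile must lie in (0, 1)", call. = FALSE)
  }
  factors <- apply(table$values, 1, function(v) {
    pos <- v[v > 0]
    if (length(pos) == 0L) return(NA_real_)
    sum(v[v <= stats::quantile(pos, quantile, names = FALSE)])
  })
  if (anyNA(factors)) {
    stop("sample '", table$sample_ids[which(is.na(factors))[1]],
         "' has no positive values", call. = FALSE)
  }
  reference <- if (is.null(state)) stats::median(factors) else
    state$reference_scale
  vals <- sweep(table$values, 1, factors, "/") * reference
  new_state <- structure(
    list(css_quantile = quantile, reference_scale = reference,
         per_sample_factors = stats::setNames(factors, table$sample_ids)),
    class = "normalization_state")
  list(
    table = abundance_table(vals, table$sample_ids, table$taxa$display_id,
                            table$value_kind),
    state = new_state
  )
}

#' Stratified train/validation/test split
#'
#' Per class: a seeded shuffle, then `round(test_fraction * n_c)` samples
#' (half away from zero, at least 1) go to test, the same rule applied to
#' `validation_fraction` of the remainder, the rest to train. Deterministic
#' given the seed.
#'
#' @param meta a `sample_metadata`.
#' @param config a [preprocess_config()].
#' @return A `data_split`: lists `train_ids`, `validation_ids`, `test_ids`
#'   plus the seed. The three are disjoint and cover every labeled sample.
#' @export
stratified_split <- function(meta, config) {
  counts <- table(meta$mapping)
  need <- if (config$validation_fraction > 0) 3L else 2L
  small <- names(counts)[counts < need]
  if (length(small)) {
    stop("class '", small[1], "' has fewer than ", need, " samples",
         call. = FALSE)
  }
  train <- character(); val <- character(); test <- character()
  withr::with_seed(config$seed, {
    for (cls in meta$label_order) {
      ids <- names(meta$mapping)[meta$mapping == cls]
      ids <- ids[sample.int(length(ids))]
      n_test <- max(1L, round_half_away(config$test_fraction * length(ids)))
      test <- c(test, ids[seq_len(n_test)])
      rest <- ids[-seq_len(n_test)]
      n_val <- round_half_away(config$validation_fraction * length(rest))
      if (n_val > 0) val <- c(val, rest[seq_len(n_val)])
      train <- c(train, rest[setdiff(seq_along(rest), seq_len(n_val))])
    }
  })
  structure(list(train_ids = train, validation_ids = val, test_ids = test,
                 seed = config$seed),
            class = "data_split")
}

round_half_away <- function(x) trunc(x + sign(x) * 0.5)

#' Assemble the model-ready feature matrix
#'
#' Columns follow `retained_taxa` order exactly; taxa missing from the table
#' (e.g. in an unknown sample's profile) are zero-filled, and novel taxa are
#' ignored. When `meta` is given the integer label vector (0-based, via the
#' stored label encoding) is returned alongside.
#'
#' @param table an `abundance_table` (already normalized when the model was
#'   trained with normalization).
#' @param retained_taxa character vector fixing the feature order.
#' @param meta optional `sample_metadata` for labeled data.
#' @return List with `features` (samples x taxa matrix) and `labels`
#'   (integer vector or NULL).
#' @export
assemble_features <- function(table, retained_taxa, meta = NULL) {
  m <- matrix(0, nrow = n_samples(table), ncol = length(retained_taxa),
              dimnames = list(table$sample_ids, retained_taxa))
  present <- retained_taxa[retained_taxa %in% table$taxa$display_id]
  m[, present] <- table$values[, present, drop = FALSE]
  labels <- NULL
  if (!is.null(meta)) {
    missing <- setdiff(table$sample_ids, names(meta$mapping))
    if (length(missing)) {
      stop("unlabeled samples: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    labels <- unname(meta$label_index[meta$mapping[table$sample_ids]])
  }
  list(features = m, labels = labels)
}

#' Fit the full preprocessing pipeline on training data
#'
#' Applies the fixed pipeline order (rank restriction, relative percent,
#' abundance filter computed on the training partition, CSS) and records
#' everything needed to replay it on unknown samples.
#'
#' @param table raw `abundance_table`.
#' @param meta `sample_metadata` aligned with `table`.
#' @param config a [preprocess_config()].
#' @param split optional precomputed `data_split`; made with
#'   [stratified_split()] otherwise.
#' @return List with `features`, `labels`, `split`, `retained_taxa`,
#'   `normalization` (state or NULL), and `config`.
#' @export
preprocess_fit <- function(table, meta, config = preprocess_config(),
                           split = NULL) {
  aligned <- align_table_metadata(table, meta, "intersect")
  table <- aligned$table; meta <- aligned$meta
  if (is.null(split)) split <- stratified_split(meta, config)
  table <- restrict_to_rank(table, config$rank)
  table <- to_relative_percent(table)
  filt <- filter_abundance(table, config$abundance_threshold,
                           reference_ids = split$train_ids)
  table <- filt$table
  norm_state <- NULL
  if (config$normalize) {
    # fit the reference scale on the training partition only, then apply
    # the frozen state everywhere (per-sample factors carry no leakage)
    fit_state <- css_normalize(subset_samples(table, split$train_ids),
                               config$css_quantile)$state
    css <- css_normalize(table, state = fit_state)
    table <- css$table
    norm_state <- structure(
      list(css_quantile = fit_state$css_quantile,
           reference_scale = fit_state$reference_scale,
           per_sample_factors =
             fit_state$per_sample_factors),
      class = "normalization_state")
  }
  fm <- assemble_features(table, filt$retained_taxa, meta)
  list(features = fm$features, labels = fm$labels, split = split,
       retained_taxa = filt$retained_taxa, normalization = norm_state,
       config = config)
}

#' Replay a fitted preprocessing pipeline on new samples
#'
#' @param table raw `abundance_table` of unknown or held-back samples.
#' @param retained_taxa taxon list stored at fit time.
#' @param config the `preprocess_config` stored at fit time.
#' @param state the `normalization_state` stored at fit time (or NULL when
#'   normalization was disabled).
#' @return The feature matrix, columns in `retained_taxa` order.
#' @export
preprocess_apply <- function(table, retained_taxa, config, state = NULL) {
  table <- restrict_to_rank(table, config$rank)
  table <- to_relative_percent(table)
  # project onto the retained taxa before CSS so the per-sample factors are
  # computed over exactly the columns they were fitted on
  m <- assemble_features(table, retained_taxa)$features
  proj <- abundance_table(m, table$sample_ids, retained_taxa,
                          "relative_percent")
  if (config$normalize) {
    if (is.null(state)) stop("missing normalization state", call. = FALSE)
    proj <- css_normalize(proj, state = state)$table
  }
  proj$values
}
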