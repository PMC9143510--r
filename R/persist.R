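# Model archives: a gzipped tar container with JSON-compatible text members
# plus a little-endian binary weight blob. Loading reproduces predictions
# bit-for-bit.

ARCHIVE_FORMAT_VERSION <- "1"

write_weight_blob <- function(blob, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(blob, con, size = 8L, endian = "little")
  invisible(path)
}

read_weight_blob <- function(path, n_max) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "double", n = n_max, size = 8L, endian = "little")
}

#' Save a trained model to a single archive file
#'
#' The archive is a gzipped tar container with members `format_version`,
#' `config.json` (network + preprocessing configuration and layer
#' dimensions), `labels.json`, `taxa.txt` (one retained display id per
#' line), `normalization.json` and `weights.bin` (all layer weights and
#' biases as little-endian doubles).
#'
#' @param model a `phenodnn_model`.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "phenodnn_model"))
  stage <- tempfile("phenodnn_archive_")
  dir.create(stage)
  on.exit(unlink(stage, recursive = TRUE), add = TRUE)
  writeLines(ARCHIVE_FORMAT_VERSION, file.path(stage, "format_version"))
  layer_dims <- lapply(model$network$layers, function(l) dim(l$W))
  cfg <- list(
    network = unclass(model$network$config),
    preprocess = unclass(model$pre_config),
    n_features = model$n_features,
    n_classes = model$n_classes,
    layer_dims = layer_dims
  )
  jsonlite::write_json(cfg, file.path(stage, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(label_order = model$labels$label_order,
         label_index = as.list(model$labels$label_index)),
    file.path(stage, "labels.json"), auto_unbox = TRUE)
  writeLines(model$retained_taxa, file.path(stage, "taxa.txt"),
             useBytes = TRUE)
  if (is.null(model$normalization)) {
    writeLines("null", file.path(stage, "normalization.json"))
  } else {
    jsonlite::write_json(
      list(css_quantile = model$normalization$css_quantile,
           reference_scale = model$normalization$reference_scale,
           per_sample_factors = as.list(model$normalization$per_sample_factors)),
      file.path(stage, "normalization.json"), auto_unbox = TRUE, digits = NA)
  }
  blob <- unlist(lapply(model$network$layers,
                        function(l) c(as.numeric(l$W), l$b)))
  write_weight_blob(blob, file.path(stage, "weights.bin"))
  # build in a temp file first so a failure never leaves a partial archive
  tmp <- tempfile(fileext = ".tar.gz")
  old <- setwd(stage)
  tryCatch(
    utils::tar(tmp, files = list.files(stage), compression = "gzip",
               tar = "internal"),
    finally = setwd(old))
  if (!file.copy(tmp, path, overwrite = TRUE)) {
    unlink(tmp)
    stop("cannot write model archive to ", path, call. = FALSE)
  }
  unlink(tmp)
  invisible(path)
}

#' Load a trained model from an archive
#'
#' Inverse of [save_model()]; the reloaded model's [predict_proba()] output
#' is bit-identical to the in-memory model's. Corrupted or truncated
#' archives and format-version mismatches raise descriptive errors.
#'
#' @param path archive file path.
#' @return A `phenodnn_model`.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model archive not found: ", path,
                               call. = FALSE)
  stage <- tempfile("phenodnn_load_")
  dir.create(stage)
  on.exit(unlink(stage, recursive = TRUE), add = TRUE)
  before <- as.integer(rownames(showConnections(all = TRUE)))
  ok <- tryCatch({
    utils::untar(path, exdir = stage, tar = "internal")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  # the internal untar can leak member connections on a truncated archive
  leaked <- setdiff(as.integer(rownames(showConnections(all = TRUE))),
                    before)
  for (i in leaked) try(close(getConnection(i)), silent = TRUE)
  members <- c("format_version", "config.json", "labels.json", "taxa.txt",
               "normalization.json", "weights.bin")
  if (!ok || !all(file.exists(file.path(stage, members)))) {
    stop("corrupted or incomplete model archive: ", path, call. = FALSE)
  }
  version <- readLines(file.path(stage, "format_version"), warn = FALSE)[1]
  if (!identical(version, ARCHIVE_FORMAT_VERSION)) {
    stop("unsupported model archive format_version '", version,
         "' (expected '", ARCHIVE_FORMAT_VERSION, "')", call. = FALSE)
  }
  cfg <- jsonlite::read_json(file.path(stage, "config.json"),
                             simplifyVector = TRUE)
  net_config <- do.call(network_config, as.list(cfg$network))
  pre_config <- do.call(preprocess_config, as.list(cfg$preprocess))
  labels <- jsonlite::read_json(file.path(stage, "labels.json"),
                                simplifyVector = TRUE)
  taxa <- readLines(file.path(stage, "taxa.txt"), warn = FALSE)
  norm_raw <- paste(readLines(file.path(stage, "normalization.json"),
                              warn = FALSE), collapse = "")
  normalization <- if (identical(trimws(norm_raw), "null")) NULL else {
    n <- jsonlite::fromJSON(norm_raw)
    structure(list(css_quantile = n$css_quantile,
                   reference_scale = n$reference_scale,
                   per_sample_factors = unlist(n$per_sample_factors)),
              class = "normalization_state")
  }
  layer_dims <- cfg$layer_dims
  if (is.matrix(layer_dims)) {
    layer_dims <- lapply(seq_len(nrow(layer_dims)),
                         function(i) layer_dims[i, ])
  }
  expected <- sum(vapply(layer_dims,
                         function(d) d[1] * d[2] + d[2], 0))
  blob <- read_weight_blob(file.path(stage, "weights.bin"), expected + 1L)
  if (length(blob) != expected) {
    stop("corrupted model archive: weight blob has ", length(blob),
         " values, expected ", expected, call. = FALSE)
  }
  layers <- vector("list", length(layer_dims))
  off <- 0L
  for (i in seq_along(layer_dims)) {
    d <- layer_dims[[i]]
    nw <- d[1] * d[2]
    layers[[i]] <- list(
      W = matrix(blob[(off + 1):(off + nw)], d[1], d[2]),
      b = blob[(off + nw + 1):(off + nw + d[2])]
    )
    off <- off + nw + d[2]
  }
  network <- structure(list(layers = layers, config = net_config,
                            n_features = as.integer(cfg$n_features),
                            n_classes = as.integer(cfg$n_classes)),
                       class = "phenodnn_network")
  structure(list(
    network = network,
    history = NULL,
    retained_taxa = taxa,
    normalization = normalization,
    labels = list(label_order = labels$label_order,
                  label_index = stats::setNames(
                    as.integer(unlist(labels$label_index)),
                    names(labels$label_index))),
    pre_config = pre_config,
    split = NULL,
    n_features = as.integer(cfg$n_features),
    n_classes = as.integer(cfg$n_classes)
  ), class = "phenodnn_model")
}
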