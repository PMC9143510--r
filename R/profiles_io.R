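# Canonical abundance container and the three supported profile dialects.

#' Construct an abundance table
#'
#' The canonical container for taxonomic profiles: a dense samples x taxa
#' matrix with lineage-annotated taxa. All readers return one and all
#' downstream steps consume one.
#'
#' @param values numeric matrix, samples in rows, taxa in columns,
#'   non-negative.
#' @param sample_ids character vector of unique sample ids (row order).
#' @param taxa character vector of taxon display ids (pipe-joined lineage
#'   strings with rank prefixes), unique, one per column.
#' @param value_kind one of `"counts"`, `"relative_percent"`,
#'   `"relative_fraction"`.
#' @return An object of class `abundance_table` with fields `values`
#'   (dimnamed matrix), `sample_ids`, `taxa` (data.frame with `display_id`
#'   and terminal `rank`), and `value_kind`.
#' @export
abundance_table <- function(values, sample_ids, taxa,
                            value_kind = c("counts", "relative_percent",
                                           "relative_fraction")) {
  value_kind <- match.arg(value_kind)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (length(sample_ids) != nrow(values) || length(taxa) != ncol(values)) {
    stop("matrix dimensions inconsistent with id lists", call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample id '", sample_ids[duplicated(sample_ids)][1], "'",
         call. = FALSE)
  }
  if (anyDuplicated(taxa)) {
    stop("duplicate taxon '", taxa[duplicated(taxa)][1], "'", call. = FALSE)
  }
  if (anyNA(values) || any(values < 0)) {
    stop("abundance values must be non-negative and non-missing",
         call. = FALSE)
  }
  dimnames(values) <- list(sample_ids, taxa)
  out <- list(
    values = values,
    sample_ids = as.character(sample_ids),
    taxa = data.frame(display_id = as.character(taxa),
                      rank = terminal_ranks(taxa),
                      stringsAsFactors = FALSE),
    value_kind = value_kind
  )
  class(out) <- "abundance_table"
  out
}

#' @export
print.abundance_table <- function(x, ...) {
  cat("<abundance_table> ", length(x$sample_ids), " samples x ",
      nrow(x$taxa), " taxa [", x$value_kind, "]\n", sep = "")
  rk <- table(x$taxa$rank, useNA = "ifany")
  cat("  taxa per rank:",
      paste(names(rk), rk, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Number of samples / taxa in an abundance table
#' @param table an `abundance_table`.
#' @return Integer count.
#' @export
n_samples <- function(table) length(table$sample_ids)

#' @rdname n_samples
#' @export
n_taxa <- function(table) nrow(table$taxa)

# Restrict a table to a subset of sample ids (in the given order).
subset_samples <- function(table, ids) {
  stopifnot(all(ids %in% table$sample_ids))
  abundance_table(table$values[ids, , drop = FALSE], ids,
                  table$taxa$display_id, table$value_kind)
}

# Infer counts vs relative_percent: percent if every sample sums to ~100 at
# the deepest standard rank present (the species rank when there is one).
infer_value_kind <- function(values, taxa_ids) {
  ranks <- terminal_ranks(taxa_ids)
  present <- RANKS[RANKS %in% ranks]
  if (length(present) == 0L) return("counts")
  deepest <- present[length(present)]
  sums <- rowSums(values[, ranks %in% deepest, drop = FALSE])
  if (all(sums >= 99 & sums <= 101)) "relative_percent" else "counts"
}

#' Read a generic TSV OTU table
#'
#' Expects a UTF-8 tab-separated file whose first column holds pipe-joined
#' lineage strings and whose remaining column headers are sample ids. The
#' value kind is inferred: `relative_percent` when every sample's abundances
#' at the deepest standard rank sum to within \[99, 101\], otherwise
#' `counts`; pass `value_kind` to override the inference.
#'
#' @param path file path.
#' @param dialect only `"generic_tsv"` is supported here; see
#'   [read_kraken_reports()] and [read_metaphlan_table()] for the others.
#' @param value_kind optional explicit value kind, skipping inference.
#' @return An [abundance_table()].
#' @export
read_otu_table <- function(path, dialect = "generic_tsv", value_kind = NULL) {
  dialect <- match.arg(dialect, "generic_tsv")
  lines <- read_nonempty_lines(path)
  if (length(lines) < 2L) stop("empty table: ", path, call. = FALSE)
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  sample_ids <- header[-1]
  if (length(sample_ids) == 0L) stop("no sample columns in ", path, call. = FALSE)
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample column '",
         sample_ids[duplicated(sample_ids)][1], "'", call. = FALSE)
  }
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  ncell <- lengths(body)
  if (any(ncell != length(header))) {
    stop("line ", which(ncell != length(header))[1] + 1L,
         ": expected ", length(header), " fields", call. = FALSE)
  }
  taxa <- vapply(body, `[[`, "", 1L)
  # validate every lineage, reporting the offending line number
  for (i in seq_along(taxa)) {
    taxa[i] <- format_taxon(parse_taxon(taxa[i], context = paste0("line ", i + 1L)))
  }
  vals <- t(vapply(body, function(f) {
    v <- suppressWarnings(as.numeric(f[-1]))
    if (anyNA(v)) stop("non-numeric abundance value in row '", f[1], "'",
                       call. = FALSE)
    v
  }, numeric(length(sample_ids))))
  if (length(sample_ids) == 1L) vals <- matrix(vals, ncol = 1L)
  if (any(vals < 0)) stop("negative abundance value in ", path, call. = FALSE)
  values <- t(vals) # samples x taxa
  if (is.null(value_kind)) value_kind <- infer_value_kind(values, taxa)
  abundance_table(values, sample_ids, taxa, value_kind)
}

#' Write a generic TSV OTU table
#'
#' Inverse of [read_otu_table()]: the written file round-trips to an equal
#' table (sample ids, taxon display ids, values).
#'
#' @param table an `abundance_table`.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_otu_table <- function(table, path) {
  stopifnot(inherits(table, "abundance_table"))
  if (n_taxa(table) == 0L) stop("empty table", call. = FALSE)
  header <- paste(c("taxon", table$sample_ids), collapse = "\t")
  rows <- vapply(seq_len(n_taxa(table)), function(j) {
    paste(c(table$taxa$display_id[j],
            format(table$values[, j], digits = 17, trim = TRUE,
                   scientific = FALSE)),
          collapse = "\t")
  }, "")
  writeLines(c(header, rows), path, useBytes = TRUE)
  invisible(path)
}

#' Read and merge Kraken2-style report files
#'
#' Each report is the standard 6-column tab-separated layout: percent of
#' reads, clade read count, direct read count, rank code, NCBI taxid, and the
#' taxon name indented by two spaces per level. Lineages are reconstructed
#' from the indentation; rows whose rank code is one of D/K/P/C/O/F/G/S map
#' onto the standard ladder (D and K both fill the kingdom slot, the inner
#' one demoted to a sub-rank), while other codes (R, U, S1, G1, ...) are
#' kept as sub-rank entries that rank restriction later skips.
#'
#' @param paths named character vector or list of file paths; names are the
#'   sample ids.
#' @param values which report column to store: `"count"` (clade read counts,
#'   `value_kind = "counts"`) or `"percent"` (the clade percentage column,
#'   `value_kind = "relative_percent"`).
#' @return A merged [abundance_table()] with taxa ordered lexicographically
#'   by display id; taxa absent from a sample get 0.
#' @export
read_kraken_reports <- function(paths, values = c("count", "percent")) {
  values <- match.arg(values)
  paths <- unlist(paths)
  if (is.null(names(paths)) || any(!nzchar(names(paths)))) {
    stop("every report path must be named with its sample id", call. = FALSE)
  }
  per_sample <- lapply(seq_along(paths), function(i) {
    parse_kraken_report(paths[[i]], values)
  })
  names(per_sample) <- names(paths)
  all_taxa <- sort(unique(unlist(lapply(per_sample, names))))
  mat <- matrix(0, nrow = length(paths), ncol = length(all_taxa),
                dimnames = list(names(paths), all_taxa))
  for (i in seq_along(per_sample)) {
    mat[i, names(per_sample[[i]])] <- unname(per_sample[[i]])
  }
  abundance_table(mat, names(paths), all_taxa,
                  if (values == "count") "counts" else "relative_percent")
}

# Parse one Kraken2 report into a named vector display_id -> value.
parse_kraken_report <- function(path, values) {
  lines <- read_nonempty_lines(path)
  keep_names <- character()
  keep_vals <- numeric()
  # stack of (level, prefix, name) for lineage reconstruction
  stack <- list()
  n_classified <- 0L
  for (ln in seq_along(lines)) {
    fields <- strsplit(lines[[ln]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 6L) {
      stop(path, ": line ", ln, ": expected 6 tab-separated columns",
           call. = FALSE)
    }
    pct <- suppressWarnings(as.numeric(fields[1]))
    clade <- suppressWarnings(as.numeric(fields[2]))
    direct <- suppressWarnings(as.numeric(fields[3]))
    if (anyNA(c(pct, clade, direct))) {
      stop(path, ": line ", ln, ": non-numeric count field", call. = FALSE)
    }
    code <- fields[4]
    raw_name <- fields[6]
    name <- sub("^ +", "", raw_name)
    level <- (nchar(raw_name) - nchar(name)) %/% 2L
    if (identical(code, "U")) next          # unclassified bucket
    if (identical(name, "root")) {
      stack <- list()                        # root anchors the tree, not a taxon
      next
    }
    n_classified <- n_classified + 1L
    # pop deeper-or-equal levels
    while (length(stack) && stack[[length(stack)]]$level >= level) {
      stack[[length(stack)]] <- NULL
    }
    std <- toupper(code) %in% c("D", "K", "P", "C", "O", "F", "G", "S") &&
      nchar(code) == 1L
    prefix <- if (std) {
      p <- c(D = "k", K = "k", P = "p", C = "c", O = "o", F = "f",
             G = "g", S = "s")[[toupper(code)]]
      # a K inside an existing kingdom (D) is demoted to a sub-rank stratum
      if (p %in% vapply(stack, `[[`, "", "prefix")) tolower(code) else p
    } else {
      tolower(code)
    }
    stack[[length(stack) + 1L]] <- list(level = level, prefix = prefix,
                                        name = gsub("|", "/", name, fixed = TRUE))
    display_id <- paste(vapply(stack, function(s)
      paste0(s$prefix, "__", s$name), ""), collapse = "|")
    keep_names <- c(keep_names, display_id)
    keep_vals <- c(keep_vals, if (values == "count") clade else pct)
  }
  if (n_classified == 0L) stop(path, ": no classified taxa", call. = FALSE)
  if (anyDuplicated(keep_names)) {
    dup <- keep_names[duplicated(keep_names)][1]
    stop(path, ": duplicated clade '", dup, "'", call. = FALSE)
  }
  stats::setNames(keep_vals, keep_names)
}

#' Read a MetaPhlAn-style merged relative-abundance table
#'
#' First column: clade names with `k__`/`p__`/.../`s__` prefixes joined by
#' `|`; remaining columns: per-sample relative abundances on the percent
#' scale. Each taxon's rank is its deepest prefix. Unknown prefixes are an
#' error (strict parsing).
#'
#' @param path file path.
#' @return An [abundance_table()] with `value_kind = "relative_percent"`.
#' @export
read_metaphlan_table <- function(path) {
  lines <- read_nonempty_lines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) < 2L) stop("empty table: ", path, call. = FALSE)
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  sample_ids <- header[-1]
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample column '",
         sample_ids[duplicated(sample_ids)][1], "'", call. = FALSE)
  }
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  taxa <- vapply(body, `[[`, "", 1L)
  for (i in seq_along(taxa)) {
    parse_taxon(taxa[i], strict = TRUE, context = paste0("line ", i + 1L))
  }
  vals <- t(vapply(body, function(f) {
    v <- suppressWarnings(as.numeric(f[-1]))
    if (anyNA(v)) stop("non-numeric abundance in row '", f[1], "'",
                       call. = FALSE)
    v
  }, numeric(length(sample_ids))))
  if (length(sample_ids) == 1L) vals <- matrix(vals, ncol = 1L)
  abundance_table(t(vals), sample_ids, taxa, "relative_percent")
}

#' Write a MetaPhlAn-style merged table
#'
#' Convenience inverse of [read_metaphlan_table()]; requires a
#' `relative_percent` table.
#'
#' @param table an `abundance_table` with `value_kind = "relative_percent"`.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_metaphlan_table <- function(table, path) {
  stopifnot(inherits(table, "abundance_table"))
  if (table$value_kind != "relative_percent") {
    stop("MetaPhlAn tables are percent-scale; convert with to_relative_percent()",
         call. = FALSE)
  }
  header <- paste(c("clade_name", table$sample_ids), collapse = "\t")
  rows <- vapply(seq_len(n_taxa(table)), function(j) {
    paste(c(table$taxa$display_id[j],
            format(table$values[, j], digits = 17, trim = TRUE,
                   scientific = FALSE)),
          collapse = "\t")
  }, "")
  writeLines(c(header, rows), path, useBytes = TRUE)
  invisible(path)
}

#' Construct sample metadata (label encoding)
#'
#' @param sample_ids character vector of sample ids.
#' @param labels character vector of class labels, parallel to `sample_ids`.
#' @return A `sample_metadata` object: `mapping` (named character vector
#'   sample id -> label), `label_order` (sorted distinct labels) and
#'   `label_index` (named integer vector label -> 0..N-1 in that order).
#' @export
sample_metadata <- function(sample_ids, labels) {
  sample_ids <- as.character(sample_ids)
  labels <- as.character(labels)
  stopifnot(length(sample_ids) == length(labels))
  dup <- duplicated(sample_ids)
  if (any(dup)) {
    for (id in unique(sample_ids[dup])) {
      if (length(unique(labels[sample_ids == id])) > 1L) {
        stop("conflicting labels for sample '", id, "'", call. = FALSE)
      }
    }
    labels <- labels[!dup]
    sample_ids <- sample_ids[!dup]
  }
  label_order <- sort(unique(labels))
  if (length(label_order) < 2L) stop("need >=2 classes", call. = FALSE)
  out <- list(
    mapping = stats::setNames(labels, sample_ids),
    label_order = label_order,
    label_index = stats::setNames(seq_along(label_order) - 1L, label_order)
  )
  class(out) <- "sample_metadata"
  out
}

#' @export
print.sample_metadata <- function(x, ...) {
  cat("<sample_metadata> ", length(x$mapping), " samples, ",
      length(x$label_order), " classes\n", sep = "")
  tb <- table(x$mapping)
  cat(" ", paste0(names(tb), " (index ", x$label_index[names(tb)], "): ",
                  tb, collapse = "; "), "\n")
  invisible(x)
}

#' Read a sample metadata TSV
#'
#' Two tab-separated columns, `sample_id` and `label`, with an optional
#' header row (recognised when the first field is `sample_id`, `sample`,
#' `id`, or a `#`-prefixed variant).
#'
#' @param path file path.
#' @return A [sample_metadata()] object. Labels are indexed 0..N-1 in
#'   lexicographic order.
#' @export
read_metadata <- function(path) {
  lines <- read_nonempty_lines(path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 2L)) {
    stop("metadata line ", which(lengths(fields) < 2L)[1],
         ": expected 'sample_id<TAB>label'", call. = FALSE)
  }
  first <- tolower(sub("^#", "", fields[[1]][1]))
  if (first %in% c("sample_id", "sample", "id", "sampleid")) {
    fields <- fields[-1]
  }
  if (length(fields) == 0L) stop("empty metadata file: ", path, call. = FALSE)
  sample_metadata(vapply(fields, `[[`, "", 1L),
                  vapply(fields, `[[`, "", 2L))
}

#' Align an abundance table with sample metadata
#'
#' @param table an `abundance_table`.
#' @param meta a `sample_metadata`.
#' @param policy `"intersect"` restricts both to the shared sample ids in
#'   table order; `"strict"` errors if the id sets differ.
#' @return List with elements `table` and `meta`, both restricted.
#' @export
align_table_metadata <- function(table, meta,
                                 policy = c("intersect", "strict")) {
  policy <- match.arg(policy)
  shared <- table$sample_ids[table$sample_ids %in% names(meta$mapping)]
  if (length(shared) == 0L) {
    stop("no shared sample ids between table and metadata", call. = FALSE)
  }
  if (policy == "strict") {
    only_t <- setdiff(table$sample_ids, names(meta$mapping))
    only_m <- setdiff(names(meta$mapping), table$sample_ids)
    if (length(only_t) || length(only_m)) {
      stop("unmatched sample ids: table-only {",
           paste(only_t, collapse = ", "), "}, metadata-only {",
           paste(only_m, collapse = ", "), "}", call. = FALSE)
    }
  }
  list(
    table = subset_samples(table, shared),
    meta = sample_metadata(shared, unname(meta$mapping[shared]))
  )
}

read_nonempty_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines[nzchar(trimws(lines))]
}
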