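#' @keywords internal
"_PACKAGE"

# Canonical rank ladder used throughout the package (domain and kingdom are
# collapsed onto the "kingdom" slot, as in MetaPhlAn-style k__ prefixes).
RANKS <- c("kingdom", "phylum", "class", "order", "family", "genus", "species")
RANK_PREFIX <- c(
  kingdom = "k", phylum = "p", class = "c", order = "o",
  family = "f", genus = "g", species = "s"
)
PREFIX_RANK <- stats::setNames(names(RANK_PREFIX), RANK_PREFIX)

#' Taxonomic ranks supported by the package
#'
#' @return Character vector of rank names from kingdom down to species.
#' @export
taxonomic_ranks <- function() RANKS

#' Parse a pipe-joined lineage string into a taxon entry
#'
#' Lineage strings use MetaPhlAn-style rank prefixes joined by `|`, e.g.
#' `"k__Bacteria|p__Firmicutes|...|s__Taxon_x"`. The standard prefixes are
#' `k__`, `p__`, `c__`, `o__`, `f__`, `g__`, `s__`. Segments with other
#' short alphanumeric prefixes (such as the `s1__` strata found below the
#' species level in Kraken2 reports) are accepted when `strict = FALSE` and
#' carried as unranked sub-levels; they are excluded by rank restriction.
#'
#' @param lineage_string a single pipe-joined lineage string.
#' @param strict when `TRUE`, only the seven standard prefixes are accepted
#'   (MetaPhlAn contract); otherwise sub-rank prefixes are tolerated.
#' @param context optional string (e.g. a line number) used in error messages.
#' @return A `taxon_entry`: list with `lineage` (data.frame of rank/prefix/
#'   name), `rank` (terminal standard rank or `NA` for sub-rank entries) and
#'   `display_id` (the canonical string; `format_taxon()` returns it).
#' @export
parse_taxon <- function(lineage_string, strict = FALSE, context = NULL) {
  where <- if (is.null(context)) "" else paste0(" (", context, ")")
  if (length(lineage_string) != 1L || is.na(lineage_string) ||
      !nzchar(lineage_string)) {
    stop("empty lineage string", where, call. = FALSE)
  }
  segs <- strsplit(lineage_string, "|", fixed = TRUE)[[1]]
  m <- regmatches(segs, regexec("^([A-Za-z][A-Za-z0-9]{0,2})__(.*)$", segs))
  bad <- vapply(m, length, 1L) == 0L
  if (any(bad)) {
    stop("malformed lineage segment '", segs[which(bad)[1]], "'", where,
         call. = FALSE)
  }
  prefix <- tolower(vapply(m, `[[`, "", 2L))
  name <- vapply(m, `[[`, "", 3L)
  rank <- unname(PREFIX_RANK[prefix])
  if (strict && anyNA(rank)) {
    stop("unknown rank prefix '", prefix[which(is.na(rank))[1]], "__'", where,
         call. = FALSE)
  }
  std <- !is.na(rank)
  ord <- match(rank[std], RANKS)
  if (anyDuplicated(ord) || is.unsorted(ord, strictly = TRUE)) {
    stop("lineage ranks not in strictly descending taxonomic order: '",
         lineage_string, "'", where, call. = FALSE)
  }
  terminal <- rank[length(rank)]
  entry <- list(
    lineage = data.frame(rank = rank, prefix = prefix, name = name,
                         stringsAsFactors = FALSE),
    rank = terminal,
    display_id = paste0(prefix, "__", name, collapse = "|")
  )
  class(entry) <- "taxon_entry"
  entry
}

#' Format a taxon entry back to its canonical pipe-joined string
#'
#' `parse_taxon(format_taxon(x))` reproduces `x`.
#'
#' @param entry a `taxon_entry`.
#' @return The canonical display id string.
#' @export
format_taxon <- function(entry) {
  stopifnot(inherits(entry, "taxon_entry"))
  entry$display_id
}

#' @export
print.taxon_entry <- function(x, ...) {
  cat("<taxon_entry> ", x$display_id, "\n  terminal rank: ",
      if (is.na(x$rank)) "(sub-rank)" else x$rank, "\n", sep = "")
  invisible(x)
}

# Terminal rank of each display id in a character vector (NA for sub-rank).
terminal_ranks <- function(display_ids) {
  last <- sub(".*\\|", "", display_ids)
  prefix <- tolower(sub("__.*$", "", last))
  unname(PREFIX_RANK[prefix])
}
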