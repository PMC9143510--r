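# Seeded synthetic case/control profile generator. Latent per-taxon
# abundances are log-normal with a multiplicative class effect on a block of
# informative taxa; sparsity zeroes entries at random; counts are obtained
# by closing each sample's latent composition to a (varying) sequencing
# depth. This emulates the heavy-tailed, sparse, compositional character of
# real taxonomic profiles without any community ecology.

#' Configuration for the synthetic profile generator
#'
#' @param n_per_class integer vector: samples per class (length = number of
#'   classes, >= 2).
#' @param n_taxa number of species-level taxa.
#' @param n_informative number of class-informative taxa (<= n_taxa).
#' @param log_fold_change class effect: informative taxa are multiplied by
#'   `exp(log_fold_change)` in their case class (>= 0).
#' @param base_lognormal_mu,base_lognormal_sigma parameters of the latent
#'   log-normal abundances.
#' @param sparsity probability a taxon's count is zeroed in a sample, in
#'   \[0, 1).
#' @param depth mean sequencing depth; per-sample depths vary uniformly
#'   within +/- 50% of it.
#' @param seed integer seed.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_per_class = c(100L, 100L), n_taxa = 200L,
                         n_informative = 20L, log_fold_change = 3,
                         base_lognormal_mu = 0, base_lognormal_sigma = 1,
                         sparsity = 0.3, depth = 50000, seed = 1L) {
  stopifnot(length(n_per_class) >= 2, all(n_per_class >= 1),
            n_taxa >= 1, n_informative >= 0, n_informative <= n_taxa,
            log_fold_change >= 0, sparsity >= 0, sparsity < 1, depth > 0)
  structure(list(n_per_class = as.integer(n_per_class),
                 n_taxa = as.integer(n_taxa),
                 n_informative = as.integer(n_informative),
                 log_fold_change = log_fold_change,
                 base_lognormal_mu = base_lognormal_mu,
                 base_lognormal_sigma = base_lognormal_sigma,
                 sparsity = sparsity, depth = depth,
                 seed = as.integer(seed)),
            class = "synth_config")
}

synth_lineages <- function(n_taxa) {
  w <- max(3L, nchar(as.character(n_taxa)))
  genus <- sprintf(paste0("SynG_%0", w, "d"), (seq_len(n_taxa) - 1L) %/% 10L + 1L)
  species <- sprintf(paste0("SynSp_%0", w, "d"), seq_len(n_taxa))
  paste0("k__SynK|p__SynP|c__SynC|o__SynO|f__SynF|g__", genus, "|s__",
         species)
}

#' Generate a labeled synthetic abundance table
#'
#' Per sample: latent abundances are drawn log-normal(mu, sigma); the
#' informative taxa of the sample's case class are multiplied by
#' `exp(log_fold_change)` (with more than two classes the informative block
#' is split evenly between the case classes; class_0 is always the
#' control); sparsity zeroes entries; counts close the latent composition
#' to the sample's sequencing depth. Fully seeded: the same config yields
#' the identical table.
#'
#' @param config a [synth_config()].
#' @return List with `table` (counts `abundance_table`, species-level
#'   synthetic lineages), `meta` ([sample_metadata()] with labels
#'   `class_0`, `class_1`, ...), and `informative_taxa` (the ground-truth
#'   display ids).
#' @export
synth_generate <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n_classes <- length(config$n_per_class)
  n <- sum(config$n_per_class)
  labels <- rep(paste0("class_", seq_len(n_classes) - 1L),
                config$n_per_class)
  sample_ids <- sprintf(paste0("sample_%0", nchar(as.character(n)), "d"),
                        seq_len(n))
  taxa <- synth_lineages(config$n_taxa)
  informative <- taxa[seq_len(config$n_informative)]
  # assign informative taxa to case classes in even blocks
  case_of_taxon <- if (config$n_informative > 0 && n_classes >= 2) {
    rep_len(seq.int(2L, n_classes), config$n_informative)
  } else integer()
  counts <- withr::with_seed(config$seed, {
    m <- matrix(0, n, config$n_taxa, dimnames = list(sample_ids, taxa))
    class_idx <- rep(seq_len(n_classes), config$n_per_class)
    for (s in seq_len(n)) {
      latent <- stats::rlnorm(config$n_taxa, config$base_lognormal_mu,
                              config$base_lognormal_sigma)
      if (class_idx[s] >= 2L && config$n_informative > 0) {
        hit <- which(case_of_taxon == class_idx[s])
        latent[hit] <- latent[hit] * exp(config$log_fold_change)
      }
      if (config$sparsity > 0) {
        drop <- stats::runif(config$n_taxa) < config$sparsity
        drop[which.max(latent)] <- FALSE  # keep every sample non-empty
        latent[drop] <- 0
      }
      depth_s <- config$depth * stats::runif(1, 0.5, 1.5)
      m[s, ] <- round(latent / sum(latent) * depth_s)
    }
    m
  })
  list(table = abundance_table(counts, sample_ids, taxa, "counts"),
       meta = sample_metadata(sample_ids, labels),
       informative_taxa = informative)
}

#' Render a generated table as Kraken2-style report files
#'
#' Generates the table for `config` and writes one syntactically valid
#' Kraken2-style report per sample into `out_dir`: six tab-separated
#' columns, two-space indentation per level, clade counts consistent up the
#' synthetic lineage (each genus line sums its species lines), plus the
#' usual unclassified and root lines. Species with zero count in a sample
#' are omitted, as a real report would. Reading the files back with
#' [read_kraken_reports()] reproduces the species-level counts exactly.
#'
#' @param config a [synth_config()].
#' @param out_dir output directory (created if missing).
#' @return List as [synth_generate()] plus `paths` (named vector of report
#'   files, names = sample ids).
#' @export
generate_kraken_reports <- function(config, out_dir) {
  gen <- synth_generate(config)
  if (!dir.exists(out_dir)) {
    if (!dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
      stop("cannot create directory ", out_dir, call. = FALSE)
    }
  }
  taxa <- gen$table$taxa$display_id
  genus_of <- sub("\\|s__.*$", "", taxa)           # lineage up to genus
  genus_names <- sub("^.*\\|g__", "", genus_of)
  species_names <- sub("^.*\\|s__", "", taxa)
  paths <- stats::setNames(
    file.path(out_dir, paste0(gen$table$sample_ids, "_report.txt")),
    gen$table$sample_ids)
  for (s in seq_along(gen$table$sample_ids)) {
    v <- gen$table$values[s, ]
    total <- sum(v)
    line <- function(pct, clade, direct, code, taxid, name, indent) {
      sprintf("%6.2f\t%d\t%d\t%s\t%d\t%s%s", pct, clade, direct, code,
              taxid, strrep("  ", indent), name)
    }
    pctf <- function(x) if (total > 0) 100 * x / total else 0
    out <- c(
      line(0, 0L, 0L, "U", 0L, "unclassified", 0L),
      line(100, as.integer(total), 0L, "R", 1L, "root", 0L),
      line(100, as.integer(total), 0L, "D", 2L, "SynK", 1L),
      line(100, as.integer(total), 0L, "P", 3L, "SynP", 2L),
      line(100, as.integer(total), 0L, "C", 4L, "SynC", 3L),
      line(100, as.integer(total), 0L, "O", 5L, "SynO", 4L),
      line(100, as.integer(total), 0L, "F", 6L, "SynF", 5L)
    )
    taxid <- 7L
    for (g in unique(genus_names)) {
      in_g <- genus_names == g
      g_total <- sum(v[in_g])
      if (g_total == 0) next
      out <- c(out, line(pctf(g_total), as.integer(g_total), 0L, "G",
                         taxid, g, 6L))
      taxid <- taxid + 1L
      for (j in which(in_g & v > 0)) {
        out <- c(out, line(pctf(v[j]), as.integer(v[j]),
                           as.integer(v[j]), "S", taxid,
                           species_names[j], 7L))
        taxid <- taxid + 1L
      }
    }
    writeLines(out, paths[s], useBytes = TRUE)
  }
  c(gen, list(paths = paths))
}
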