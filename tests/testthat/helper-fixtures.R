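# Small builders shared across the suite. Everything is generated in code.

toy_table <- function(values, sample_ids = NULL, taxa = NULL,
                      value_kind = "counts") {
  values <- as.matrix(values)
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(values)))
  if (is.null(taxa)) {
    taxa <- paste0("k__K|p__P|c__C|o__O|f__F|g__G", seq_len(ncol(values)),
                   "|s__Sp", seq_len(ncol(values)))
  }
  abundance_table(values, sample_ids, taxa, value_kind)
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# a hand-built 5-clade Kraken2-style report (plus unclassified + root)
toy_kraken_report <- function(path, sp1 = 60L, sp2 = 30L, genus_extra = 0L) {
  total <- sp1 + sp2 + genus_extra
  lines <- c(
    sprintf("  0.00\t0\t0\tU\t0\tunclassified"),
    sprintf("100.00\t%d\t0\tR\t1\troot", total),
    sprintf("100.00\t%d\t0\tD\t2\t  Bacteria", total),
    sprintf("100.00\t%d\t0\tP\t3\t    Firmicutes", total),
    sprintf("100.00\t%d\t%d\tG\t4\t      Genus1", total, genus_extra),
    sprintf(" %.2f\t%d\t%d\tS\t5\t        Species1", 100 * sp1 / total, sp1, sp1),
    sprintf(" %.2f\t%d\t%d\tS\t6\t        Species2", 100 * sp2 / total, sp2, sp2)
  )
  writeLines(lines, path)
  path
}

# fast, convergent training configuration used for learning-behavior tests
# (shallow net, no dropout, grid-range learning rate, enough epochs)
convergent_net <- function(seed = 1L, epochs = 120L) {
  network_config(n_layers = 2L, n_neurons = 32L, dropout_enabled = FALSE,
                 learning_rate = 1e-3, epochs = epochs, batch_size = 50L,
                 seed = seed)
}
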