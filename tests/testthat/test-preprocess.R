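test_that("rank restriction keeps exactly the requested rank and is idempotent", {
  taxa <- c("k__K|p__P|c__C|o__O|f__F|g__G1|s__Sp1",
            "k__K|p__P|c__C|o__O|f__F|g__G1|s__Sp2",
            "k__K|p__P|c__C|o__O|f__F|g__G1")
  tab <- abundance_table(matrix(1:6, 2, 3), c("a", "b"), taxa, "counts")
  sp <- restrict_to_rank(tab, "species")
  expect_identical(n_taxa(sp), 2L)
  expect_identical(restrict_to_rank(sp, "species"), sp)
  expect_identical(n_taxa(restrict_to_rank(tab, "genus")), 1L)
  expect_error(restrict_to_rank(sp, "family"), "family")
})

test_that("relative percent closes counts and passes percent through", {
  tab <- toy_table(matrix(c(2, 3, 5), 1, 3))
  pct <- to_relative_percent(tab)
  expect_equal(unname(pct$values[1, ]), c(20, 30, 50))
  expect_identical(to_relative_percent(pct), pct)
  zero <- toy_table(matrix(c(1, 1, 1, 0, 0, 0), 2, 3, byrow = TRUE),
                    sample_ids = c("ok", "empty"))
  expect_error(to_relative_percent(zero), "empty")
})

test_that("abundance filter is boundary-inclusive and replayable", {
  vals <- matrix(c(0.50, 0.02, 0.03,
                   0.10, 0.01, 0.01), 2, 3, byrow = TRUE)
  tab <- toy_table(vals, value_kind = "relative_percent")
  f <- filter_abundance(tab, 0.03)
  expect_identical(f$retained_taxa, tab$taxa$display_id[c(1, 3)])
  expect_identical(filter_abundance(tab, 0)$retained_taxa,
                   tab$taxa$display_id)
  expect_error(filter_abundance(tab, 5), "threshold")
})

test_that("abundance filter agrees with a brute-force scan on 200 taxa", {
  set.seed(11)
  vals <- matrix(rexp(40 * 200), 40, 200)
  vals <- vals / rowSums(vals) * 100
  tab <- toy_table(vals, value_kind = "relative_percent")
  maxima <- apply(vals, 2, max)
  thresholds <- c(sort(maxima)[150], sample(maxima, 10),
                  runif(9, 0, max(maxima)))
  for (th in thresholds) {
    keep_brute <- which(vapply(seq_len(200), function(j)
      max(vals[, j]) >= th, TRUE))
    f <- filter_abundance(tab, th)
    expect_identical(f$retained_taxa, tab$taxa$display_id[keep_brute])
  }
  # filtering is invariant to sample order
  perm <- sample(nrow(vals))
  tab_p <- toy_table(vals[perm, ], sample_ids = tab$sample_ids[perm],
                     value_kind = "relative_percent")
  expect_identical(filter_abundance(tab_p, 0.5)$retained_taxa,
                   filter_abundance(tab, 0.5)$retained_taxa)
})

test_that("CSS factors match the hand-computed case and the scaling contract", {
  tab <- toy_table(matrix(c(1, 2, 3, 4), 1, 4))
  out <- css_normalize(tab, 0.5)
  # median of positives 2.5 -> factor = 1 + 2 = 3; single sample => ref = 3
  expect_equal(unname(out$state$per_sample_factors), 3)
  expect_equal(out$state$reference_scale, 3)
  expect_equal(unname(out$table$values[1, ]), c(1, 2, 3, 4))

  # multiplying one sample by 10 leaves its normalized row unchanged
  two <- toy_table(rbind(c(1, 2, 3, 4), 10 * c(1, 2, 3, 4)))
  n2 <- css_normalize(two, 0.5)
  expect_equal(n2$table$values[1, ], n2$table$values[2, ])
  expect_equal(unname(n2$state$per_sample_factors), c(3, 30))

  # identical samples get identical factors and rows
  same <- toy_table(rbind(c(5, 1, 0, 2), c(5, 1, 0, 2)))
  ns <- css_normalize(same, 0.5)
  expect_equal(ns$table$values[1, ], ns$table$values[2, ])
  expect_equal(ns$state$per_sample_factors[[1]],
               ns$state$per_sample_factors[[2]])

  expect_error(css_normalize(tab, 1.2), "quantile")
  allzero <- abundance_table(rbind(c(1, 2), c(0, 0)), c("a", "b"),
                             c("k__A|s__X", "k__A|s__Y"), "counts")
  expect_error(css_normalize(allzero, 0.5), "'b'")
})

test_that("CSS prediction mode reuses the stored reference scale only", {
  set.seed(2)
  train <- toy_table(matrix(rexp(50), 5, 10))
  fit <- css_normalize(train, 0.5)
  # re-normalizing one training sample alone reproduces its row bit-for-bit
  single <- toy_table(train$values[2, , drop = FALSE], sample_ids = "s2")
  re <- css_normalize(single, state = fit$state)
  expect_identical(re$table$values[1, ], fit$table$values[2, ])
})

test_that("stratified splits hit exact per-class counts and are deterministic", {
  meta <- sample_metadata(sprintf("s%03d", 1:100),
                          rep(c("case", "ctrl"), c(40, 60)))
  cfg <- preprocess_config(test_fraction = 0.15, validation_fraction = 0.15,
                           seed = 7)
  sp <- stratified_split(meta, cfg)
  test_labels <- meta$mapping[sp$test_ids]
  expect_identical(sum(test_labels == "ctrl"), 9L)
  expect_identical(sum(test_labels == "case"), 6L)
  expect_identical(stratified_split(meta, cfg), sp)
  all_ids <- sort(c(sp$train_ids, sp$validation_ids, sp$test_ids))
  expect_identical(all_ids, sort(names(meta$mapping)))
  expect_length(intersect(sp$train_ids, sp$test_ids), 0L)
  expect_length(intersect(sp$validation_ids, sp$test_ids), 0L)

  novalid <- stratified_split(meta, preprocess_config(
    validation_fraction = 0, seed = 7))
  expect_length(novalid$validation_ids, 0L)
  expect_identical(sort(c(novalid$train_ids, novalid$test_ids)),
                   sort(names(meta$mapping)))

  tiny <- sample_metadata(c("a", "b", "c", "d"), c("x", "x", "x", "y"))
  expect_error(stratified_split(tiny, cfg), "'y'")
})

test_that("feature assembly fixes column order and zero-fills missing taxa", {
  gen <- synth_generate(synth_config(n_per_class = c(4L, 4L), n_taxa = 12L,
                                     n_informative = 3L, seed = 5))
  tab <- to_relative_percent(restrict_to_rank(gen$table, "species"))
  retained <- tab$taxa$display_id
  fm <- assemble_features(tab, retained, gen$meta)
  expect_identical(dim(fm$features), c(8L, 12L))
  expect_identical(colnames(fm$features), retained)
  expect_identical(sort(unique(fm$labels)), 0:1)
  # permuting input columns leaves the matrix unchanged
  perm <- sample(12)
  tab_p <- abundance_table(tab$values[, perm], tab$sample_ids,
                           tab$taxa$display_id[perm], tab$value_kind)
  expect_identical(assemble_features(tab_p, retained)$features, fm$features)
  # dropping taxa zero-fills them
  tab_d <- abundance_table(tab$values[, -c(1, 5, 9)], tab$sample_ids,
                           tab$taxa$display_id[-c(1, 5, 9)], tab$value_kind)
  fd <- assemble_features(tab_d, retained)$features
  expect_true(all(fd[, c(1, 5, 9)] == 0))
  expect_identical(fd[, -c(1, 5, 9)], fm$features[, -c(1, 5, 9)])
})

test_that("replaying the saved preprocessing state reproduces training features", {
  gen <- synth_generate(synth_config(n_per_class = c(12L, 12L),
                                     n_taxa = 40L, n_informative = 8L,
                                     seed = 9))
  cfg <- preprocess_config(seed = 9)
  prep <- preprocess_fit(gen$table, gen$meta, cfg)
  replay <- preprocess_apply(gen$table, prep$retained_taxa, cfg,
                             prep$normalization)
  expect_identical(replay[rownames(prep$features), ], prep$features)
})
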