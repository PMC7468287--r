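small_expression <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_expression(expression_spec(n_genes = 2000, seed = 4))
    cache
  }
})

test_that("expression_spec validates invariants", {
  expect_error(expression_spec(n_genes = 10, planted_gene_count = 11), "exceed")
  expect_error(expression_spec(planted_fold_range = c(0.5, 2)), "> 1")
  expect_error(expression_spec(target_regions = "a", contrast_regions = "a"),
               "disjoint")
})

test_that("generated table has full factorial coverage and positive values", {
  es <- small_expression()
  t <- es$table
  expect_equal(nrow(t), 2000 * 2 * 11 * 4)
  expect_true(all(t$value > 0))
  expect_equal(length(unique(t$gene_id)), 2000)
  expect_setequal(unique(t$layer), c("SG", "MZ", "CP", "SP"))
  expect_identical(generate_expression(es$spec)$table$value, t$value)
})

test_that("aggregation is the linear-scale mean over specimens and structures", {
  df <- expand.grid(gene_id = "g1", specimen_id = c("s1", "s2"),
                    region = c("t1", "t2", "c1"), layer = "SG",
                    stringsAsFactors = FALSE)
  df$value <- c(1, 2, 3, 4, 10, 20)
  t <- as_expression_table(df)
  cfg <- region_set_config(c("t1", "t2"), "c1")
  agg <- aggregate_expression(t, cfg, "SG")
  expect_equal(agg$target_mean, mean(c(1, 2, 3, 4)))
  expect_equal(agg$contrast_mean, 15)
  expect_equal(agg$n_target, 4L)
  expect_error(aggregate_expression(t, cfg, "CP"), "not present")
})

test_that("fold change applies the pseudocount symmetrically", {
  expect_equal(fold_change(10, 0), 10.5 / 0.5)
  expect_equal(fold_change(0, 0), 1)
  expect_equal(fold_change(3, 1, eps = 0), 3)
  expect_error(fold_change(-1, 2), "non-negative")
})

test_that("percentile selection count follows the rank-based rule", {
  folds <- stats::setNames(seq_len(35000) / 1000, sprintf("g%05d", 1:35000))
  sel <- select_top_percentile(folds, 99.9)
  expect_equal(sel$n_selected, 35)
  expect_equal(sum(sel$table$selected), 35)
  # selected genes are exactly the 35 largest folds
  expect_setequal(sel$table$gene_id[sel$table$selected],
                  names(sort(folds, decreasing = TRUE))[1:35])
  # tiny tables floor at one gene
  expect_equal(select_top_percentile(c(a = 1, b = 2), 99.9)$n_selected, 1)
})

test_that("boundary ties break lexicographically and ranks are dense", {
  folds <- c(z = 5, a = 5, m = 5, b = 1)
  sel <- select_top_percentile(folds, 50)   # n_sel = round(4 * 0.5) = 2
  expect_equal(sel$n_selected, 2)
  expect_identical(sel$table$gene_id[sel$table$selected], c("a", "m"))
  expect_identical(sel$table$rank, c(1L, 1L, 1L, 2L))
  expect_equal(sel$cutoff_fold, 5)
})

test_that("planted genes dominate the per-layer selection", {
  es <- small_expression()
  res <- contrast_report(es$table)
  expect_identical(res$cutoffs$layer, c("SG", "MZ", "CP", "SP"))
  for (b in res$layers) {
    expect_equal(b$n_selected, 2)   # 2000 genes -> top 0.1% = 2
    sel <- b$table$gene_id[b$table$selected]
    planted <- es$truth$gene_id[es$truth$layer == b$layer]
    expect_true(all(sel %in% planted))
  }
})

test_that("null table (no planted signal) yields folds near 1", {
  es0 <- generate_expression(expression_spec(n_genes = 2000,
                                             planted_gene_count = 0, seed = 9))
  agg <- aggregate_expression(es0$table, region_set_config(), "CP")
  folds <- fold_change(agg$target_mean, agg$contrast_mean)
  expect_gt(stats::median(folds), 0.9)
  expect_lt(stats::median(folds), 1.1)
})

test_that("a layer with an empty contrast side is skipped with a warning", {
  es <- small_expression()
  t <- es$table
  keep <- !(t$layer == "MZ" & t$region %in% default_contrast_structures())
  t2 <- as_expression_table(as.data.frame(t)[keep, ])
  expect_warning(res <- contrast_report(t2), "MZ")
  expect_false("MZ" %in% res$cutoffs$layer)
  expect_setequal(res$cutoffs$layer, c("SG", "CP", "SP"))
})
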