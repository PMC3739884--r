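test_that("Akaike weights follow the closed form and normalize", {
  tr <- worked_tree()
  scan <- single_threshold_scan(tr)
  cmp <- model_comparison(scan$models, tr)
  expect_equal(sum(cmp$weights), 1, tolerance = 1e-12)
  # weights for AIC gap of 2: exp(-1) / (1 + exp(-1)) on a two-model set
  w2 <- exp(-(c(10, 12) - 10) / 2)
  expect_equal((w2 / sum(w2))[1], 0.7311, tolerance = 1e-4)
  expect_true(all(diff(cmp$table$aic) >= 0))
  expect_true(1 %in% cmp$confidence_set)  # best model always in the set
  expect_true(all(cmp$support >= 0 & cmp$support <= 1))
})

test_that("duplicate delimitations are removed before weighting", {
  tr <- worked_tree()
  scan <- single_threshold_scan(tr)
  doubled <- c(scan$models, scan$models[!vapply(scan$models,
                                                function(f) f$is_null, TRUE)])
  cmp1 <- model_comparison(scan$models, tr)
  cmp2 <- model_comparison(doubled, tr)
  expect_equal(nrow(cmp2$table), nrow(cmp1$table))
  expect_equal(cmp2$weights, cmp1$weights, tolerance = 1e-12)
  expect_error(model_comparison(scan$models[
    !vapply(scan$models, function(f) f$is_null, TRUE)], tr), "null")
})

test_that("node support sums model weights containing the node", {
  # two tight 3-tip clusters separated by a deep split: the two-cluster
  # model should dominate the comparison
  tr <- read_newick(paste0(
    "(((a1:0.01,a2:0.01):0.01,a3:0.02):0.98,",
    "((b1:0.012,b2:0.012):0.01,b3:0.022):0.978);"))
  scan <- single_threshold_scan(tr)
  cmp <- model_comparison(scan$models, tr)
  best <- scan$best
  expect_equal(best$k, 2L)
  s <- cmp$support[as.character(best$delimitation$mrca)]
  expect_true(all(s > 0.5))
  # a node present in every non-null model has support = sum of their weights
  w_nonnull <- sum(cmp$weights[!cmp$table$is_null])
  expect_lte(max(cmp$support), w_nonnull + 1e-12)
})

test_that("model-averaged estimates are weight-blended with unconditional SEs", {
  tr <- read_newick("((a:0.01,b:0.01):0.99,(c:0.012,d:0.012):0.988);")
  scan <- single_threshold_scan(tr)
  cmp <- model_comparison(scan$models, tr, se = TRUE)
  avg <- cmp$averaged
  expect_setequal(avg$parameter,
                  c("lambda_spec", "p_spec", "lambda_coal", "p_coal"))
  lc <- avg$estimate[avg$parameter == "lambda_coal"]
  rng <- range(vapply(cmp$models, function(f) f$lambda_coal, 0))
  expect_gte(lc, rng[1]); expect_lte(lc, rng[2])
  expect_true(all(avg$se[!is.na(avg$se)] >= 0))
})

test_that("confidence set grows to reach the requested level", {
  tr <- worked_tree()
  scan <- single_threshold_scan(tr)
  for (lv in c(0.5, 0.95, 0.99)) {
    cmp <- model_comparison(scan$models, tr, level = lv)
    expect_gte(sum(cmp$weights[cmp$confidence_set]), lv)
    # minimality: dropping the last member goes below the level
    if (length(cmp$confidence_set) > 1L)
      expect_lt(sum(cmp$weights[utils::head(cmp$confidence_set, -1)]), lv)
  }
})
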