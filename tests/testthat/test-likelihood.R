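test_that("null likelihood matches the hand-computed worked example", {
  tr <- worked_tree()
  # lnL = ln(12 lambda^2) - 2.8 lambda at p = 1; lambda = 5/7 is the exact
  # profile optimum 2 / (6*0.2 + 2*0.8)
  expect_equal(null_loglik(tr, 5 / 7, 1), log(12 * (5 / 7)^2) - 2,
               tolerance = 1e-12)
  # 2-tip tree: single exponential observation, profile lambda = 1/(2x)
  tr2 <- read_newick("(a:0.7,b:0.7);")
  iv2 <- compute_intervals(tr2, NULL)
  expect_equal(moran_lambdas(iv2, p_coal = 1)$lambda_coal, 1 / (2 * 0.7))
  # exponential scale family: doubling ages and halving lambda shifts lnL
  # by exactly -(M-1) log 2
  tr_big <- rescale_root_age(tr, 2)
  expect_equal(null_loglik(tr_big, 5 / 14, 1),
               null_loglik(tr, 5 / 7, 1) - 2 * log(2), tolerance = 1e-10)
  expect_error(null_loglik(tr, -1), "positive")
})

test_that("mixed likelihood and rate estimators match the worked example", {
  tr <- worked_tree()
  iv <- compute_intervals(tr, delimitation(tr, mrca = 5L, singletons = 3L))

  ml <- moran_lambdas(iv, 1, 1)
  expect_equal(ml$lambda_coal, 2.5, tolerance = 1e-12)     # 1 / (2*0.2)
  expect_equal(ml$lambda_spec, 5 / 9, tolerance = 1e-12)   # 1 / (1*0.2 + 2*0.8)

  # total-rate likelihood at the Moran rates, by hand:
  # ln(5/9 + 2*2.5) - (5/9 + 5)*0.2 + ln(2*5/9) - (2*5/9)*0.8
  expect_equal(mixed_loglik(iv, 5 / 9, 1, 2.5, 1),
               log(50 / 9) - (50 / 9) * 0.2 + log(10 / 9) - (10 / 9) * 0.8,
               tolerance = 1e-12)

  # exact profile rates solve the stationarity equations in closed form here:
  # lambda_spec = 0.625, lambda_coal = 2.1875
  pl <- profile_lambdas(iv, 1, 1)
  expect_equal(pl$lambda_spec, 0.625, tolerance = 1e-8)
  expect_equal(pl$lambda_coal, 2.1875, tolerance = 1e-8)
  expect_equal(pl$logLik, mixed_loglik(iv, 0.625, 1, 2.1875, 1),
               tolerance = 1e-10)

  # zero rate with stem-only intervals present invalidates the model
  expect_equal(mixed_loglik(iv, 0, 1, 2.5, 1), -Inf)
})

test_that("profile rates are stationary points of the likelihood", {
  set.seed(41)
  for (i in 1:25) {
    tr <- random_tree(sample(5:30, 1))
    d <- random_delim(tr)
    iv <- compute_intervals(tr, d)
    if (iv$n_spec_events == 0L || iv$n_coal_events == 0L) next
    ps <- stats::runif(1, 0.4, 2); pc <- stats::runif(1, 0.4, 2)
    pl <- profile_lambdas(iv, ps, pc)
    if (pl$lambda_spec == 0 || pl$lambda_coal == 0) next  # boundary optimum
    eps <- 1e-6
    g1 <- (mixed_loglik(iv, pl$lambda_spec * (1 + eps), ps, pl$lambda_coal, pc) -
           mixed_loglik(iv, pl$lambda_spec * (1 - eps), ps, pl$lambda_coal, pc)) /
      (2 * eps * pl$lambda_spec)
    g2 <- (mixed_loglik(iv, pl$lambda_spec, ps, pl$lambda_coal * (1 + eps), pc) -
           mixed_loglik(iv, pl$lambda_spec, ps, pl$lambda_coal * (1 - eps), pc)) /
      (2 * eps * pl$lambda_coal)
    expect_lt(abs(g1), 1e-4)
    expect_lt(abs(g2), 1e-4)
  }
})

test_that("single-cluster and all-singleton models reduce correctly", {
  tr <- worked_tree()
  # single cluster at the root: likelihood-equivalent to the null, AIC + 4
  f_root <- fit_delimitation(tr, delimitation(tr, mrca = 4L))
  f_null <- fit_null(tr)
  expect_equal(f_root$logLik, f_null$logLik, tolerance = 1e-8)
  expect_equal(f_root$aic, f_null$aic + 4, tolerance = 1e-6)
  expect_equal(f_root$n_params, 4L)
  expect_equal(f_null$n_params, 2L)

  # all-singleton model on a 2-tip tree: one pure-Yule event,
  # lnL = ln(2^p lambda) - 2^p lambda x maximized at 2^p lambda = 1/x
  tr2 <- read_newick("(a:0.7,b:0.7);")
  iv2 <- compute_intervals(tr2, delimitation(tr2, singletons = 1:2))
  expect_equal(mixed_loglik(iv2, 1 / 1.4, 1, 0, 1),
               log(1 / 0.7) - 1, tolerance = 1e-10)
  expect_equal(iv2$n_spec_events, 1L)
  expect_equal(iv2$n_coal_events, 0L)

  # fits report estimability through the rates
  f_sing <- fit_delimitation(tr, delimitation(tr, singletons = 1:3))
  expect_equal(f_sing$lambda_coal, 0)
  expect_equal(f_sing$p_coal, 1)
})

test_that("aic bookkeeping follows the definition", {
  tr <- worked_tree()
  f <- fit_delimitation(tr, delimitation(tr, mrca = 5L, singletons = 3L))
  expect_equal(f$aic, 2 * f$n_params - 2 * f$logLik)
  expect_equal(f$k, 2L)
})
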