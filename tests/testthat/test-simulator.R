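test_that("single-population coalescent matches closed-form moments", {
  # E[Tmrca] = 4 Ne (1 - 1/n) under the diploid convention
  set.seed(71)
  ages <- replicate(1500, root_age(simulate_null_tree(5, Ne = 1e4)))
  se <- stats::sd(ages) / sqrt(length(ages))
  expect_lt(abs(mean(ages) - 32000), 3 * se)
  # n = 2 on the standard coalescent scale: Exp(1) root age
  ages2 <- replicate(1500, root_age(simulate_null_tree(2)))
  expect_lt(abs(mean(ages2) - 1), 3 * stats::sd(ages2) / sqrt(1500))
  tr <- simulate_null_tree(150, seed = 1)
  expect_equal(tr$Nnode, 149L)
  expect_s3_class(tr, "gmyc_tree")
})

test_that("two-species divergence adds the ancestral coalescent time", {
  st <- assign_population_sizes(read_newick("(sp1:50000,sp2:50000);"),
                                "fixed", 1e4)
  set.seed(72)
  div <- replicate(1500,
    root_age(simulate_gene_tree(st, c(sp1 = 1, sp2 = 1))$gene_tree))
  # tau + Exp(mean 2 Ne) above the split
  expect_lt(abs(mean(div) - 70000), 3 * stats::sd(div) / sqrt(1500))
  expect_gt(min(div), 50000)
})

test_that("species-tree simulators produce calibrated shapes", {
  st <- simulate_yule_species_tree(30, seed = 3)
  expect_equal(root_age(st), 1e7)
  expect_equal(length(st$tip.label), 30L)
  st2 <- simulate_yule_species_tree(2, seed = 4)
  expect_equal(root_age(st2), 1e7)
  # incomplete sampling slows apparent diversification (gamma < 0)
  set.seed(73)
  g <- replicate(60, gamma_statistic(
    subsample_species(simulate_yule_species_tree(50), 30)))
  expect_lt(mean(g), -2 * stats::sd(g) / sqrt(60))
  # extinction pulls branching toward the present (gamma above Yule)
  set.seed(74)
  gy <- replicate(60, gamma_statistic(simulate_yule_species_tree(30)))
  gb <- replicate(60, gamma_statistic(simulate_bd_species_tree(30, 0.3)))
  expect_gt(mean(gb), mean(gy))
  # pruning preserves validity and ages
  st3 <- subsample_species(st, 10, seed = 5)
  expect_s3_class(st3, "gmyc_tree")
  expect_lte(root_age(st3), 1e7 + 1e-6)
  expect_error(subsample_species(st, 1), "n_keep")
})

test_that("population size assignment is mean-calibrated and inherited", {
  st <- simulate_yule_species_tree(20, seed = 6)
  stf <- assign_population_sizes(st, "fixed", 1e5)
  expect_true(all(attr(stf, "Ne") == 1e5))
  set.seed(75)
  draws <- replicate(300, attr(assign_population_sizes(
    st, "lognormal", 1e4, sigma_log = 1), "Ne")[1:20])
  expect_lt(abs(mean(draws) - 1e4), 3 * stats::sd(draws) / sqrt(length(draws)))
  # sigma 0 degenerates to fixed
  st0 <- assign_population_sizes(st, "lognormal", 1e4, sigma_log = 0)
  expect_true(all(attr(st0, "Ne") == 1e4))
  # ancestors inherit from the lowest-indexed descendant tip
  Ne <- attr(assign_population_sizes(st, "lognormal", 1e4, seed = 8), "Ne")
  tu <- tips_under(st)
  for (v in 21:39) expect_equal(Ne[v], Ne[min(tu[[v]])])
})

test_that("growth and decline demographies satisfy the harmonic-mean constraint", {
  st <- assign_population_sizes(simulate_yule_species_tree(10, seed = 9),
                                "fixed", 1e5)
  for (sc in c("D1", "D2")) {
    std <- assign_demography(st, sc)
    Tb <- attr(std, "Tb")
    ages <- sort(node_ages(std)[12:19])
    expect_equal(Tb, ages[2] / 2)  # half the second most recent split
    s <- attr(std, "demography")[[1]][[1]]
    hm <- Tb / stats::integrate(function(t) 1 / (s$N0 * exp(s$r * (t - s$t0))),
                                0, Tb, rel.tol = 1e-10)$value
    expect_equal(hm, 1e5, tolerance = 1e-6)
    # 10-fold change across the growth/decline phase
    N_at_Tb <- s$N0 * exp(s$r * (Tb - s$t0))
    expect_equal(N_at_Tb / s$N0, if (sc == "D1") 1 / 10 else 10,
                 tolerance = 1e-9)
  }
  expect_equal(attr(assign_demography(st, "D1"), "demography")[[1]][[1]]$N0,
               9e5 / log(10), tolerance = 1e-9)
})

test_that("sampling schemes distribute gene copies as specified", {
  st <- assign_population_sizes(simulate_yule_species_tree(30, seed = 10),
                                "fixed", 1e4)
  per <- draw_sample_map(st, "per_species", 5)
  expect_true(all(per == 5L))
  expect_equal(sum(per), 150L)
  set.seed(76)
  uni <- draw_sample_map(st, "uniform_total", 150)
  expect_equal(sum(uni), 150L)
  # percentage of species sampled exactly once ~ binomial closed form (3.2%)
  set.seed(77)
  ones <- replicate(300, mean(draw_sample_map(st, "uniform_total", 150) == 1L))
  closed <- stats::dbinom(1, 150, 1 / 30)
  expect_lt(abs(mean(ones) - closed), 3 * stats::sd(ones) / sqrt(300))
})

test_that("gene trees within species trees respect the truth map", {
  st <- assign_population_sizes(simulate_yule_species_tree(10, seed = 12),
                                "fixed", 1e4)
  sim <- simulate_gene_tree(st, stats::setNames(rep(3L, 10), st$tip.label),
                            seed = 13)
  gt <- sim$gene_tree
  expect_s3_class(gt, "gmyc_tree")
  expect_equal(length(gt$tip.label), 30L)
  expect_setequal(names(sim$truth), gt$tip.label)
  expect_equal(sort(unique(unname(sim$truth))), sort(st$tip.label))
  # at low Ne relative to splits, most species come out monophyletic
  set.seed(14)
  mono <- replicate(10, {
    s <- simulate_gene_tree(st, stats::setNames(rep(3L, 10), st$tip.label))
    mean(vapply(st$tip.label, function(sp) {
      tips <- match(names(s$truth)[s$truth == sp], s$gene_tree$tip.label)
      ape::is.monophyletic(s$gene_tree, tips)
    }, TRUE))
  })
  expect_gt(mean(mono), 0.7)
})

test_that("scenarios compose reproducibly and reject out-of-scope names", {
  r1 <- scenario("B", mean_Ne = 1e4, n_replicates = 2, seed = 15)
  r2 <- scenario("B", mean_Ne = 1e4, n_replicates = 2, seed = 15)
  expect_identical(write_newick(r1[[1]]$gene_tree),
                   write_newick(r2[[1]]$gene_tree))
  expect_identical(r1[[2]]$truth, r2[[2]]$truth)
  expect_equal(root_age(r1[[1]]$scaled_tree), 1)
  expect_equal(length(r1[[1]]$truth), 150L)
  expect_equal(length(unique(r1[[1]]$truth)), 30L)

  a <- scenario("A", n_replicates = 1, seed = 16)
  expect_equal(length(a[[1]]$truth), 150L)
  expect_null(a[[1]]$species_tree)

  c1 <- scenario("C1", mean_Ne = 1e4, n_replicates = 1, seed = 17)
  expect_equal(length(unique(c1[[1]]$truth)), 30L)

  f1 <- scenario("F1", mean_Ne = 1e4, n_replicates = 1, seed = 18)
  expect_equal(length(f1[[1]]$truth), 150L)
  expect_lte(length(unique(f1[[1]]$truth)), 30L)

  expect_error(scenario("G", n_replicates = 1, seed = 1), "out of scope")
  expect_error(scenario("H", n_replicates = 1, seed = 1), "out of scope")
})
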