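test_that("Newick reading validates ultrametric bifurcating trees", {
  tr <- read_newick("((a:1,b:1):1,c:2);")
  expect_s3_class(tr, "gmyc_tree")
  expect_equal(length(tr$tip.label), 3L)
  ages <- node_ages(tr)
  expect_equal(unname(ages[1:3]), c(0, 0, 0))
  expect_equal(root_age(tr), 2)
  expect_equal(sort(ages[4:5]), c(1, 2))

  expect_error(read_newick("((a:1,b:1):1,c:1.5);"), "not ultrametric")
  expect_error(read_newick("((a:0,b:0):2,c:2);"), "zero-length terminal")
  expect_error(read_newick("((a:0,b:0):2,c:2);"), "haplotypes")
  expect_error(read_newick("((a:1,b:1,c:1):1,d:2);"), "bifurcating")
  expect_warning(read_newick("((a:1,b:1)x:1,c:2);"), "node labels")
})

test_that("Newick round trip preserves topology and ages", {
  set.seed(11)
  for (n in c(4, 9, 25)) {
    tr <- random_tree(n)
    tr2 <- read_newick(write_newick(tr))
    expect_equal(sort(tr2$tip.label), sort(tr$tip.label))
    d1 <- ape::cophenetic.phylo(tr)
    d2 <- ape::cophenetic.phylo(tr2)[rownames(d1), colnames(d1)]
    expect_equal(d2, d1, tolerance = 1e-9)
  }
})

test_that("rescaling the root age scales all ages linearly", {
  tr <- read_newick("((a:1,b:1):1,c:2);")
  tr2 <- rescale_root_age(tr, 1)
  expect_equal(root_age(tr2), 1)
  expect_equal(sort(node_ages(tr2)[4:5]), c(0.5, 1))
  expect_equal(node_ages(rescale_root_age(tr, 2)), node_ages(tr))
  big <- rescale_root_age(tr, 1e7)
  expect_equal(root_age(big), 1e7)
  expect_error(rescale_root_age(tr, -1))
})

test_that("gamma statistic matches the interval formula and ape", {
  # g2 = g3 = 1: hand evaluation of the Pybus-Harvey formula
  expect_equal(gamma_statistic(read_newick("((a:1,b:1):1,c:2);")),
               -0.3464102, tolerance = 1e-6)
  set.seed(5)
  for (i in 1:20) {
    tr <- random_tree(sample(3:40, 1))
    expect_equal(gamma_statistic(tr), ape::gammaStat(tr), tolerance = 1e-9)
    # scale invariance
    expect_equal(gamma_statistic(rescale_root_age(tr, 10)),
                 gamma_statistic(tr), tolerance = 1e-9)
  }
  expect_error(gamma_statistic(read_newick("(a:1,b:1);")), "3 tips")
})

test_that("Colless index counts subtree imbalance", {
  expect_identical(colless_index(balanced4()), 0L)
  expect_identical(colless_index(caterpillar4()), 3L)
  expect_identical(colless_index(read_newick("(a:1,b:1);")), 0L)
  # invariant to branch lengths and bounded by the caterpillar value
  set.seed(6)
  for (i in 1:10) {
    n <- sample(4:20, 1)
    tr <- random_tree(n)
    expect_lte(colless_index(tr), (n - 1) * (n - 2) / 2)
    expect_identical(colless_index(rescale_root_age(tr, 5)), colless_index(tr))
  }
})

test_that("shape metrics summarize species and gene trees together", {
  st <- read_newick("((sp1:1,sp2:1):1,sp3:2);")
  gt <- read_newick(paste0("(((sp1_1:0.1,sp1_2:0.1):0.9,",
                           "(sp2_1:0.2,sp2_2:0.2):0.8):1,sp3_1:2);"))
  truth <- c(sp1_1 = "sp1", sp1_2 = "sp1", sp2_1 = "sp2", sp2_2 = "sp2",
             sp3_1 = "sp3")
  sm <- shape_metrics(gt, st, truth)
  expect_equal(sm$mean_branching_time, 1.5)
  expect_equal(sm$mean_species_tmrca, 0.15)  # mean of 0.1 and 0.2
  expect_true(sm$tmrca_defined)
  expect_equal(sm$colless, colless_index(st))

  # all species sampled once: no within-species pairs
  gt1 <- read_newick("((sp1_1:1,sp2_1:1):1,sp3_1:2);")
  truth1 <- c(sp1_1 = "sp1", sp2_1 = "sp2", sp3_1 = "sp3")
  sm1 <- shape_metrics(gt1, st, truth1)
  expect_false(sm1$tmrca_defined)
  expect_equal(sm1$mean_species_tmrca, 0)
  expect_error(shape_metrics(gt, st, truth[-1]), "assignment")
})
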