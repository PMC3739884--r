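test_that("delimitations partition tips and reject overlaps", {
  tr <- worked_tree()
  d <- delimitation(tr, mrca = 5L, singletons = 3L)  # cherry + c
  expect_equal(d$k, 2L)
  expect_equal(d$species_of, c(1L, 1L, 2L))
  expect_error(delimitation(tr, mrca = c(4L, 5L)), "overlap")
  expect_error(delimitation(tr, mrca = 5L), "no species")
  expect_error(delimitation(tr, mrca = 2L), "internal")
  # single-cluster model at the root
  expect_equal(delimitation(tr, mrca = 4L)$k, 1L)
})

test_that("branch classification separates stems from within-cluster branches", {
  tr <- worked_tree()
  d <- delimitation(tr, mrca = 5L, singletons = 3L)
  cls <- classify_branches(tr, d)
  child <- tr$edge[, 2]
  expect_equal(unname(cls[child == 1L]), "coalescent:1")  # a
  expect_equal(unname(cls[child == 2L]), "coalescent:1")  # b
  expect_equal(unname(cls[child == 3L]), "speciation")    # c (singleton stem)
  expect_equal(unname(cls[child == 5L]), "speciation")    # cherry stem

  # single cluster: every branch is coalescent
  cls1 <- classify_branches(tr, delimitation(tr, mrca = 4L))
  expect_true(all(grepl("coalescent", cls1)))
  # all singletons: every branch is a diversification branch
  cls2 <- classify_branches(tr, delimitation(tr, singletons = 1:3))
  expect_true(all(cls2 == "speciation"))
  expect_equal(length(cls2), 2L * 3L - 2L)
})

test_that("threshold delimitations follow the age cut-off", {
  tr <- worked_tree()
  d1 <- threshold_delimitation(tr, 1.0)   # only the root is a speciation node
  expect_equal(sort(d1$mrca), 5L)
  expect_equal(d1$singletons, 3L)
  d2 <- threshold_delimitation(tr, 0.2)   # every node is a speciation node
  expect_equal(d2$mrca, integer(0))
  expect_equal(sort(d2$singletons), 1:3)
})

test_that("interval tables carry the per-process lineage counts", {
  tr <- worked_tree()
  iv <- compute_intervals(tr, delimitation(tr, mrca = 5L, singletons = 3L))
  expect_equal(iv$x, c(0.2, 0.8))
  expect_equal(sum(iv$x), root_age(tr))
  expect_equal(iv$n_spec, c(1L, 2L))       # c's stem, then both stems
  expect_equal(iv$ev_class, c(2L, 1L))     # coalescent then speciation
  expect_equal(iv$ev_val, c(2, 2))         # n(n-1) = 2*1; n_spec = 2
  expect_equal(iv$cc, 2)                   # one cluster with 2 lineages
  expect_equal(iv$ci, 1L)

  # null counts: 3 then 2 lineages, all coalescent
  iv0 <- compute_intervals(tr, NULL)
  expect_equal(iv0$n_spec, c(0L, 0L))
  expect_equal(iv0$ev_class, c(2L, 2L))
  expect_equal(iv0$cc, c(6, 2))
  expect_equal(iv0$n_coal_events, 2L)
})

test_that("interval waiting times always sum to the root age", {
  set.seed(21)
  for (i in 1:15) {
    tr <- random_tree(sample(4:25, 1))
    d <- random_delim(tr)
    iv <- compute_intervals(tr, d)
    expect_equal(sum(iv$x), root_age(tr), tolerance = 1e-9)
    expect_equal(length(iv$x), length(tr$tip.label) - 1L)
    # lineage conservation: stems + cluster lineages = branches crossing
    ages <- node_ages(tr)
    mids <- cumsum(iv$x) - iv$x / 2
    crossing <- vapply(mids, function(t)
      sum(ages[tr$edge[, 2]] < t & ages[tr$edge[, 1]] > t), 0L)
    counted <- vapply(seq_along(iv$x), function(i)
      iv$n_spec[i] +
        sum(round((1 + sqrt(1 + 4 * iv$cc[iv$ci == i])) / 2)), 0)
    expect_equal(counted, as.numeric(crossing))
  }
})

test_that("delimitation-model counts match exhaustive enumeration", {
  expect_equal(format(count_delimitation_models(read_newick("(a:1,b:1);"))), "2")
  expect_equal(format(count_delimitation_models(balanced4())), "5")
  expect_equal(format(count_delimitation_models(caterpillar4())), "4")
  set.seed(31)
  for (i in 1:10) {
    tr <- random_tree(sample(4:8, 1))
    expect_equal(as.numeric(count_delimitation_models(tr)),
                 length(enum_delims(tr)))
  }
  # balanced 128-tip tree: doubly-exponential growth needs big integers
  bal <- as_gmyc_tree(ape::compute.brlen(ape::stree(128, "balanced")))
  expect_equal(format(count_delimitation_models(bal)),
               "44127887745906175987802")
})
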