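# Shared fixtures and independent oracles used across the test files.

# the worked 3-tip example used throughout: cherry (a,b) at age 0.2, root 1.0
worked_tree <- function() read_newick("((a:0.2,b:0.2):0.8,c:1.0);")

balanced4 <- function() read_newick("((a:1,b:1):1,(c:1,d:1):1);")
caterpillar4 <- function() read_newick("(((a:1,b:1):1,c:2):1,d:3);")

# random small ultrametric tree (coalescent shape)
random_tree <- function(n) as_gmyc_tree(ape::rcoal(n))

# brute-force enumeration of ALL monophyletic delimitations of a tree,
# independent of the package recursion: returns a list of
# list(mrca=, singletons=)
enum_delims <- function(tree) {
  m <- length(tree$tip.label)
  kids <- function(v) tree$edge[, 2][tree$edge[, 1] == v]
  rec <- function(v) {
    if (v <= m)
      return(list(list(mrca = integer(0), singletons = v)))
    out <- list(list(mrca = v, singletons = integer(0)))
    ch <- kids(v)
    for (dl in rec(ch[1])) for (dr in rec(ch[2]))
      out[[length(out) + 1L]] <- list(
        mrca = c(dl$mrca, dr$mrca),
        singletons = c(dl$singletons, dr$singletons))
    out
  }
  rec(m + 1L)
}

# exhaustive maximum likelihood over every delimitation (oracle for the
# threshold scan and the heuristic search on small trees)
exhaustive_best_loglik <- function(tree) {
  best <- -Inf
  for (d in enum_delims(tree)) {
    fit <- fit_delimitation(tree, delimitation(tree, d$mrca, d$singletons))
    if (is.finite(fit$logLik) && fit$logLik > best) best <- fit$logLik
  }
  best
}

# full 4-parameter numeric maximization of mixed_loglik (independent of the
# profile machinery); started both from neutral values and from `from`
numeric_ml_loglik <- function(iv, from = NULL) {
  negf <- function(th) {
    v <- -mixed_loglik(iv, exp(th[1]), exp(th[2]), exp(th[3]), exp(th[4]))
    if (!is.finite(v)) 1e10 else v
  }
  starts <- list(c(0, 0, 0, 0))
  if (!is.null(from)) starts <- c(starts, list(from))
  best <- Inf
  for (s in starts) {
    o <- stats::optim(s, negf, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 20000L))
    o <- stats::optim(o$par, negf, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 20000L))
    if (o$value < best) best <- o$value
  }
  -best
}

# random monophyletic delimitation: from the root, each internal node is a
# diversification node with probability `p_split`, otherwise a cluster MRCA
random_delim <- function(tree, p_split = 0.6) {
  m <- length(tree$tip.label)
  kids <- function(v) tree$edge[, 2][tree$edge[, 1] == v]
  mrca <- integer(0); singles <- integer(0)
  walk <- function(v, force_split = FALSE) {
    if (v <= m) {
      singles <<- c(singles, v)
    } else if (force_split || stats::runif(1) < p_split) {
      for (ch in kids(v)) walk(ch)
    } else {
      mrca <<- c(mrca, v)
    }
  }
  walk(m + 1L, force_split = TRUE)  # keep at least two units
  delimitation(tree, mrca = mrca, singletons = singles)
}
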