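#' Construct a species delimitation
#'
#' A delimitation is a candidate model of species limits on a gene tree: a set
#' of internal MRCA nodes, each defining a multi-tip species cluster, plus a
#' set of singleton tips that are species of their own. Together the cluster
#' tip sets and singletons must partition the tips exactly, which also forces
#' every delimited species to be monophyletic.
#'
#' @param tree a `gmyc_tree`.
#' @param mrca integer vector of internal node ids (ape numbering,
#'   `M+1..2M-1`) defining multi-tip clusters.
#' @param singletons integer vector of tip ids (`1..M`) that are species of
#'   their own.
#' @return an object of class `gmyc_delimitation` with elements `mrca`,
#'   `singletons`, `k` (number of species) and `species_of` (integer species
#'   index for every tip).
#' @export
delimitation <- function(tree, mrca = integer(), singletons = integer()) {
  tree <- as_gmyc_tree(tree)
  m <- n_tips(tree)
  mrca <- sort(unique(as.integer(mrca)))
  singletons <- sort(unique(as.integer(singletons)))
  if (length(mrca) && (any(mrca <= m) || any(mrca > 2L * m - 1L)))
    stop("'mrca' must contain internal node ids")
  if (length(singletons) && (any(singletons < 1L) || any(singletons > m)))
    stop("'singletons' must contain tip ids")

  tu <- tips_under(tree)
  species_of <- integer(m)
  k <- 0L
  for (v in mrca) {
    k <- k + 1L
    tt <- tu[[v]]
    if (any(species_of[tt] != 0L))
      stop("invalid delimitation: clusters/singletons overlap")
    species_of[tt] <- k
  }
  for (t in singletons) {
    k <- k + 1L
    if (species_of[t] != 0L)
      stop("invalid delimitation: clusters/singletons overlap")
    species_of[t] <- k
  }
  if (any(species_of == 0L))
    stop("invalid delimitation: some tips belong to no species")
  structure(
    list(mrca = mrca, singletons = singletons, k = k, species_of = species_of),
    class = "gmyc_delimitation")
}

#' @export
print.gmyc_delimitation <- function(x, ...) {
  cat(sprintf("Delimitation: %d species (%d clusters, %d singletons)\n",
              x$k, length(x$mrca), length(x$singletons)))
  invisible(x)
}

# canonical key for deduplicating identical delimitations
delim_key <- function(delim) {
  paste(paste(delim$mrca, collapse = ","),
        paste(delim$singletons, collapse = ","), sep = "|")
}

#' Delimitation induced by a threshold time
#'
#' Under the single-threshold model every node at least as old as the
#' threshold `T` is a diversification event and every younger node a
#' within-species coalescence. Clusters are the maximal clades whose MRCA is
#' younger than `T`; tips whose parent node is a diversification node become
#' singletons.
#'
#' @param tree a `gmyc_tree`.
#' @param threshold positive threshold age, at most the root age.
#' @return a `gmyc_delimitation`.
#' @export
threshold_delimitation <- function(tree, threshold) {
  tree <- as_gmyc_tree(tree)
  m <- n_tips(tree)
  ages <- node_ages(tree)
  eps <- 1e-12 * root_age(tree)
  is_spec <- ages >= threshold - eps
  is_spec[seq_len(m)] <- FALSE
  par <- parents_of(tree)
  internal <- (m + 1L):(2L * m - 1L)
  root <- m + 1L
  par_spec <- c(FALSE, is_spec)[par[internal] + 1L]  # root's parent counts as spec
  mrca <- internal[!is_spec[internal] & (internal == root | par_spec)]
  singles <- which(is_spec[par[seq_len(m)]])
  delimitation(tree, mrca = mrca, singletons = singles)
}

#' Classify branches as diversification or within-species coalescent
#'
#' Every branch strictly inside a cluster (tipward of its MRCA) belongs to
#' that species' coalescent process; the stem branch of each cluster or
#' singleton and every deeper branch belongs to the diversification
#' (speciation) process.
#'
#' @param tree a `gmyc_tree`.
#' @param delim a `gmyc_delimitation`.
#' @return a character vector over edges of `tree$edge`: `"speciation"` or
#'   `"coalescent:<species index>"`.
#' @export
classify_branches <- function(tree, delim) {
  tree <- as_gmyc_tree(tree)
  proc <- node_process(tree, delim)  # per-node species index, 0 = speciation
  child <- tree$edge[, 2]
  cls <- rep("speciation", nrow(tree$edge))
  # an edge is coalescent iff its *parent* node lies inside (or at) a cluster
  par_proc <- proc[tree$edge[, 1]]
  coal <- par_proc > 0L
  cls[coal] <- paste0("coalescent:", par_proc[coal])
  cls
}

# species (cluster) index per node: j if the node is the MRCA of cluster j or
# a descendant of it, 0 otherwise (diversification part of the tree; singleton
# tips are stems, hence 0). Clusters are indexed in the sorted order used by
# delimitation(), matching species_of for cluster tips.
node_process <- function(tree, delim) {
  m <- n_tips(tree)
  proc <- integer(2L * m - 1L)
  proc[seq_len(m)] <- delim$species_of
  proc[delim$singletons] <- 0L
  for (j in seq_along(delim$mrca)) {
    v <- delim$mrca[j]
    proc[v] <- j
    proc[internal_descendants(tree, v)] <- j
  }
  proc
}

internal_descendants <- function(tree, v) {
  m <- n_tips(tree)
  children <- children_of(tree)
  out <- integer(0)
  stack <- children[[v]]
  while (length(stack)) {
    k <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (k > m) {
      out <- c(out, k)
      stack <- c(stack, children[[k]])
    }
  }
  out
}

#' Waiting-interval table for a delimitation
#'
#' The sufficient statistic for all GMYC likelihoods: the ordered waiting
#' times `x_i` between successive branching events anywhere in the tree,
#' together with the number of lineages each branching process contributes
#' during each interval, and the class (diversification or within-species
#' coalescent) of the event terminating each interval.
#'
#' @param tree a `gmyc_tree`.
#' @param delim a `gmyc_delimitation`; `NULL` means the null model (the whole
#'   tree as a single population).
#' @return an object of class `gmyc_intervals`; see Details in the package
#'   vignette. The element `x` sums to the root age and has one entry per
#'   internal node.
#' @export
compute_intervals <- function(tree, delim = NULL) {
  tree <- as_gmyc_tree(tree)
  m <- n_tips(tree)
  if (is.null(delim)) delim <- delimitation(tree, mrca = m + 1L)
  ages <- node_ages(tree)
  internal <- (m + 1L):(2L * m - 1L)
  ord <- internal[order(ages[internal], internal)]

  proc <- node_process(tree, delim)
  n_clusters <- length(delim$mrca)
  # lineage counts at the present: per-cluster sampled copies, singleton stems
  ncoal <- tabulate(delim$species_of[setdiff(seq_len(m), delim$singletons)],
                    nbins = n_clusters)
  nspec <- length(delim$singletons)

  ne <- m - 1L
  x <- diff(c(0, ages[ord]))
  sweep <- intervals_sweep_cpp(proc[ord], x, ncoal, nspec)
  nspec_i <- sweep$nspec_i
  ev_class <- sweep$ev_class
  ev_val <- sweep$ev_val
  cc <- sweep$cc
  ci <- sweep$ci
  prev <- ages[ord[ne]]

  # fast-path views over positive-length intervals (zero-length intervals,
  # i.e. tied node ages, contribute nothing and are excluded consistently
  # from both the density and the event counts)
  pos <- x > 0
  posmap <- cumsum(pos)            # old interval index -> position in xp
  xp <- x[pos]
  ap <- nspec_i[pos]
  ia_pos <- which(ap > 0L)
  cc_keep <- pos[ci]
  ccv <- cc[cc_keep]
  cip <- posmap[ci[cc_keep]]
  spec_ev <- pos & ev_class == 1L
  coal_ev <- pos & ev_class == 2L

  structure(list(
    x = x, n_spec = nspec_i, ev_class = ev_class, ev_val = ev_val,
    cc = cc, ci = ci, root_age = prev, m = m,
    n_spec_events = sum(spec_ev), n_coal_events = sum(coal_ev),
    xp = xp, ia_pos = ia_pos, log_ap = log(ap[ia_pos]),
    ccv = ccv, log_ccv = log(ccv), cip = cip
  ), class = "gmyc_intervals")
}

#' @export
print.gmyc_intervals <- function(x, ...) {
  cat(sprintf(
    "Waiting-interval table: %d intervals (%d speciation, %d coalescent events), root age %.6g\n",
    length(x$x), x$n_spec_events, x$n_coal_events, x$root_age))
  invisible(x)
}

#' Count all monophyletic delimitation models of a tree
#'
#' The number of distinct sets of MRCA nodes / singleton tips that partition
#' the tips into monophyletic groups, by the recursion `f(tip) = 1`,
#' `f(v) = 1 + f(left) f(right)` (the `1` is the whole subtree as one
#' cluster). The count grows doubly exponentially, so exact arithmetic is
#' carried in an arbitrary-precision integer.
#'
#' @param tree a `gmyc_tree`.
#' @return a `gmyc_bigint`; use `format()` for the exact decimal string or
#'   `as.numeric()` for a double approximation.
#' @export
count_delimitation_models <- function(tree) {
  tree <- as_gmyc_tree(tree)
  m <- n_tips(tree)
  po <- ape::reorder.phylo(tree, "postorder")
  f <- vector("list", 2L * m - 1L)
  for (i in seq_len(m)) f[[i]] <- big_from_int(1L)
  # children arrive in postorder pairs
  for (e in seq(1L, nrow(po$edge), by = 2L)) {
    p <- po$edge[e, 1]
    c1 <- po$edge[e, 2]; c2 <- po$edge[e + 1L, 2]
    f[[p]] <- big_add(big_from_int(1L), big_mul(f[[c1]], f[[c2]]))
  }
  f[[m + 1L]]
}
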