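#' Validate an ultrametric gene tree
#'
#' Checks that a `phylo` object is a rooted, strictly bifurcating ultrametric
#' tree with no zero-length branches, and attaches node ages (time measured
#' backward from the tips, which sit at age 0). All downstream delimitation
#' and simulation code works on trees validated by this constructor.
#'
#' Ultrametricity is judged relative to the root age: the spread of tip depths
#' must not exceed `tol * root_age`. Trees failing validation are rejected
#' rather than silently corrected, because any correction would perturb the
#' waiting intervals that carry all of the model's information.
#'
#' @param phy a `phylo` object with branch lengths.
#' @param tol relative ultrametricity tolerance (fraction of the root age).
#' @return the tree with class `c("gmyc_tree", "phylo")` and an `ages`
#'   attribute: a numeric vector over node ids (tips `1..M`, internal nodes
#'   `M+1..2M-1`) giving each node's age.
#' @export
as_gmyc_tree <- function(phy, tol = 1e-6) {
  if (inherits(phy, "gmyc_tree")) return(phy)
  if (!inherits(phy, "phylo")) stop("'phy' must be a \"phylo\" object")
  if (is.null(phy$edge.length)) stop("tree has no branch lengths")
  if (!ape::is.rooted(phy)) stop("tree must be rooted")
  m <- length(phy$tip.label)
  if (m < 2L) stop("tree must have at least 2 tips")
  if (anyDuplicated(phy$tip.label)) stop("tip labels must be unique")
  if (phy$Nnode != m - 1L || !ape::is.binary(phy))
    stop("tree must be strictly bifurcating (no polytomies, no root of degree 2)")
  if (!is.null(phy$root.edge)) phy$root.edge <- NULL

  depth <- ape::node.depth.edgelength(phy)  # distance from the root
  root_age <- max(depth[seq_len(m)])
  if (root_age <= 0) stop("tree has zero total depth")
  abs_tol <- tol * root_age
  spread <- root_age - min(depth[seq_len(m)])
  if (spread > abs_tol)
    stop(sprintf(
      "tree is not ultrametric: tip depths differ by %.3g (tolerance %.3g)",
      spread, abs_tol))

  tip_edge <- phy$edge[, 2] <= m
  short <- tip_edge & phy$edge.length <= 0
  if (any(short)) {
    bad <- phy$tip.label[phy$edge[short, 2]]
    stop(sprintf(
      paste0("zero-length terminal branch at tip(s) %s; identical haplotypes ",
             "should be pruned to a single copy before analysis"),
      paste(sQuote(bad), collapse = ", ")))
  }
  if (any(!tip_edge & phy$edge.length <= 0))
    stop("tree has a non-positive internal branch length")

  ages <- root_age - depth
  ages[seq_len(m)] <- 0
  attr(phy, "ages") <- ages
  # cache the traversal structures used throughout delimitation handling
  nn <- 2L * m - 1L
  children <- vector("list", nn)
  par <- integer(nn)
  for (e in seq_len(nrow(phy$edge))) {
    p <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
    children[[p]] <- c(children[[p]], ch)
    par[ch] <- p
  }
  tu <- vector("list", nn)
  for (i in seq_len(m)) tu[[i]] <- i
  po <- ape::reorder.phylo(phy, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]; ch <- po$edge[e, 2]
    tu[[p]] <- c(tu[[p]], tu[[ch]])
  }
  attr(phy, "children") <- children
  attr(phy, "parents") <- par
  attr(phy, "tips_under") <- tu
  class(phy) <- c("gmyc_tree", "phylo")
  phy
}

#' Read an ultrametric tree from Newick
#'
#' Accepts either a file path or a literal Newick string. Branch lengths are
#' mandatory; internal node labels are dropped with a warning; a trailing
#' root edge length is ignored. The tree is validated with [as_gmyc_tree()].
#'
#' @param x Newick text (contains `(` or `;`) or a path to a Newick file.
#' @inheritParams as_gmyc_tree
#' @return a `gmyc_tree`.
#' @export
read_newick <- function(x, tol = 1e-6) {
  stopifnot(is.character(x), length(x) == 1L)
  phy <- if (grepl("[(;]", x)) ape::read.tree(text = x) else ape::read.tree(file = x)
  if (is.null(phy)) stop("failed to parse Newick input")
  if (!is.null(phy$node.label) && any(nzchar(phy$node.label))) {
    warning("internal node labels present in Newick input; ignored")
  }
  phy$node.label <- NULL
  as_gmyc_tree(phy, tol = tol)
}

#' Write a tree to Newick
#'
#' @param tree a `gmyc_tree` or `phylo`.
#' @param file optional path; if `NULL` the Newick string is returned.
#' @return the Newick string (invisibly when writing to a file).
#' @export
write_newick <- function(tree, file = NULL) {
  class(tree) <- "phylo"
  txt <- ape::write.tree(tree, digits = 12)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Node ages of a validated tree
#'
#' @param tree a `gmyc_tree`.
#' @return numeric vector of ages indexed by node id (tips first).
#' @export
node_ages <- function(tree) {
  ages <- attr(tree, "ages")
  if (is.null(ages)) ages <- attr(as_gmyc_tree(tree), "ages")
  ages
}

n_tips <- function(tree) length(tree$tip.label)

#' Root age of a validated tree
#'
#' @param tree a `gmyc_tree`.
#' @return the age of the root node (the tree height).
#' @export
root_age <- function(tree) max(node_ages(tree))

#' Rescale a tree to a target root age
#'
#' Multiplies all branch lengths (hence all node ages) by
#' `target / root_age`, leaving the topology untouched. Used to place
#' simulated trees on a common relative time scale before analysis.
#'
#' @param tree a `gmyc_tree`.
#' @param target positive root age after rescaling.
#' @return the rescaled `gmyc_tree`.
#' @export
rescale_root_age <- function(tree, target) {
  stopifnot(is.numeric(target), length(target) == 1L, target > 0)
  tree <- as_gmyc_tree(tree)
  f <- target / root_age(tree)
  tree$edge.length <- tree$edge.length * f
  attr(tree, "ages") <- attr(tree, "ages") * f
  tree
}

#' Pybus-Harvey gamma statistic
#'
#' Standardized departure of the internode intervals from the constant-rate
#' pure-birth expectation: negative values indicate branching concentrated
#' toward the root (an apparent slowdown), positive values an apparent
#' acceleration toward the tips. Invariant under rescaling of branch lengths.
#'
#' With `g_k` the interval during which `k` lineages exist and
#' `T = sum(k * g_k)`, the statistic is
#' `[(1/(n-2)) * sum_{i=2}^{n-1} sum_{k=2}^{i} k g_k - T/2] / (T sqrt(1/(12(n-2))))`.
#'
#' @param tree a `gmyc_tree` with at least 3 tips.
#' @return the (dimensionless) gamma statistic.
#' @export
gamma_statistic <- function(tree) {
  tree <- as_gmyc_tree(tree)
  n <- n_tips(tree)
  if (n < 3L) stop("gamma statistic requires at least 3 tips")
  ages <- sort(node_ages(tree)[(n + 1L):(2L * n - 1L)], decreasing = TRUE)
  # ages[j] is the age at which the number of lineages goes from j to j+1
  # (ages[1] = root age); g_k = ages[k-1] - ages[k], with ages[n] = 0.
  g <- c(ages, 0)
  g <- g[-length(g)] - g[-1L]            # g[k-1] is g_k, k = 2..n
  k <- 2:n
  kg <- k * g
  bigT <- sum(kg)
  cum <- cumsum(kg)                      # cum[i-1] = sum_{k=2}^{i} k g_k
  inner <- sum(cum[seq_len(n - 2L)]) / (n - 2L)
  (inner - bigT / 2) / (bigT * sqrt(1 / (12 * (n - 2L))))
}

#' Colless imbalance index
#'
#' Sum over internal nodes of the absolute difference between the numbers of
#' tips descending from the two children. Zero for a fully balanced topology;
#' at most `(n-1)(n-2)/2` (the caterpillar).
#'
#' @param tree a `gmyc_tree` with at least 2 tips.
#' @return a non-negative integer.
#' @export
colless_index <- function(tree) {
  tree <- as_gmyc_tree(tree)
  class(tree) <- "phylo"
  b <- ape::balance(tree)
  as.integer(sum(abs(b[, 1] - b[, 2])))
}

#' Tree-shape summary of a simulated replicate
#'
#' Collects the shape statistics used to summarize simulation output: the
#' gamma statistic and Colless index of the species tree, the mean branching
#' (speciation) time, and the mean age over species of the most recent common
#' ancestor of each species' sampled gene copies on the gene tree (a measure
#' of within-species variation). Species sampled fewer than twice carry no
#' within-species coalescence and are skipped; if no species has two or more
#' samples the mean Tmrca is reported as 0 with `tmrca_defined = FALSE`.
#'
#' @param gene_tree a `gmyc_tree` over sampled gene copies.
#' @param species_tree a `gmyc_tree` over species.
#' @param assignment named character vector mapping every gene-tree tip label
#'   to a species-tree tip label.
#' @return a list with `gamma`, `colless`, `mean_branching_time`,
#'   `mean_species_tmrca`, and `tmrca_defined`.
#' @export
shape_metrics <- function(gene_tree, species_tree, assignment) {
  gene_tree <- as_gmyc_tree(gene_tree)
  species_tree <- as_gmyc_tree(species_tree)
  tips <- gene_tree$tip.label
  if (!all(tips %in% names(assignment)))
    stop("every gene-tree tip needs a species assignment")
  sp <- assignment[tips]

  ns <- n_tips(species_tree)
  sp_ages <- node_ages(species_tree)[(ns + 1L):(2L * ns - 1L)]
  ages <- node_ages(gene_tree)

  tmrcas <- numeric(0)
  for (s in unique(sp)) {
    idx <- which(sp == s)
    if (length(idx) >= 2L) {
      anc <- ape::getMRCA(gene_tree, idx)
      tmrcas <- c(tmrcas, ages[anc])
    }
  }
  list(
    gamma = gamma_statistic(species_tree),
    colless = colless_index(species_tree),
    mean_branching_time = mean(sp_ages),
    mean_species_tmrca = if (length(tmrcas)) mean(tmrcas) else 0,
    tmrca_defined = length(tmrcas) > 0L
  )
}

#' @export
print.gmyc_tree <- function(x, ...) {
  cat(sprintf("Ultrametric gene tree: %d tips, root age %.6g\n",
              n_tips(x), root_age(x)))
  invisible(x)
}

# descendant tips of every node, as a list indexed by node id (cached on the
# validated tree)
tips_under <- function(tree) {
  tu <- attr(tree, "tips_under")
  if (!is.null(tu)) return(tu)
  attr(as_gmyc_tree(tree), "tips_under")
}

# parent of every node (0 for the root)
parents_of <- function(tree) {
  par <- attr(tree, "parents")
  if (!is.null(par)) return(par)
  m <- n_tips(tree)
  par <- integer(2L * m - 1L)
  par[tree$edge[, 2]] <- tree$edge[, 1]
  par
}

children_of <- function(tree) {
  ch <- attr(tree, "children")
  if (!is.null(ch)) return(ch)
  attr(as_gmyc_tree(tree), "children")
}
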