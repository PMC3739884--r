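# Species-tree and multispecies-coalescent gene-tree simulation.
#
# Conventions: time is measured in generations, backward from the present
# (age 0 at the tips). The coalescent uses the diploid convention: a pair of
# lineages in a population of effective size N coalesces at rate 1/(2N) per
# generation, so E[pairwise coalescence time] = 2N and
# E[Tmrca of n samples] = 4N(1 - 1/n) under constant N.
#
# Per-branch demography is a list of segments (t0, t1, N0, r): for absolute
# age t in [t0, t1), N(t) = N0 * exp(r * (t - t0)), with r the backward-time
# exponential rate (r < 0 means the population shrinks backward in time,
# i.e. grows forward in time).

seg <- function(t0, t1, N0, r = 0) list(t0 = t0, t1 = t1, N0 = N0, r = r)

constant_demography <- function(N) list(seg(0, Inf, N, 0))

# pairwise coalescent intensity accumulated over [t, t + w] inside one segment
seg_pair_intensity <- function(s, t, w) {
  if (w <= 0) return(0)
  if (s$r == 0) return(w / (2 * s$N0))
  (exp(-s$r * (t - s$t0)) - exp(-s$r * (t + w - s$t0))) / (2 * s$N0 * s$r)
}

# inverse: the w solving seg_pair_intensity(s, t, w) = eps (eps feasible)
seg_pair_invert <- function(s, t, eps) {
  if (s$r == 0) return(2 * s$N0 * eps)
  a <- exp(-s$r * (t - s$t0)) - 2 * s$N0 * s$r * eps
  -log(a) / s$r - (t - s$t0)
}

# simulate pairwise coalescence among `lins` (integer gene-lineage ids) from
# age t0 up to t1 under `segs`; `state` is an environment carrying the gene
# tree under construction (ages, children, next internal id)
sim_within_branch <- function(lins, t0, t1, segs, state) {
  t <- t0
  while (length(lins) >= 2L && t < t1) {
    k <- length(lins)
    npair <- k * (k - 1) / 2
    target <- stats::rexp(1L)            # required pairwise intensity * npair
    # walk segments to find the event age
    event_age <- NA_real_
    tt <- t
    remaining <- target / npair
    for (s in segs) {
      if (s$t1 <= tt) next
      if (s$t0 >= t1) break
      lo <- max(tt, s$t0); hi <- min(t1, s$t1)
      if (hi <= lo) next
      cap <- seg_pair_intensity(s, lo, hi - lo)
      if (remaining <= cap) {
        event_age <- lo + seg_pair_invert(s, lo, remaining)
        break
      }
      remaining <- remaining - cap
      tt <- hi
    }
    if (is.na(event_age) || event_age >= t1) break
    pair <- sample(seq_along(lins), 2L)
    v <- state$next_id
    state$next_id <- v + 1L
    state$age[v] <- event_age
    state$child1[v] <- lins[pair[1L]]
    state$child2[v] <- lins[pair[2L]]
    lins <- c(lins[-pair], v)
    t <- event_age
  }
  lins
}

# assemble the recorded coalescent events into a phylo object
build_gene_phylo <- function(state, tip_labels) {
  g <- length(tip_labels)
  n_int <- g - 1L
  ev <- seq(g + 1L, g + n_int)           # internal ids in creation order
  # renumber so the root (oldest event, created last) is g + 1
  ord <- order(state$age[ev], decreasing = TRUE)
  new_id <- integer(g + n_int)
  new_id[seq_len(g)] <- seq_len(g)
  new_id[ev[ord]] <- seq(g + 1L, g + n_int)
  edge <- matrix(0L, 2L * n_int, 2L)
  len <- numeric(2L * n_int)
  age_new <- numeric(g + n_int)
  age_new[new_id] <- state$age[seq_len(g + n_int)]
  r <- 0L
  for (v in ev) {
    for (ch in c(state$child1[v], state$child2[v])) {
      r <- r + 1L
      edge[r, ] <- c(new_id[v], new_id[ch])
      len[r] <- state$age[v] - state$age[ch]
    }
  }
  phy <- list(edge = edge, edge.length = len, tip.label = tip_labels,
              Nnode = n_int)
  class(phy) <- "phylo"
  attr(phy, "order") <- NULL
  as_gmyc_tree(phy)
}

#' Simulate a constant-rate (Yule) species tree
#'
#' Pure-birth tree conditioned on the number of extant species, rescaled so
#' that the root age is exactly `root_age` generations. With the default 30
#' species and 10^7 generations the implied net speciation rate is
#' `(log(30) - log(2)) / 1e7` per lineage per generation, a typical value for
#' recent radiations.
#'
#' @param n_species number of species (>= 2).
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @param root_age root age in generations after rescaling.
#' @return a `gmyc_tree` with tip labels `sp1..spN`.
#' @export
simulate_yule_species_tree <- function(n_species, seed = NULL, root_age = 1e7) {
  simulate_bd_species_tree(n_species, relative_extinction = 0, seed = seed,
                           root_age = root_age)
}

#' Simulate a birth-death species tree conditioned on extant species count
#'
#' Constant-rate birth-death process conditioned on `n_species` surviving
#' sampled species (the reconstructed tree of survivors), rescaled to a fixed
#' root age. Extinction pulls branching events toward the present ("pull of
#' the present"), so replicate gamma statistics are stochastically larger
#' than under the pure-birth model.
#'
#' @param n_species number of extant species (>= 2).
#' @param relative_extinction extinction rate as a fraction of the
#'   speciation rate, in `[0, 1)`.
#' @inheritParams simulate_yule_species_tree
#' @return a `gmyc_tree` with tip labels `sp1..spN`.
#' @export
simulate_bd_species_tree <- function(n_species, relative_extinction = 0,
                                     seed = NULL, root_age = 1e7) {
  stopifnot(n_species >= 2L,
            relative_extinction >= 0, relative_extinction < 1)
  if (!is.null(seed)) set.seed(seed)
  phy <- ape::rphylo(n_species, birth = 1, death = relative_extinction,
                     fossils = FALSE)
  phy$tip.label <- paste0("sp", seq_len(n_species))
  rescale_root_age(as_gmyc_tree(phy), root_age)
}

#' Randomly subsample species from a species tree
#'
#' Keeps a uniformly chosen subset of tips and prunes the rest, suppressing
#' the resulting degree-2 nodes. Node ages of retained splits are preserved
#' and the tree is deliberately NOT rescaled: sampling 30 of 50 species
#' leaves a deficit of recent speciation events relative to the (unchanged)
#' root age, which is the point of the incomplete-sampling scenario.
#'
#' @param tree a species `gmyc_tree`.
#' @param n_keep number of species to retain (>= 2).
#' @param seed integer seed, or `NULL`.
#' @return the pruned `gmyc_tree`.
#' @export
subsample_species <- function(tree, n_keep, seed = NULL) {
  tree <- as_gmyc_tree(tree)
  stopifnot(n_keep >= 2L, n_keep <= n_tips(tree))
  if (!is.null(seed)) set.seed(seed)
  keep <- sort(sample(n_tips(tree), n_keep))
  class(tree) <- "phylo"
  for (a in c("ages", "children", "parents", "tips_under"))
    attr(tree, a) <- NULL
  as_gmyc_tree(ape::keep.tip(tree, keep))
}

#' Assign per-branch effective population sizes
#'
#' In `"fixed"` mode every branch receives `mean_Ne`. In `"lognormal"` mode
#' each extant species draws its size from a log-normal with natural-scale
#' mean `mean_Ne` (log-scale sd `sigma_log`, log-scale mean
#' `log(mean_Ne) - sigma_log^2/2`); each ancestral branch inherits the size
#' of its lowest-indexed descendant species, in deterministic tip order.
#'
#' @param tree a species `gmyc_tree`.
#' @param mode `"fixed"` or `"lognormal"`.
#' @param mean_Ne mean effective population size (individuals).
#' @param sigma_log log-scale standard deviation for `"lognormal"` mode.
#' @param seed integer seed, or `NULL`.
#' @return the tree with attributes `Ne` (per-node branch sizes) and
#'   `demography` (per-node segment lists, constant for now).
#' @export
assign_population_sizes <- function(tree, mode = c("fixed", "lognormal"),
                                    mean_Ne, sigma_log = 1, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(mean_Ne > 0)
  tree <- as_gmyc_tree(tree)
  if (!is.null(seed)) set.seed(seed)
  m <- n_tips(tree)
  tipNe <- if (mode == "fixed" || sigma_log == 0) {
    rep(mean_Ne, m)
  } else {
    stats::rlnorm(m, meanlog = log(mean_Ne) - sigma_log^2 / 2,
                  sdlog = sigma_log)
  }
  tu <- tips_under(tree)
  Ne <- numeric(2L * m - 1L)
  for (v in seq_len(2L * m - 1L)) Ne[v] <- tipNe[min(tu[[v]])]
  attr(tree, "Ne") <- Ne
  attr(tree, "demography") <- lapply(Ne, constant_demography)
  tree
}

#' Apply a growth or decline demographic history within species
#'
#' Scenario `"D1"` (recent growth): each species suffered an instantaneous
#' bottleneck `T_b` generations ago followed by exponential growth to the
#' present. The growth generates a 10-fold size increase and the bottleneck
#' severity is chosen so that the harmonic mean size over the growth period
#' equals the branch's `N_e`; present size is `9 N_e / log(10)`, bottleneck
#' size a tenth of that, and size before `T_b` is constant `N_e`. Scenario
#' `"D2"` mirrors it: instantaneous growth at `T_b` followed by exponential
#' 10-fold decline to the present, with the harmonic mean over the decline
#' period again equal to `N_e`.
#'
#' `T_b` is half the age of the penultimate (by default second most recent)
#' speciation node of the species tree.
#'
#' @param tree a species `gmyc_tree` with constant sizes already assigned by
#'   [assign_population_sizes()].
#' @param scenario `"D1"` or `"D2"`.
#' @param penultimate `"youngest"` (default: second most recent speciation
#'   node) or `"oldest"` (second oldest) — the reading of "penultimate" is
#'   configurable.
#' @return the tree with terminal-branch demographies replaced by the
#'   two-phase profiles.
#' @export
assign_demography <- function(tree, scenario = c("D1", "D2"),
                              penultimate = c("youngest", "oldest")) {
  scenario <- match.arg(scenario)
  penultimate <- match.arg(penultimate)
  tree <- as_gmyc_tree(tree)
  Ne <- attr(tree, "Ne")
  demo <- attr(tree, "demography")
  if (is.null(Ne) || is.null(demo))
    stop("assign constant population sizes first")
  m <- n_tips(tree)
  int_ages <- sort(node_ages(tree)[(m + 1L):(2L * m - 1L)])
  Tb <- 0.5 * if (penultimate == "youngest") int_ages[2L]
              else int_ages[length(int_ages) - 1L]
  if (Tb <= 0) stop("non-positive bottleneck age")
  r <- log(10) / Tb
  for (tip in seq_len(m)) {
    N_e <- Ne[tip]
    if (scenario == "D1") {
      # N(t) = N0 10^(-t/Tb) backward; harmonic mean over [0,Tb] = N0 ln10/9
      N0 <- 9 * N_e / log(10)
      demo[[tip]] <- list(seg(0, Tb, N0, -r), seg(Tb, Inf, N_e, 0))
    } else {
      # N(t) = N0 10^(t/Tb) backward; harmonic mean = N0 ln10/0.9
      N0 <- 0.9 * N_e / log(10)
      demo[[tip]] <- list(seg(0, Tb, N0, r), seg(Tb, Inf, N_e, 0))
    }
  }
  attr(tree, "demography") <- demo
  attr(tree, "Tb") <- Tb
  attr(tree, "demography_scenario") <- scenario
  tree
}

#' Draw the number of gene copies sampled per species
#'
#' @param tree a species `gmyc_tree`.
#' @param scheme `"per_species"` (every species gets exactly `n`),
#'   `"uniform_total"` (`n` individuals multinomially over species with equal
#'   probabilities), or `"proportional_total"` (probabilities proportional to
#'   tip population sizes, which must have been assigned).
#' @param n samples per species, or total, depending on the scheme.
#' @param seed integer seed, or `NULL`.
#' @return named integer vector over species labels (zeros possible under the
#'   total schemes).
#' @export
draw_sample_map <- function(tree,
                            scheme = c("per_species", "uniform_total",
                                       "proportional_total"),
                            n, seed = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(n > 1L)
  tree <- as_gmyc_tree(tree)
  if (!is.null(seed)) set.seed(seed)
  m <- n_tips(tree)
  counts <- switch(scheme,
    per_species = rep(as.integer(n), m),
    uniform_total = as.integer(stats::rmultinom(1L, n, rep(1 / m, m))),
    proportional_total = {
      Ne <- attr(tree, "Ne")
      if (is.null(Ne)) stop("proportional sampling needs assigned population sizes")
      as.integer(stats::rmultinom(1L, n, Ne[seq_len(m)] / sum(Ne[seq_len(m)])))
    })
  stats::setNames(counts, tree$tip.label)
}

#' Simulate a gene tree within a species tree (multispecies coalescent)
#'
#' Within every species-tree branch, taken tipward to rootward, the sampled
#' gene lineages coalesce pairwise at rate `1/(2 N(t))` per generation under
#' that branch's demography (time-varying rates are handled by inverting the
#' accumulated coalescent intensity). Lineages that fail to coalesce by the
#' top of a branch pass into the parent branch; above the species-tree root
#' the process continues under the root's ancestral (constant) size until a
#' single lineage remains. Node ages are continuous, so simultaneous events
#' never occur.
#'
#' @param tree a species `gmyc_tree` with demography assigned.
#' @param samples named integer vector of gene copies per species (total
#'   >= 2); species absent from the vector, or with zero count, are skipped.
#' @param seed integer seed, or `NULL`.
#' @return a list: `gene_tree` (a `gmyc_tree`, ages in generations),
#'   `truth` (named character vector mapping gene tips to species labels).
#' @export
simulate_gene_tree <- function(tree, samples, seed = NULL) {
  tree <- as_gmyc_tree(tree)
  demo <- attr(tree, "demography")
  if (is.null(demo)) stop("species tree has no assigned demography")
  if (!is.null(seed)) set.seed(seed)
  m <- n_tips(tree)
  counts <- integer(m)
  idx <- match(names(samples), tree$tip.label)
  if (anyNA(idx)) stop("sample map names must be species-tree tip labels")
  counts[idx] <- as.integer(samples)
  g <- sum(counts)
  if (g < 2L) stop("need at least two sampled gene copies in total")

  tip_labels <- character(g)
  tip_species <- character(g)
  pool <- vector("list", 2L * m - 1L)
  nxt <- 1L
  for (s in seq_len(m)) {
    if (counts[s] == 0L) next
    ids <- seq.int(nxt, nxt + counts[s] - 1L)
    tip_labels[ids] <- paste0(tree$tip.label[s], "_", seq_len(counts[s]))
    tip_species[ids] <- tree$tip.label[s]
    pool[[s]] <- ids
    nxt <- nxt + counts[s]
  }

  state <- new.env(parent = emptyenv())
  state$age <- numeric(2L * g - 1L)
  state$child1 <- integer(2L * g - 1L)
  state$child2 <- integer(2L * g - 1L)
  state$next_id <- g + 1L

  ages <- node_ages(tree)
  internal <- (m + 1L):(2L * m - 1L)
  ord <- internal[order(ages[internal], internal)]
  children <- children_of(tree)
  kids_of <- function(v) children[[v]]
  for (v in ord) {
    lins <- integer(0)
    for (ch in kids_of(v)) {
      from <- if (ch <= m) 0 else ages[ch]
      surv <- sim_within_branch(pool[[ch]] %||% integer(0), from, ages[v],
                                demo[[ch]], state)
      lins <- c(lins, surv)
    }
    pool[[v]] <- lins
  }
  root <- m + 1L
  sim_within_branch(pool[[root]], ages[root], Inf, demo[[root]], state)

  list(gene_tree = build_gene_phylo(state, tip_labels),
       truth = stats::setNames(tip_species, tip_labels))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a single-population neutral coalescent tree
#'
#' Kingman coalescent for `n_tips` samples in one panmictic population of
#' constant size `Ne` (diploid convention), ages in generations. The default
#' `Ne = 0.5` puts branch lengths on the standard coalescent scale on which
#' a pair of lineages coalesces at rate 1. Null trees are rescaled to root
#' age 1 before delimitation anyway, so the choice of `Ne` is immaterial
#' there.
#'
#' @param n_tips number of samples (>= 2).
#' @param seed integer seed, or `NULL`.
#' @param Ne constant effective population size.
#' @return a `gmyc_tree` with tips `t1..tn`.
#' @export
simulate_null_tree <- function(n_tips, seed = NULL, Ne = 0.5) {
  stopifnot(n_tips >= 2L)
  if (!is.null(seed)) set.seed(seed)
  g <- as.integer(n_tips)
  state <- new.env(parent = emptyenv())
  state$age <- numeric(2L * g - 1L)
  state$child1 <- integer(2L * g - 1L)
  state$child2 <- integer(2L * g - 1L)
  state$next_id <- g + 1L
  sim_within_branch(seq_len(g), 0, Inf, constant_demography(Ne), state)
  build_gene_phylo(state, paste0("t", seq_len(g)))
}

#' Simulated evaluation scenarios
#'
#' Composes the simulator operations into the named evaluation scenarios:
#'
#' * `A` — null model: one panmictic population, 150 sampled copies.
#' * `B` — 30-species Yule tree (root age 10^7 generations), constant equal
#'   population sizes, 5 copies per species.
#' * `C1` — as B but the 30 species are drawn from a 50-species Yule tree
#'   (recent deficit of speciation events).
#' * `C2` — as B but birth-death species tree with relative extinction 0.3
#'   (recent excess of speciation events).
#' * `D1` / `D2` — as B plus recent 10-fold exponential growth / decline
#'   within species (harmonic-mean size equal to `mean_Ne`).
#' * `E` — as B with log-normally distributed population sizes.
#' * `F1` — as B but 150 copies sampled uniformly at random across species.
#' * `F2` — log-normal sizes and copies sampled proportionally to size.
#'
#' Structured-population and sequence-based scenarios are out of scope and
#' rejected.
#'
#' @param name scenario name.
#' @param mean_Ne (mean) effective population size; the evaluation grid in
#'   the accompanying study is `1e4, 1e5, 5e5, 1e6`.
#' @param n_replicates number of replicate gene trees.
#' @param seed master seed; each replicate runs on an independently derived
#'   stream so replicate `i` is reproducible in isolation.
#' @param n_species,samples_per_species,total_samples,sigma_log scenario
#'   knobs, defaulting to the study conditions.
#' @return list of replicates; each has `gene_tree` (ages in generations),
#'   `scaled_tree` (rescaled to root age 1), `scale_factor`, `truth`,
#'   `species_tree` (`NULL` for scenario A), `sample_map`, `seed`.
#' @export
scenario <- function(name, mean_Ne = 1e4, n_replicates = 100L, seed = 1L,
                     n_species = 30L, samples_per_species = 5L,
                     total_samples = 150L, sigma_log = 1) {
  if (name %in% c("G", "H"))
    stop(sprintf("scenario %s (structured populations / sequence simulation) is out of scope",
                 name))
  name <- match.arg(name, c("A", "B", "C1", "C2", "D1", "D2", "E", "F1", "F2"))
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_replicates)

  lapply(seq_len(n_replicates), function(i) {
    set.seed(rep_seeds[i])
    if (name == "A") {
      gt <- simulate_null_tree(total_samples)
      truth <- stats::setNames(rep("sp1", total_samples), gt$tip.label)
      stree <- NULL; smap <- NULL
    } else {
      stree <- switch(name,
        C1 = subsample_species(simulate_yule_species_tree(50L), n_species),
        C2 = simulate_bd_species_tree(n_species, relative_extinction = 0.3),
        simulate_yule_species_tree(n_species))
      mode <- if (name %in% c("E", "F2")) "lognormal" else "fixed"
      stree <- assign_population_sizes(stree, mode, mean_Ne,
                                       sigma_log = sigma_log)
      if (name %in% c("D1", "D2")) stree <- assign_demography(stree, name)
      smap <- switch(name,
        F1 = draw_sample_map(stree, "uniform_total", total_samples),
        F2 = draw_sample_map(stree, "proportional_total", total_samples),
        draw_sample_map(stree, "per_species", samples_per_species))
      sim <- simulate_gene_tree(stree, smap)
      gt <- sim$gene_tree; truth <- sim$truth
    }
    fac <- 1 / root_age(gt)
    list(gene_tree = gt,
         scaled_tree = rescale_root_age(gt, 1),
         scale_factor = fac,
         truth = truth,
         species_tree = stree,
         sample_map = smap,
         seed = rep_seeds[i])
  })
}
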