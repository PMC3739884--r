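#' Split/fuse neighborhood of a delimitation
#'
#' The local moves of the multiple-threshold heuristic:
#' * SPLIT — replace a multi-tip cluster's MRCA by its two children (children
#'   that are tips become singletons);
#' * FUSE — where both children of a node are themselves delimited units (a
#'   cluster MRCA or a singleton tip), replace the pair by their parent as a
#'   single MRCA.
#'
#' Both moves keep every delimited species monophyletic by construction. The
#' result list is deduplicated and deterministically ordered.
#'
#' @param tree a `gmyc_tree`.
#' @param delim a `gmyc_delimitation`.
#' @return list of `gmyc_delimitation` neighbors.
#' @export
neighbors <- function(tree, delim) {
  tree <- as_gmyc_tree(tree)
  m <- n_tips(tree)
  par <- parents_of(tree)
  children <- children_of(tree)
  kids_of <- function(v) children[[v]]

  out <- list(); seen <- character(0)
  add <- function(mrca, singles) {
    d <- delimitation(tree, mrca = mrca, singletons = singles)
    key <- delim_key(d)
    if (!key %in% seen) {
      seen <<- c(seen, key)
      out[[length(out) + 1L]] <<- d
    }
  }

  for (v in delim$mrca) {                       # splits
    kids <- kids_of(v)
    add(mrca = c(setdiff(delim$mrca, v), kids[kids > m]),
        singles = c(delim$singletons, kids[kids <= m]))
  }

  unit_root <- logical(2L * m - 1L)             # fuses
  unit_root[delim$mrca] <- TRUE
  unit_root[delim$singletons] <- TRUE
  cand <- unique(par[c(delim$mrca, delim$singletons)])
  cand <- cand[cand != 0L]
  for (v in cand) {
    kids <- kids_of(v)
    if (all(unit_root[kids]))
      add(mrca = c(setdiff(delim$mrca, kids), v),
          singles = setdiff(delim$singletons, kids))
  }
  out
}

#' Multiple-threshold heuristic search
#'
#' Greedy hill-climbing over delimitations under the split/fuse move set,
#' seeded by default from the single-threshold maximum-likelihood
#' delimitation (the seeding the evaluation study found most reliable). Each
#' round fits every neighbor of the incumbent and accepts the best one if its
#' log-likelihood improves on the incumbent by more than `tol`; the search
#' stops when a round brings no improvement. All models evaluated along the
#' way are returned so they can be pooled into [model_comparison()].
#'
#' @param tree a `gmyc_tree`.
#' @param start a `gmyc_delimitation` to start from; default the best model
#'   of [single_threshold_scan()].
#' @param tol minimal log-likelihood improvement to accept a move.
#' @return an object of class `gmyc_search`: `best` (the final `gmyc_fit`),
#'   `visited` (all fits, deduplicated by delimitation), `found` (the fits
#'   of the accepted trajectory — the models the search *found*, which are
#'   the ones pooled into confidence sets), `trajectory` (accepted model
#'   keys in order), `rounds`, `converged`.
#' @export
heuristic_search <- function(tree, start = NULL, tol = 1e-9) {
  tree <- as_gmyc_tree(tree)
  if (is.null(start)) start <- single_threshold_scan(tree)$best$delimitation

  visited <- new.env(parent = emptyenv())
  get_fit <- function(delim) {
    key <- delim_key(delim)
    f <- visited[[key]]
    if (is.null(f)) {
      f <- tryCatch(fit_delimitation(tree, delim),
                    error = function(e) NULL)
      if (is.null(f))
        f <- new_fit(delim, NA_real_,
                     list(lambda_spec = 0, p_spec = 1, lambda_coal = 0, p_coal = 1),
                     -Inf, 4L, 1L)
      visited[[key]] <- f
    }
    f
  }

  incumbent <- get_fit(start)
  trajectory <- delim_key(start)
  rounds <- 0L; converged <- FALSE
  repeat {
    rounds <- rounds + 1L
    nb <- neighbors(tree, incumbent$delimitation)
    if (!length(nb)) { converged <- TRUE; break }
    fits <- lapply(nb, get_fit)
    ll <- vapply(fits, function(f) f$logLik, 0)
    best_i <- which.max(ll)
    if (ll[best_i] > incumbent$logLik + tol) {
      incumbent <- fits[[best_i]]
      key <- delim_key(incumbent$delimitation)
      if (key %in% trajectory) { converged <- TRUE; break }  # cycle guard
      trajectory <- c(trajectory, key)
    } else {
      converged <- TRUE
      break
    }
    if (rounds > 10000L) break
  }

  fits <- as.list(visited)
  fits <- fits[vapply(fits, function(f) is.finite(f$logLik), TRUE)]
  fits <- fits[order(vapply(fits, function(f) f$aic, 0))]
  found <- lapply(trajectory, function(k) visited[[k]])
  structure(list(best = incumbent, visited = unname(fits),
                 found = found,
                 trajectory = trajectory, rounds = rounds,
                 converged = converged, tree = tree),
            class = "gmyc_search")
}

#' @export
print.gmyc_search <- function(x, ...) {
  cat(sprintf(
    paste0("Multiple-threshold heuristic: %d rounds, %d models evaluated, ",
           "%sconverged\n  best: k = %d, lnL = %.4f\n"),
    x$rounds, length(x$visited), if (x$converged) "" else "NOT ",
    x$best$k, x$best$logLik))
  invisible(x)
}
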