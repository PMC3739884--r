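#' Exact-match delimitation accuracy
#'
#' A true species counts as correctly delimited iff some estimated cluster or
#' singleton contains exactly that species' sampled tips. Accuracy is the
#' number of correct species divided by the number of species with at least
#' one sampled tip (species can be unsampled under the random-total sampling
#' schemes).
#'
#' @param tree the gene `gmyc_tree` the delimitation lives on.
#' @param delim a `gmyc_delimitation`, or `NULL` for the null model (one
#'   cluster containing everything).
#' @param truth named character vector mapping every tip label to its true
#'   species.
#' @return proportion in `[0, 1]`.
#' @export
exact_match_accuracy <- function(tree, delim, truth) {
  tree <- as_gmyc_tree(tree)
  tips <- tree$tip.label
  if (!setequal(tips, names(truth)))
    stop("tip labels and truth map do not match")
  truth <- truth[tips]
  est_species <- if (is.null(delim)) rep(1L, length(tips)) else delim$species_of
  est_sets <- split(tips, est_species)
  est_keys <- vapply(est_sets, function(s) paste(sort(s), collapse = "\r"), "")
  true_sets <- split(tips, truth)
  true_keys <- vapply(true_sets, function(s) paste(sort(s), collapse = "\r"), "")
  mean(true_keys %in% est_keys)
}

#' False-positive / false-negative rates over replicate records
#'
#' Under null truth, a false positive is a replicate whose confidence set
#' excludes the null model; under alternative truth, a false negative is a
#' replicate whose confidence set includes it.
#'
#' @param records data frame with a logical `null_in_confidence_set` column
#'   (one row per replicate), e.g. from [run_study()].
#' @param truth_kind `"null"` or `"alternative"` — what generated the data.
#' @return a one-row data frame with `n`, and `false_positive_rate` or
#'   `false_negative_rate`.
#' @export
error_rates <- function(records, truth_kind = c("null", "alternative")) {
  truth_kind <- match.arg(truth_kind)
  if (!nrow(records)) stop("no replicate records")
  inc <- records$null_in_confidence_set
  if (truth_kind == "null") {
    data.frame(n = length(inc), false_positive_rate = mean(!inc))
  } else {
    data.frame(n = length(inc), false_negative_rate = mean(inc))
  }
}

# fit one replicate with one method and assemble its record row
replicate_record <- function(rep, method, level = 0.95) {
  tree <- rep$scaled_tree
  scan <- single_threshold_scan(tree)
  if (method == "single") {
    models <- scan$models
    best <- scan$best
  } else {
    search <- heuristic_search(tree, start = scan$best$delimitation)
    models <- c(scan$models, search$found)
    best <- search$best
  }
  cmp <- model_comparison(models, tree, level = level)
  lrt <- likelihood_ratio_test(scan$best, scan$null)
  acc <- exact_match_accuracy(tree, best$delimitation, rep$truth)
  supp <- cmp$support[as.character(best$delimitation$mrca)]
  supp[is.na(supp)] <- 0

  shape <- if (!is.null(rep$species_tree)) {
    shape_metrics(tree, rep$species_tree, rep$truth)
  } else {
    list(gamma = NA_real_, colless = NA_integer_,
         mean_branching_time = NA_real_, mean_species_tmrca = NA_real_)
  }

  data.frame(
    method = method,
    n_species_sampled = length(unique(rep$truth)),
    n_clusters = best$k,
    accuracy = acc,
    null_in_confidence_set = cmp$null_in_confidence_set,
    lrt_D = lrt$D, lrt_p = lrt$p_value,
    lambda_spec = best$lambda_spec, p_spec = best$p_spec,
    lambda_coal = best$lambda_coal, p_coal = best$p_coal,
    logLik = best$logLik, null_logLik = scan$null$logLik,
    mean_support = if (length(supp)) mean(supp) else NA_real_,
    gamma = shape$gamma, colless = shape$colless,
    mean_branching_time = shape$mean_branching_time,
    mean_species_tmrca = shape$mean_species_tmrca)
}

#' Run an evaluation study over simulated replicates
#'
#' For each combination of scenario, population size and method: simulate
#' replicate gene trees, rescale each to root age 1, run the single-threshold
#' scan (plus the heuristic search for the multiple-threshold method), build
#' the 95% confidence set, and record accuracy, error indicators, cluster
#' counts, fitted parameters, mean support over the ML delimitation's MRCA
#' nodes, and tree-shape covariates. Confidence sets are built per method:
#' single-threshold models only for `"single"`, pooled with the
#' heuristic-visited models for `"multiple"`. Replicate failures are caught
#' and flagged, never aborting the batch.
#'
#' @param scenarios character vector of scenario names.
#' @param ne_grid numeric vector of (mean) population sizes.
#' @param n_replicates replicates per (scenario, Ne) cell.
#' @param methods subset of `c("single", "multiple")`.
#' @param seed master seed (each cell derives its own stream).
#' @param level confidence-set level.
#' @return list with `records` (one row per replicate x method) and
#'   `summary` (per scenario x Ne x method: mean accuracy, FP or FN rate,
#'   cluster-count quartiles, parameter medians, mean support).
#' @export
run_study <- function(scenarios = "B", ne_grid = 1e4, n_replicates = 30L,
                      methods = "single", seed = 1L, level = 0.95) {
  stopifnot(all(methods %in% c("single", "multiple")))
  set.seed(seed)
  cells <- expand.grid(scenario = scenarios, ne = ne_grid,
                       stringsAsFactors = FALSE)
  cell_seeds <- sample.int(.Machine$integer.max - 1L, nrow(cells))

  records <- list()
  for (ci in seq_len(nrow(cells))) {
    sc <- cells$scenario[ci]; ne <- cells$ne[ci]
    reps <- scenario(sc, mean_Ne = ne, n_replicates = n_replicates,
                     seed = cell_seeds[ci])
    for (i in seq_along(reps)) {
      for (method in methods) {
        row <- tryCatch(
          replicate_record(reps[[i]], method, level = level),
          error = function(e) {
            data.frame(method = method, n_species_sampled = NA_integer_,
                       n_clusters = NA_integer_, accuracy = NA_real_,
                       null_in_confidence_set = NA, lrt_D = NA_real_,
                       lrt_p = NA_real_, lambda_spec = NA_real_,
                       p_spec = NA_real_, lambda_coal = NA_real_,
                       p_coal = NA_real_, logLik = NA_real_,
                       null_logLik = NA_real_, mean_support = NA_real_,
                       gamma = NA_real_, colless = NA_integer_,
                       mean_branching_time = NA_real_,
                       mean_species_tmrca = NA_real_)
          })
        row <- cbind(data.frame(scenario = sc, ne = ne, replicate = i,
                                failed = is.na(row$n_clusters)), row)
        records[[length(records) + 1L]] <- row
      }
    }
  }
  records <- do.call(rbind, records)

  grp <- interaction(records$scenario, records$ne, records$method, drop = TRUE)
  summ <- do.call(rbind, lapply(split(records, grp), function(d) {
    ok <- !d$failed
    data.frame(
      scenario = d$scenario[1], ne = d$ne[1], method = d$method[1],
      n = sum(ok), n_failed = sum(!ok),
      mean_accuracy = mean(d$accuracy[ok]),
      null_in_confidence_set_rate = mean(d$null_in_confidence_set[ok]),
      clusters_q1 = stats::quantile(d$n_clusters[ok], 0.25, names = FALSE),
      clusters_median = stats::median(d$n_clusters[ok]),
      clusters_q3 = stats::quantile(d$n_clusters[ok], 0.75, names = FALSE),
      p_spec_median = stats::median(d$p_spec[ok], na.rm = TRUE),
      p_coal_median = stats::median(d$p_coal[ok], na.rm = TRUE),
      mean_support = mean(d$mean_support[ok], na.rm = TRUE))
  }))
  rownames(summ) <- NULL
  list(records = records, summary = summ)
}
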