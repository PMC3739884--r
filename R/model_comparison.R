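#' Multimodel comparison with Akaike weights
#'
#' Computes Akaike weights `w_i = exp(-dAIC_i/2) / sum(exp(-dAIC/2))` over a
#' set of candidate delimitation models (always including the null fit
#' exactly once), the confidence set (the smallest AIC-ascending prefix whose
#' cumulative weight reaches `level`), per-node support values (the summed
#' weight of models in which a node appears as a species-defining MRCA), and
#' model-averaged parameter estimates with unconditional standard errors.
#'
#' Duplicate models (identical delimitations) are removed before weighting —
#' pooling the single-threshold candidates with heuristic-search visits would
#' otherwise double-count weights.
#'
#' Model averaging uses `theta_bar = sum(w_i theta_i)` and the unconditional
#' standard error `sum(w_i sqrt(var_i + (theta_i - theta_bar)^2))`, with
#' per-model variances from the observed information (numeric Hessian of the
#' full likelihood at the optimum). Diversification parameters are averaged
#' over the models in which they exist (weights renormalized); the null
#' model's rate and exponent enter the coalescent-parameter averages.
#' Hessians are only evaluated for models with non-negligible weight
#' (`w > 1e-6`); others contribute their point estimate with zero variance.
#'
#' @param models list of `gmyc_fit` objects (possibly from several searches),
#'   containing exactly one null fit.
#' @param tree the `gmyc_tree` the models were fitted to (needed for the
#'   Hessians; may be omitted if `se = FALSE`).
#' @param level confidence level for the model confidence set.
#' @param se compute model-averaged standard errors (slower).
#' @return an object of class `gmyc_comparison` with elements `models`
#'   (deduplicated, AIC-ascending), `table` (data frame: model_id,
#'   threshold, k, logLik, n_params, aic, daic, weight, cumulative_weight,
#'   in_confidence_set, is_null), `weights`, `confidence_set` (indices into
#'   `models`), `support` (named vector over MRCA node ids), `averaged`
#'   (data frame of model-averaged parameters and unconditional SEs), and
#'   `null_in_confidence_set`.
#' @export
model_comparison <- function(models, tree = NULL, level = 0.95, se = FALSE) {
  stopifnot(length(models) >= 1L, level > 0, level < 1)
  keys <- vapply(models, function(f)
    if (f$is_null) "null" else delim_key(f$delimitation), "")
  if (sum(keys == "null") != 1L)
    stop("'models' must contain the null fit exactly once")
  models <- models[!duplicated(keys)]

  aic <- vapply(models, function(f) f$aic, 0)
  ord <- order(aic)
  models <- models[ord]; aic <- aic[ord]
  daic <- aic - aic[1L]
  w <- exp(-daic / 2); w <- w / sum(w)
  cum <- cumsum(w)
  r <- which(cum >= level)[1L]
  conf <- seq_len(r)
  is_null <- vapply(models, function(f) f$is_null, TRUE)

  support <- numeric(0)
  for (i in seq_along(models)) {
    if (is_null[i]) next
    for (v in models[[i]]$delimitation$mrca) {
      key <- as.character(v)
      support[key] <- if (key %in% names(support)) support[key] + w[i] else w[i]
    }
  }
  support <- pmin(support, 1)

  tab <- data.frame(
    model_id = vapply(seq_along(models), function(i)
      if (is_null[i]) "null" else sprintf("m%03d", i), ""),
    threshold = vapply(models, function(f) f$threshold, 0),
    k = vapply(models, function(f) f$k, 0L),
    logLik = vapply(models, function(f) f$logLik, 0),
    n_params = vapply(models, function(f) f$n_params, 0L),
    aic = aic, daic = daic, weight = w, cumulative_weight = cum,
    in_confidence_set = seq_along(models) %in% conf,
    is_null = is_null)

  avg <- model_average(models, w, tree, se = se)

  structure(list(models = models, table = tab, weights = w,
                 confidence_set = conf, support = support, averaged = avg,
                 level = level,
                 null_in_confidence_set = any(is_null[conf])),
            class = "gmyc_comparison")
}

#' @export
print.gmyc_comparison <- function(x, ...) {
  cat(sprintf(
    paste0("Model comparison: %d candidate delimitations, %d in the %.0f%% ",
           "confidence set (null %s)\n"),
    nrow(x$table), length(x$confidence_set), 100 * x$level,
    if (x$null_in_confidence_set) "included" else "excluded"))
  print(utils::head(x$table, 8L), row.names = FALSE, digits = 5)
  invisible(x)
}

model_average <- function(models, w, tree, se = FALSE) {
  pars <- c("lambda_spec", "p_spec", "lambda_coal", "p_coal")
  est <- matrix(NA_real_, length(models), 4L, dimnames = list(NULL, pars))
  has <- matrix(FALSE, length(models), 4L, dimnames = list(NULL, pars))
  for (i in seq_along(models)) {
    f <- models[[i]]
    if (f$is_null) {
      est[i, c("lambda_coal", "p_coal")] <- c(f$lambda_coal, f$p_coal)
      has[i, c("lambda_coal", "p_coal")] <- TRUE
    } else {
      est[i, ] <- c(f$lambda_spec, f$p_spec, f$lambda_coal, f$p_coal)
      has[i, 1:2] <- f$lambda_spec > 0
      has[i, 3:4] <- f$lambda_coal > 0
    }
  }
  vars <- matrix(0, length(models), 4L, dimnames = list(NULL, pars))
  if (se && !is.null(tree)) {
    for (i in seq_along(models)) {
      if (w[i] <= 1e-6) next
      vars[i, ] <- fit_variances(tree, models[[i]])
    }
  }
  out <- data.frame(parameter = pars, estimate = NA_real_, se = NA_real_)
  for (j in 1:4) {
    m <- has[, j]
    if (!any(m)) next
    wj <- w[m] / sum(w[m])
    th <- est[m, j]
    mean_th <- sum(wj * th)
    out$estimate[j] <- mean_th
    out$se[j] <- sum(wj * sqrt(pmax(vars[m, j], 0) + (th - mean_th)^2))
  }
  out
}

# per-parameter variances from the observed information of the full
# (unprofiled) likelihood at the fitted optimum; NA-safe
fit_variances <- function(tree, fit) {
  out <- c(lambda_spec = 0, p_spec = 0, lambda_coal = 0, p_coal = 0)
  iv <- if (fit$is_null) compute_intervals(tree, NULL)
        else compute_intervals(tree, fit$delimitation)
  free <- c(fit$lambda_spec > 0, fit$lambda_spec > 0,
            fit$lambda_coal > 0, fit$lambda_coal > 0)
  if (fit$is_null) free[1:2] <- FALSE
  theta0 <- c(fit$lambda_spec, fit$p_spec, fit$lambda_coal, fit$p_coal)
  if (!any(free)) return(out)
  fn <- function(th) {
    full <- theta0; full[free] <- th
    ll <- mixed_loglik(iv, full[1], full[2], full[3], full[4])
    if (!is.finite(ll)) -1e10 else ll
  }
  H <- try(stats::optimHess(theta0[free], fn), silent = TRUE)
  if (inherits(H, "try-error")) return(out)
  V <- try(solve(-H), silent = TRUE)
  if (inherits(V, "try-error")) return(out)
  d <- diag(V)
  d[!is.finite(d) | d < 0] <- 0
  out[free] <- d
  out
}
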