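#' Add-one empirical p-value
#'
#' `(1 + #\{null <= observed\}) / (1 + #nulls)`: ties count against the model
#' and the p-value is always positive, so a model beating all of 999 nulls
#' reports exactly 1/1000.
#'
#' @param observed Observed statistic (here, LOO-RMSE; smaller is better).
#' @param nulls Numeric vector of null statistics.
#' @return Empirical p-value in (0, 1].
#' @export
empirical_pvalue <- function(observed, nulls) {
  (1 + sum(nulls <= observed)) / (1 + length(nulls))
}

#' Size-matched random-component null distribution
#'
#' Draws up to `cap` distinct component subsets of the same size as the true
#' selection (enumerating all subsets when there are no more than `cap`),
#' never including the true subset, fits an OLS model on each and records its
#' LOO-RMSE. The observed model's rank within this distribution gives the
#' empirical p-value.
#'
#' @param scores A `projected_scores` object or samples x components matrix.
#' @param phenotype Numeric outcome per sample.
#' @param model The fitted `translatable_model` (supplies the subset size,
#'   the true component set and the observed LOO-RMSE).
#' @param cap Maximum number of null models (default 1000).
#' @param seed Optional integer seed.
#' @return A `null_distribution` object: `scheme = "random_pc"`, `rmse`
#'   vector, `failures` (always 0 for this scheme), `n_attempted`,
#'   `observed_rmse`, `empirical_p`.
#' @export
random_pc_null <- function(scores, phenotype, model, cap = 1000, seed = NULL) {
  X <- .score_matrix(scores)
  y <- as.numeric(phenotype)
  if (model$status != "ok") stop("model has no successful selection", call. = FALSE)
  comp <- colnames(X)
  k <- length(model$selected)
  K <- ncol(X)
  if (k > K) stop("selection larger than component count", call. = FALSE)
  total <- choose(K, k)
  if (total <= 1) stop("degenerate null: only one size-", k,
                       " subset exists, p undefined", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  true_key <- paste(sort(match(model$selected, comp)), collapse = ",")
  if (total <= cap) {
    subsets <- utils::combn(K, k, simplify = FALSE)
    keys <- vapply(subsets, paste, character(1), collapse = ",")
    subsets <- subsets[keys != true_key]
  } else {
    seen <- character(0)
    subsets <- list()
    while (length(subsets) < cap) {
      s <- sort(sample.int(K, k))
      key <- paste(s, collapse = ",")
      if (key == true_key || key %in% seen) next
      seen <- c(seen, key)
      subsets[[length(subsets) + 1L]] <- s
    }
  }
  rmse <- vapply(subsets, function(s) .loo_rmse(X[, s, drop = FALSE], y),
                 numeric(1))
  structure(
    list(scheme = "random_pc",
         rmse = rmse,
         failures = 0L,
         n_attempted = length(subsets),
         observed_rmse = model$loo_rmse,
         empirical_p = empirical_pvalue(model$loo_rmse, rmse)),
    class = "null_distribution"
  )
}

#' Phenotype-permutation null distribution
#'
#' Each null model starts from a unique permutation of the phenotype vector
#' (never the observed ordering) and runs the full two-step pipeline:
#' consensus LASSO selection followed, when any component survives the
#' frequency threshold, by the final linear model. Permutations in which no
#' component is selected are recorded as failures and contribute no RMSE;
#' an all-failure outcome is a meaningful result ("no successful nulls") and
#' leaves the empirical p undefined (`NA`).
#'
#' @param scores A `projected_scores` object or samples x components matrix.
#' @param phenotype Numeric outcome per sample (non-constant).
#' @param model The fitted `translatable_model` (for the observed LOO-RMSE).
#' @param n Number of null models (default 100). If fewer distinct
#'   permutations exist, all of them (minus the observed) are used.
#' @param seed Optional integer seed.
#' @param repeats,folds,lasso_per_fold,threshold Passed to
#'   [consensus_lasso()] for each null run.
#' @return A `null_distribution` object: `scheme = "permuted_phenotype"`,
#'   `rmse` (successful nulls only), `failures`, `n_attempted`,
#'   `observed_rmse`, `empirical_p` (`NA` when no null succeeded).
#' @export
permutation_null <- function(scores, phenotype, model, n = 100, seed = NULL,
                             repeats = 10, folds = 5, lasso_per_fold = 10,
                             threshold = 0.40) {
  X <- .score_matrix(scores)
  y <- as.numeric(phenotype)
  if (length(unique(y)) < 2) {
    stop("phenotype is constant; permutations are degenerate", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  perms <- .unique_permutations(y, n)
  run_seeds <- sample.int(.Machine$integer.max, length(perms))
  rmse <- numeric(0)
  failures <- 0L
  for (i in seq_along(perms)) {
    sel <- consensus_lasso(X, perms[[i]], repeats = repeats, folds = folds,
                           lasso_per_fold = lasso_per_fold,
                           threshold = threshold, seed = run_seeds[i])
    if (length(sel$selected) == 0) {
      failures <- failures + 1L
    } else {
      fit <- fit_final_model(X, perms[[i]], sel$selected)
      rmse <- c(rmse, fit$loo_rmse)
    }
  }
  p <- if (length(rmse) > 0 && model$status == "ok") {
    empirical_pvalue(model$loo_rmse, rmse)
  } else NA_real_
  structure(
    list(scheme = "permuted_phenotype",
         rmse = rmse,
         failures = failures,
         n_attempted = length(perms),
         observed_rmse = if (model$status == "ok") model$loo_rmse else NA_real_,
         empirical_p = p),
    class = "null_distribution"
  )
}

# up to n unique permutations of y, none equal to y itself
.unique_permutations <- function(y, n) {
  counts <- table(y)
  log_total <- lgamma(length(y) + 1) - sum(lgamma(counts + 1))
  total <- if (log_total < log(1e7)) round(exp(log_total)) else Inf
  if (total - 1 < 1) stop("phenotype admits no distinct permutation", call. = FALSE)
  y_key <- paste(y, collapse = ",")
  if (is.finite(total) && total - 1 <= n) {
    perms <- .enumerate_multiset_permutations(y)
    keys <- vapply(perms, paste, character(1), collapse = ",")
    return(perms[keys != y_key])
  }
  seen <- character(0)
  out <- list()
  while (length(out) < n) {
    p <- sample(y)
    key <- paste(p, collapse = ",")
    if (key == y_key || key %in% seen) next
    seen <- c(seen, key)
    out[[length(out) + 1L]] <- p
  }
  out
}

# recursive enumeration of all distinct orderings of a small multiset
.enumerate_multiset_permutations <- function(y) {
  vals <- sort(unique(y))
  counts <- as.integer(table(factor(y, levels = vals)))
  out <- list()
  recurse <- function(prefix, counts) {
    if (all(counts == 0)) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible(NULL))
    }
    for (v in seq_along(vals)) {
      if (counts[v] > 0) {
        counts[v] <- counts[v] - 1L
        recurse(c(prefix, vals[v]), counts)
        counts[v] <- counts[v] + 1L
      }
    }
  }
  recurse(numeric(0), counts)
  out
}

#' @export
print.null_distribution <- function(x, ...) {
  cat("<null_distribution> scheme:", x$scheme, "\n")
  cat("  nulls:", length(x$rmse), "successful,", x$failures, "failed of",
      x$n_attempted, "attempted\n")
  if (is.na(x$empirical_p)) {
    cat("  no successful nulls; empirical p undefined\n")
  } else {
    cat("  observed LOO-RMSE", signif(x$observed_rmse, 4),
        "-> empirical p =", signif(x$empirical_p, 4), "\n")
  }
  invisible(x)
}
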