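#' Consensus LASSO selection of translatable components
#'
#' Stability selection over repeated stratified cross-validation. For each
#' of `repeats` rounds the samples are partitioned into `folds`
#' phenotype-stratified folds, giving `repeats * folds` runs in total (50
#' under the defaults). Within each run, an L1-penalized least-squares
#' regression of the phenotype on the component scores is fit on the
#' training samples only; the penalty is chosen by inner 5-fold
#' cross-validation of the mean-squared-error curve under the
#' one-standard-error rule (the sparsest penalty within one standard error
#' of the error minimum — the conservative convention stability selection
#' needs so that chance correlations do not enter), with the inner
#' cross-validation repeated `lasso_per_fold` times (fresh inner fold
#' assignments) and the error curves pooled so the penalty choice does not
#' hinge on one arbitrary inner partition. The run's selection is the set of
#' components with nonzero coefficients at that penalty. Components whose
#' selection frequency over all runs reaches `threshold` (at least 40
#' percent by default; a frequency exactly at the threshold counts) are
#' returned.
#'
#' @param scores A `projected_scores` object or a samples x components
#'   numeric matrix.
#' @param phenotype Numeric outcome per sample (e.g. genotype dose 0/1/2);
#'   must be non-constant.
#' @param repeats Number of cross-validation rounds (default 10).
#' @param folds Folds per round (default 5).
#' @param lasso_per_fold Inner cross-validation repetitions per run whose
#'   error curves are pooled for the penalty choice (default 10).
#' @param threshold Selection-frequency cutoff (default 0.40).
#' @param seed Optional integer seed; with it results are bit-reproducible.
#' @return A `consensus_selection` object: `frequency` tibble (`component`,
#'   `frequency`, `selected`), `selected` component ids, `runs` log tibble
#'   (repeat, fold, chosen penalty, nonzero set), `n_runs`, `threshold`.
#' @export
consensus_lasso <- function(scores, phenotype, repeats = 10, folds = 5,
                            lasso_per_fold = 10, threshold = 0.40, seed = NULL) {
  X <- .score_matrix(scores)
  y <- as.numeric(phenotype)
  stopifnot(nrow(X) == length(y))
  if (length(unique(y)) < 2) {
    stop("selection error: phenotype is constant", call. = FALSE)
  }
  if (nrow(X) < folds * 2) {
    stop("selection error: need at least folds * 2 samples", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  comp <- colnames(X)
  if (is.null(comp)) comp <- paste0("PC", seq_len(ncol(X)))
  classes <- table(y)
  if (any(classes < folds)) {
    warning("fewer samples than folds in some phenotype class; ",
            "stratification is best-effort", call. = FALSE)
  }
  run_log <- vector("list", repeats * folds)
  r <- 0L
  for (rep_i in seq_len(repeats)) {
    fold_id <- .stratified_folds(y, folds)
    for (fold_i in seq_len(folds)) {
      r <- r + 1L
      train <- which(fold_id != fold_i)
      fit <- .lasso_run(X[train, , drop = FALSE], y[train], lasso_per_fold)
      run_log[[r]] <- tibble::tibble(repeat_ = rep_i, fold = fold_i,
                                     lambda = fit$lambda,
                                     selected = list(comp[fit$nonzero]))
    }
  }
  runs <- dplyr::bind_rows(run_log)
  counts <- vapply(comp, function(cm) {
    sum(vapply(runs$selected, function(s) cm %in% s, logical(1)))
  }, integer(1))
  freq <- counts / nrow(runs)
  frequency <- tibble::tibble(component = comp, frequency = unname(freq),
                              selected = unname(freq >= threshold))
  structure(
    list(frequency = frequency,
         selected = comp[freq >= threshold],
         runs = runs,
         n_runs = nrow(runs),
         threshold = threshold),
    class = "consensus_selection"
  )
}

# phenotype-stratified fold assignment: shuffle within class, deal round-robin
.stratified_folds <- function(y, folds) {
  fold_id <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    idx <- idx[sample.int(length(idx))]
    fold_id[idx] <- rep_len(sample.int(folds), length(idx))
  }
  fold_id
}

# one lasso run: penalty from `reps` pooled inner 5-fold CV error curves
# under the one-standard-error rule, nonzero set at that penalty
.lasso_run <- function(x, y, reps) {
  n <- nrow(x)
  empty <- list(lambda = NA_real_, nonzero = integer(0))
  if (n < 4 || stats::sd(y) == 0) return(empty)
  nf <- min(5, max(2, floor(n / 2)))
  path <- glmnet::glmnet(x, y, family = "gaussian", standardize = TRUE)
  lam <- path$lambda
  fold_mse <- list()
  for (b in seq_len(reps)) {
    foldid <- sample(rep_len(seq_len(nf), n))
    for (f in seq_len(nf)) {
      tr <- foldid != f
      if (sum(tr) < 2 || sum(!tr) < 1) next
      s <- stats::sd(y[tr])
      if (is.na(s) || s == 0) next
      fit <- glmnet::glmnet(x[tr, , drop = FALSE], y[tr], family = "gaussian",
                            lambda = lam, standardize = TRUE)
      pred <- stats::predict(fit, x[!tr, , drop = FALSE])
      m <- colMeans((pred - y[!tr])^2)
      mse <- rep(NA_real_, length(lam))
      mse[seq_along(m)] <- m
      fold_mse[[length(fold_mse) + 1L]] <- mse
    }
  }
  if (length(fold_mse) == 0) return(empty)
  M <- do.call(rbind, fold_mse)
  ok <- colSums(is.na(M)) == 0
  if (!any(ok)) return(empty)
  cvm <- colMeans(M[, ok, drop = FALSE])
  cvse <- if (nrow(M) > 1) {
    apply(M[, ok, drop = FALSE], 2, stats::sd) / sqrt(nrow(M))
  } else rep(0, sum(ok))
  i_min <- which.min(cvm)
  # 1-SE rule: sparsest (largest) penalty whose CV error is within one
  # standard error of the minimum; lambdas are sorted decreasing
  i_best <- min(which(cvm <= cvm[i_min] + cvse[i_min]))
  best_i <- which(ok)[i_best]
  list(lambda = lam[best_i],
       nonzero = which(as.numeric(path$beta[, best_i]) != 0))
}

#' @export
print.consensus_selection <- function(x, ...) {
  cat("<consensus_selection> ", x$n_runs, " runs, threshold ",
      x$threshold, "\n  selected: ",
      if (length(x$selected) > 0) paste(x$selected, collapse = ", ") else "(none)",
      "\n", sep = "")
  invisible(x)
}

#' Fit the final translatable linear model
#'
#' Ordinary least squares of the phenotype on the consensus-selected
#' component scores, with per-coefficient t and p values and the
#' leave-one-out cross-validated RMSE (each sample predicted from a model
#' refit without it; computed through the exact hat-matrix identity).
#'
#' @param scores A `projected_scores` object or samples x components matrix.
#' @param phenotype Numeric outcome per sample.
#' @param selected Character vector of selected component ids. An empty
#'   selection is a meaningful outcome: the returned model carries status
#'   `"selection_failed"` instead of an error.
#' @return A `translatable_model` object: `status`, `selected`,
#'   `coefficients` tibble (`term`, `estimate`, `statistic`, `p.value`),
#'   `loo_rmse`, `insample_rmse`, `loo_predictions` tibble, `n`.
#' @export
fit_final_model <- function(scores, phenotype, selected) {
  X <- .score_matrix(scores)
  y <- as.numeric(phenotype)
  if (length(selected) == 0) {
    return(structure(list(status = "selection_failed", selected = character(0)),
                     class = "translatable_model"))
  }
  missing_cols <- setdiff(selected, colnames(X))
  if (length(missing_cols) > 0) {
    stop("unknown component id(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  Xs <- X[, selected, drop = FALSE]
  n <- nrow(Xs)
  if (n <= length(selected) + 1) {
    stop("need n > number of selected components + 1", call. = FALSE)
  }
  df <- data.frame(y = y, Xs, check.names = FALSE)
  fit <- stats::lm(y ~ ., data = df)
  sm <- summary(fit)$coefficients
  coefs <- tibble::tibble(
    term = rownames(sm),
    estimate = sm[, "Estimate"],
    statistic = sm[, "t value"],
    p.value = sm[, "Pr(>|t|)"]
  )
  e <- stats::residuals(fit)
  h <- stats::hatvalues(fit)
  loo_resid <- e / (1 - h)
  structure(
    list(
      status = "ok",
      selected = selected,
      coefficients = coefs,
      loo_rmse = sqrt(mean(loo_resid^2)),
      insample_rmse = sqrt(mean(e^2)),
      loo_predictions = tibble::tibble(
        sample_id = if (!is.null(rownames(Xs))) rownames(Xs) else as.character(seq_len(n)),
        observed = y,
        predicted = unname(y - loo_resid)
      ),
      n = n
    ),
    class = "translatable_model"
  )
}

#' @export
print.translatable_model <- function(x, ...) {
  if (x$status != "ok") {
    cat("<translatable_model> status:", x$status, "\n")
    return(invisible(x))
  }
  cat("<translatable_model> ", length(x$selected), " component(s): ",
      paste(x$selected, collapse = ", "), "\n  LOO-RMSE = ",
      signif(x$loo_rmse, 4), " (in-sample ", signif(x$insample_rmse, 4),
      ")\n", sep = "")
  invisible(x)
}

# fast OLS LOO-RMSE for a fixed column subset (used by the null schemes)
.loo_rmse <- function(X, y) {
  Xd <- cbind(1, X)
  qrX <- qr(Xd)
  e <- qr.resid(qrX, y)
  Q <- qr.Q(qrX)
  h <- rowSums(Q^2)
  sqrt(mean((e / (1 - h))^2))
}

#' Intersect the three translatable-component criteria
#'
#' A component is reported as translatable when it is (a) consensus-selected,
#' (b) significant in the final linear model (coefficient p below
#' `coef_alpha`) and (c) passes the age-decoupling F-test.
#'
#' @param model A `translatable_model` (fitted on the consensus selection).
#' @param age_results Tibble from [age_decoupling()] on the same components,
#'   with columns `component` and `pass`.
#' @param coef_alpha Coefficient significance threshold (default 0.05).
#' @return Character vector of component ids (possibly empty).
#' @export
intersect_translatable <- function(model, age_results, coef_alpha = 0.05) {
  if (model$status != "ok") return(character(0))
  sig <- model$coefficients$term[model$coefficients$term != "(Intercept)" &
                                 model$coefficients$p.value < coef_alpha]
  sig <- gsub("^`|`$", "", sig)
  passed <- age_results$component[age_results$pass]
  intersect(intersect(model$selected, sig), passed)
}
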