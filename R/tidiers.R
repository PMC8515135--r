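#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted PCA space
#'
#' @param x A `pca_space`.
#' @param ... Unused.
#' @return A tibble with one row per retained component: `component`,
#'   `explained_fraction`, `cumulative_fraction`.
#' @method tidy pca_space
#' @export
tidy.pca_space <- function(x, ...) {
  tibble::tibble(
    component = colnames(x$loadings),
    explained_fraction = x$explained_fraction,
    cumulative_fraction = cumsum(x$explained_fraction)
  )
}

#' @rdname tidy.pca_space
#' @return For `glance()`: a one-row tibble with `n_components`, `n_genes`,
#'   `n_samples`, `variance_retained`.
#' @method glance pca_space
#' @export
glance.pca_space <- function(x, ...) {
  tibble::tibble(
    n_components = x$n_components,
    n_genes = length(x$gene_order),
    n_samples = nrow(x$sample_scores),
    variance_retained = sum(x$explained_fraction)
  )
}

#' Tidy projected scores into long form
#'
#' @param x A `projected_scores` object.
#' @param ... Unused.
#' @return A tibble with columns `sample_id`, `component`, `score` joined
#'   with the projecting study's metadata.
#' @method tidy projected_scores
#' @export
tidy.projected_scores <- function(x, ...) {
  long <- tibble::tibble(
    sample_id = rep(rownames(x$scores), times = ncol(x$scores)),
    component = rep(colnames(x$scores), each = nrow(x$scores)),
    score = as.vector(x$scores)
  )
  if (!is.null(x$metadata)) long <- dplyr::left_join(long, x$metadata, by = "sample_id")
  long
}

#' @rdname tidy.projected_scores
#' @return For `glance()`: one row per component with its projected-variance
#'   fraction.
#' @method glance projected_scores
#' @export
glance.projected_scores <- function(x, ...) {
  tibble::tibble(component = x$component,
                 projected_fraction = x$projected_fraction)
}

#' Tidy a consensus selection
#'
#' @param x A `consensus_selection`.
#' @param ... Unused.
#' @return The per-component frequency tibble (`component`, `frequency`,
#'   `selected`).
#' @method tidy consensus_selection
#' @export
tidy.consensus_selection <- function(x, ...) x$frequency

#' @rdname tidy.consensus_selection
#' @return For `glance()`: `n_runs`, `threshold`, `n_selected`.
#' @method glance consensus_selection
#' @export
glance.consensus_selection <- function(x, ...) {
  tibble::tibble(n_runs = x$n_runs, threshold = x$threshold,
                 n_selected = length(x$selected))
}

#' Tidy a translatable model
#'
#' @param x A `translatable_model`.
#' @param ... Unused.
#' @return The coefficient tibble (`term`, `estimate`, `statistic`,
#'   `p.value`); zero rows for a failed selection.
#' @method tidy translatable_model
#' @export
tidy.translatable_model <- function(x, ...) {
  if (x$status != "ok") {
    return(tibble::tibble(term = character(0), estimate = numeric(0),
                          statistic = numeric(0), p.value = numeric(0)))
  }
  x$coefficients
}

#' @rdname tidy.translatable_model
#' @return For `glance()`: `status`, `n_components`, `loo_rmse`,
#'   `insample_rmse`, `n`.
#' @method glance translatable_model
#' @export
glance.translatable_model <- function(x, ...) {
  if (x$status != "ok") {
    return(tibble::tibble(status = x$status, n_components = 0L,
                          loo_rmse = NA_real_, insample_rmse = NA_real_,
                          n = NA_integer_))
  }
  tibble::tibble(status = x$status, n_components = length(x$selected),
                 loo_rmse = x$loo_rmse, insample_rmse = x$insample_rmse,
                 n = x$n)
}

#' Tidy a null distribution
#'
#' @param x A `null_distribution`.
#' @param ... Unused.
#' @return A tibble with one row per successful null model (`scheme`,
#'   `rmse`).
#' @method tidy null_distribution
#' @export
tidy.null_distribution <- function(x, ...) {
  tibble::tibble(scheme = x$scheme, rmse = x$rmse)
}

#' @rdname tidy.null_distribution
#' @return For `glance()`: `scheme`, `n_attempted`, `n_successful`,
#'   `failures`, `observed_rmse`, `empirical_p`.
#' @method glance null_distribution
#' @export
glance.null_distribution <- function(x, ...) {
  tibble::tibble(scheme = x$scheme, n_attempted = x$n_attempted,
                 n_successful = length(x$rmse), failures = x$failures,
                 observed_rmse = x$observed_rmse, empirical_p = x$empirical_p)
}
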