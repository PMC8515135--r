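#' Run the full cross-species translatable-components pipeline
#'
#' Convenience wrapper chaining the pipeline stages in their fixed order:
#' restrict both studies to one-to-one homologs, optionally narrow the human
#' study to a permissive DEG list (computed on the unstandardized scale),
#' z-score each study internally, fit the human PCA space, project the mouse
#' samples, run consensus LASSO against the mouse genotype dose, fit the
#' final linear model, run per-component age-decoupling F-tests, and
#' intersect the three translatability criteria.
#'
#' @param human Human [expression_study()] (unstandardized log scale).
#' @param mouse Mouse [expression_study()] (unstandardized log scale).
#' @param map A `homolog_map`; omit for studies sharing gene identifiers.
#' @param deg_alpha If non-`NULL`, run [select_degs()] at this BH threshold
#'   and keep only selected genes before PCA (default `NULL`: all homologs).
#' @param deg_cap Optional cap forwarded to [select_degs()].
#' @param var_cum,var_each PCA retention thresholds.
#' @param label_map Mouse phenotype encoding for [encode_phenotype()].
#' @param repeats,folds,lasso_per_fold,threshold Consensus LASSO settings.
#' @param age_threshold Age-decoupling pass threshold (default 0.01).
#' @param coef_alpha Final-model coefficient significance threshold.
#' @param seed Optional integer seed for the selection stage.
#' @return A `transcompr_result` list: `pca`, `projected`, `phenotype`,
#'   `selection`, `model`, `age`, `translatable` (component ids passing all
#'   three criteria).
#' @export
run_transcompr <- function(human, mouse, map = NULL,
                           deg_alpha = NULL, deg_cap = NULL,
                           var_cum = 0.95, var_each = 0.01,
                           label_map = c(WT = 0L, HET = 1L, HO = 2L),
                           repeats = 10, folds = 5, lasso_per_fold = 10,
                           threshold = 0.40, age_threshold = 0.01,
                           coef_alpha = 0.05, seed = NULL) {
  if (!is.null(map)) {
    human <- homolog_filter(human, map)
    mouse <- homolog_filter(mouse, map)
  }
  if (!is.null(deg_alpha)) {
    degs <- select_degs(human, alpha = deg_alpha, cap = deg_cap)
    human <- keep_genes(human, degs$gene[degs$selected])
  }
  human_z <- zscore_genes(human)
  mouse_z <- zscore_genes(mouse)
  pca <- fit_pca(human_z, var_cum = var_cum, var_each = var_each)
  projected <- project_into(pca, mouse_z, map = map)
  phenotype <- encode_phenotype(mouse$metadata, label_map)
  selection <- consensus_lasso(projected, phenotype, repeats = repeats,
                               folds = folds, lasso_per_fold = lasso_per_fold,
                               threshold = threshold, seed = seed)
  model <- fit_final_model(projected, phenotype, selection$selected)
  age <- age_decoupling(projected, age = mouse$metadata$age,
                        disease = phenotype, threshold = age_threshold)
  translatable <- intersect_translatable(model, age, coef_alpha = coef_alpha)
  structure(
    list(pca = pca, projected = projected, phenotype = phenotype,
         selection = selection, model = model, age = age,
         translatable = translatable),
    class = "transcompr_result"
  )
}

#' @export
print.transcompr_result <- function(x, ...) {
  cat("<transcompr_result>\n")
  cat("  human PCA: K =", x$pca$n_components, "components\n")
  cat("  consensus-selected:",
      if (length(x$selection$selected) > 0)
        paste(x$selection$selected, collapse = ", ") else "(none)", "\n")
  if (x$model$status == "ok") {
    cat("  final model LOO-RMSE:", signif(x$model$loo_rmse, 4), "\n")
  } else {
    cat("  final model:", x$model$status, "\n")
  }
  cat("  translatable (all criteria):",
      if (length(x$translatable) > 0)
        paste(x$translatable, collapse = ", ") else "(none)", "\n")
  invisible(x)
}
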