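#' Number of principal components to retain
#'
#' Applies the more restrictive of two criteria to a vector of explained
#' variance fractions: (1) the smallest number of leading components that
#' cumulatively explain at least `var_cum` of the total variance, and (2) the
#' number of components that each individually explain at least `var_each`.
#'
#' @param fractions Numeric vector of explained-variance fractions, in
#'   decreasing component order.
#' @param var_cum Cumulative-variance threshold (default 0.95).
#' @param var_each Individual-variance threshold (default 0.01).
#' @return Integer K, the retained component count.
#' @examples
#' retain_components(c(0.50, 0.30, 0.15, 0.04, 0.01))  # 3
#' retain_components(c(0.96, 0.02, 0.02))              # 1
#' @export
retain_components <- function(fractions, var_cum = 0.95, var_each = 0.01) {
  hit <- which(cumsum(fractions) >= var_cum - 1e-12)
  k_cum <- if (length(hit) > 0) hit[1] else length(fractions)
  k_each <- sum(fractions >= var_each - 1e-12)
  k <- min(k_cum, k_each)
  if (k < 1) stop("retention error: no component satisfies the retention rule",
                  call. = FALSE)
  as.integer(k)
}

#' Fit a principal component space on a z-scored study
#'
#' Singular-value decomposition of the sample configuration (samples as
#' observations, genes as variables; per-gene z-scoring has already centered
#' each variable). The retained component count K follows
#' [retain_components()] applied to the full decomposition's
#' explained-variance fractions. For determinism each loading column is
#' sign-flipped so its largest-magnitude entry is positive.
#'
#' @param study A z-scored [expression_study()] with >= 2 genes and >= 3
#'   samples.
#' @param var_cum,var_each Retention thresholds, see [retain_components()].
#' @return A `pca_space` object: `gene_order`, `loadings` (genes x K,
#'   orthonormal columns), `explained_fraction` (length K),
#'   `all_fractions` (full decomposition), `sample_scores` (samples x K),
#'   `n_components`, `species`.
#' @export
fit_pca <- function(study, var_cum = 0.95, var_each = 0.01) {
  vals <- study$values
  if (nrow(vals) < 2 || ncol(vals) < 3) {
    stop("need >= 2 genes and >= 3 samples for PCA", call. = FALSE)
  }
  X <- t(vals)                               # samples x genes
  sv <- svd(X)
  fractions <- sv$d^2 / sum(sv$d^2)
  k <- retain_components(fractions, var_cum, var_each)
  V <- sv$v[, seq_len(k), drop = FALSE]
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k, k)
  # deterministic sign: largest-|loading| entry positive per column
  for (j in seq_len(k)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) {
      V[, j] <- -V[, j]
      scores[, j] <- -scores[, j]
    }
  }
  comp <- paste0("PC", seq_len(k))
  dimnames(V) <- list(rownames(vals), comp)
  dimnames(scores) <- list(colnames(vals), comp)
  structure(
    list(
      gene_order = rownames(vals),
      loadings = V,
      explained_fraction = fractions[seq_len(k)],
      all_fractions = fractions,
      sample_scores = scores,
      n_components = k,
      species = study$species,
      metadata = study$metadata
    ),
    class = "pca_space"
  )
}

#' @export
print.pca_space <- function(x, ...) {
  cat("<pca_space> ", length(x$gene_order), " genes, ",
      nrow(x$sample_scores), " samples, K = ", x$n_components,
      " (", round(100 * sum(x$explained_fraction), 1), "% variance)\n", sep = "")
  invisible(x)
}

#' Relate component scores to sample phenotypes
#'
#' For each retained component, fits `score ~ intercept + age + sex + disease`
#' on the training samples and reports per-term t-values and sequential ANOVA
#' p-values. A binary disease enters as a 0/1 covariate (t-value reported);
#' a multi-level categorical disease enters treatment-coded and its
#' association is the omnibus ANOVA p (no single t-value).
#'
#' @param model A `pca_space`.
#' @param metadata Per-sample metadata (defaults to the metadata stored in
#'   the model); must cover age, sex and disease for all scored samples.
#' @return A `phenotype_association` tibble with columns `component`, `term`,
#'   `statistic` (t-value; `NA` for multi-df terms), `p.value` (ANOVA p).
#' @export
phenotype_regression <- function(model, metadata = model$metadata) {
  md <- metadata[match(rownames(model$sample_scores), metadata$sample_id), ]
  if (anyNA(md$sample_id)) stop("metadata does not cover all scored samples", call. = FALSE)
  disease <- .disease_term(md)
  sex <- .binary_sex(md$sex)
  purrr::map_dfr(seq_len(model$n_components), function(j) {
    df <- data.frame(score = model$sample_scores[, j], age = md$age,
                     sex = sex, disease = disease)
    fit <- stats::lm(score ~ age + sex + disease, data = df)
    if (qr(stats::model.matrix(fit))$rank < ncol(stats::model.matrix(fit))) {
      stop("model error: phenotype design rank-deficient", call. = FALSE)
    }
    an <- stats::anova(fit)
    coefs <- summary(fit)$coefficients
    terms_ <- c("age", "sex", "disease")
    tval <- vapply(terms_, function(tm) {
      rows <- grep(paste0("^", tm), rownames(coefs))
      if (length(rows) == 1) coefs[rows, "t value"] else NA_real_
    }, numeric(1))
    tibble::tibble(
      component = colnames(model$sample_scores)[j],
      term = terms_,
      statistic = unname(tval),
      p.value = an[terms_, "Pr(>F)"]
    )
  }) -> out
  class(out) <- c("phenotype_association", class(out))
  out
}

.disease_term <- function(md) {
  code <- md[["disease_code"]]
  if (!is.null(code) && !all(is.na(code)) && length(unique(code)) == 2) {
    return(as.integer(code == max(code)))
  }
  lev <- sort(unique(md$disease_label))
  if (length(lev) == 2) as.integer(md$disease_label == lev[2]) else factor(md$disease_label)
}

#' Project another species' samples into a fitted component space
#'
#' Rows of the (independently z-scored) projecting study are re-ordered to
#' the model's gene order through the one-to-one homolog map, and scores are
#' the matrix product of the sample profiles with the model loadings. The
#' per-component projected-variance fraction is the share of the total
#' squared score mass, over the retained components, falling on each
#' component.
#'
#' @param model A `pca_space` fitted on one species.
#' @param study A z-scored [expression_study()] from the other species (or
#'   the same species, e.g. for the self-projection identity).
#' @param map Optional `homolog_map`; omit when the two studies share gene
#'   identifiers. Every model gene must have a one-to-one partner present in
#'   `study`.
#' @return A `projected_scores` object: `scores` (samples x K),
#'   `projected_fraction` (length K, sums to 1), `component` names.
#' @export
project_into <- function(model, study, map = NULL) {
  if (is.null(map)) {
    partner <- stats::setNames(model$gene_order, model$gene_order)
  } else {
    map <- one_to_one_pairs(map)
    if (model$species == "human") {
      partner <- stats::setNames(map$mouse_gene, map$human_gene)
    } else {
      partner <- stats::setNames(map$human_gene, map$mouse_gene)
    }
    missing_pairs <- setdiff(model$gene_order, names(partner))
    if (length(missing_pairs) > 0) {
      stop("projection error: model gene(s) without homolog pair: ",
           paste(utils::head(missing_pairs, 5), collapse = ", "),
           if (length(missing_pairs) > 5) ", ...", call. = FALSE)
    }
    partner <- partner[model$gene_order]
  }
  absent <- setdiff(unname(partner), rownames(study$values))
  if (length(absent) > 0) {
    stop("projection error: partner gene(s) absent from projecting study: ",
         paste(utils::head(absent, 5), collapse = ", "),
         if (length(absent) > 5) ", ...", call. = FALSE)
  }
  Y <- study$values[unname(partner), , drop = FALSE]   # model gene order
  scores <- t(Y) %*% model$loadings
  ss <- colSums(scores^2)
  structure(
    list(
      scores = scores,
      projected_fraction = ss / sum(ss),
      component = colnames(model$loadings),
      metadata = study$metadata
    ),
    class = "projected_scores"
  )
}

#' @export
print.projected_scores <- function(x, ...) {
  cat("<projected_scores> ", nrow(x$scores), " samples x ",
      ncol(x$scores), " components\n", sep = "")
  invisible(x)
}

.score_matrix <- function(scores) {
  if (inherits(scores, "projected_scores")) scores$scores
  else if (inherits(scores, "pca_space")) scores$sample_scores
  else as.matrix(scores)
}
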