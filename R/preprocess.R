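#' Z-score each gene across a study's samples
#'
#' Internal normalization applied per study before PCA or projection: every
#' gene row is centered to mean 0 and scaled to sample standard deviation 1
#' across that study's samples. Zero-variance genes cannot be scaled and are
#' dropped with a message.
#'
#' @param study An [expression_study()] with at least two samples.
#' @return The z-scored [expression_study()].
#' @export
zscore_genes <- function(study) {
  if (ncol(study$values) < 2) stop("need >= 2 samples to z-score", call. = FALSE)
  sds <- apply(study$values, 1, stats::sd)
  keep <- sds > 0
  if (!any(keep)) stop("input error: all genes have zero variance", call. = FALSE)
  if (sum(!keep) > 0) {
    message("zscore_genes: dropping ", sum(!keep), " zero-variance gene(s)")
  }
  vals <- study$values[keep, , drop = FALSE]
  vals <- (vals - rowMeans(vals)) / sds[keep]
  expression_study(vals, study$metadata, study$species)
}

#' Permissive differential-expression gene selection
#'
#' Fits, per gene, an ordinary least-squares model
#' `expression ~ intercept + age + sex + disease` and tests the disease
#' coefficient with a two-sided t-test. P-values are Benjamini-Hochberg
#' adjusted across all genes and genes with adjusted p below `alpha`
#' (default 0.20, deliberately permissive) are selected. An optional `cap`
#' trims the selection to the `cap` smallest adjusted p-values (ties broken
#' by raw p, then gene id).
#'
#' @param study An [expression_study()] on the unstandardized (pre z-score)
#'   scale.
#' @param alpha BH-adjusted p-value threshold (default 0.20).
#' @param cap Optional integer cap on the number of selected genes.
#' @param disease Optional 0/1 vector overriding the disease encoding; by
#'   default `disease_code` is used when present, otherwise the two levels of
#'   `disease_label` are coded 0/1 in sorted order.
#' @return A `deg_result` tibble with columns `gene`, `estimate` (disease
#'   coefficient), `statistic`, `p.value`, `adj.p.value`, `selected`, and a
#'   `cap` attribute.
#' @export
select_degs <- function(study, alpha = 0.20, cap = NULL, disease = NULL) {
  md <- study$metadata
  if (is.null(disease)) disease <- .binary_disease(md)
  sex <- .binary_sex(md$sex)
  X <- cbind(`(Intercept)` = 1, age = md$age, sex = sex, disease = disease)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("model error: design matrix rank-deficient; offending column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  Y <- t(study$values)                      # samples x genes
  B <- qr.coef(qrX, Y)                      # coefficients x genes
  res <- Y - X %*% B
  n <- nrow(X); p <- ncol(X)
  rss <- colSums(res^2)
  sigma2 <- rss / (n - p)
  xtx_inv <- chol2inv(qr.R(qrX))
  se_d <- sqrt(sigma2 * xtx_inv[4, 4])
  est <- B["disease", ]
  tval <- est / se_d
  pval <- 2 * stats::pt(-abs(tval), df = n - p)
  padj <- stats::p.adjust(pval, method = "BH")
  out <- tibble::tibble(
    gene = rownames(study$values),
    estimate = unname(est),
    statistic = unname(tval),
    p.value = unname(pval),
    adj.p.value = unname(padj),
    # alpha = 1 disables filtering (adjusted p can equal 1 exactly)
    selected = if (alpha >= 1) rep(TRUE, length(padj)) else unname(padj < alpha)
  )
  if (!is.null(cap) && sum(out$selected) > cap) {
    ord <- order(out$adj.p.value, out$p.value, out$gene)
    ranked <- ord[out$selected[ord]][seq_len(cap)]
    out$selected <- FALSE
    out$selected[ranked] <- TRUE
  }
  attr(out, "cap") <- cap
  class(out) <- c("deg_result", class(out))
  out
}

.binary_disease <- function(md) {
  if (!is.null(md[["disease_code"]]) && !all(is.na(md[["disease_code"]]))) {
    code <- md[["disease_code"]]
    if (length(unique(code)) != 2) {
      stop("disease must be binary for DEG selection; got codes: ",
           paste(sort(unique(code)), collapse = ", "), call. = FALSE)
    }
    return(as.integer(code == max(code)))
  }
  lev <- sort(unique(md$disease_label))
  if (length(lev) != 2) {
    stop("disease must be binary for DEG selection; got labels: ",
         paste(lev, collapse = ", "), call. = FALSE)
  }
  as.integer(md$disease_label == lev[2])
}

.binary_sex <- function(sex) {
  lev <- sort(unique(as.character(sex)))
  if (length(lev) > 2) stop("sex must be two-level", call. = FALSE)
  as.integer(as.character(sex) == lev[length(lev)])
}

#' Restrict a study to genes with one-to-one cross-species homologs
#'
#' Keeps only genes present in the one-to-one portion of the homolog map (in
#' the study's own row order) and records each gene's partner identifier so
#' the other species' matrix can later be row-aligned.
#'
#' @param study An [expression_study()].
#' @param map A `homolog_map`; only its one-to-one pairs are used.
#' @return The filtered [expression_study()] with a `partner` attribute: a
#'   named character vector mapping each retained gene to its homolog.
#' @export
homolog_filter <- function(study, map) {
  map <- one_to_one_pairs(map)
  own <- if (study$species == "human") map$human_gene else map$mouse_gene
  other <- if (study$species == "human") map$mouse_gene else map$human_gene
  partner <- stats::setNames(other, own)
  keep <- rownames(study$values) %in% own
  if (!any(keep)) stop("input error: no genes overlap the homolog map", call. = FALSE)
  out <- expression_study(study$values[keep, , drop = FALSE],
                          study$metadata, study$species)
  attr(out, "partner") <- partner[rownames(out$values)]
  out
}

#' Encode mouse disease status as a numeric dose
#'
#' Wild-type controls are coded 0, heterozygous disease-model animals 1 and
#' homozygous animals 2, so genotype dose enters downstream regressions as a
#' single numeric response.
#'
#' @param metadata Data frame with a `disease_label` column (or a character
#'   vector of labels).
#' @param label_map Named integer vector mapping labels to codes; default
#'   `c(WT = 0, HET = 1, HO = 2)`.
#' @return Integer vector of codes, one per sample.
#' @export
encode_phenotype <- function(metadata, label_map = c(WT = 0L, HET = 1L, HO = 2L)) {
  labels <- if (is.data.frame(metadata)) metadata$disease_label else as.character(metadata)
  unknown <- setdiff(unique(labels), names(label_map))
  if (length(unknown) > 0) {
    stop("unknown disease label(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  unname(as.integer(label_map[labels]))
}
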