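#' Nested F-test separating disease information from age
#'
#' For one component's sample scores, compares a null linear model with age
#' (as a factor) alone against an alternative adding disease (as a factor):
#'
#' \deqn{F = \frac{(RSS_{null} - RSS_{alt}) / (p_{alt} - p_{null})}
#'            {RSS_{alt} / (N - p_{alt} - 1)}}
#'
#' where each p counts the model's non-intercept degrees of freedom. A small
#' p-value means disease explains score variation beyond what age accounts
#' for — the component carries disease information distinct from aging.
#'
#' @param score Numeric vector of one component's sample scores.
#' @param age Age per sample, coerced to a factor (e.g. 2/4/8/18 months).
#' @param disease Disease status per sample, coerced to a factor (e.g.
#'   genotype dose 0/1/2).
#' @param threshold Pass threshold on the F-test p-value (default 0.01).
#' @return A one-row `age_decoupling` tibble: `rss_null`, `rss_alt`,
#'   `df_null`, `df_alt`, `n`, `statistic`, `p.value`, `pass`.
#' @export
age_disease_ftest <- function(score, age, disease, threshold = 0.01) {
  score <- as.numeric(score)
  age <- factor(age)
  disease <- factor(disease)
  n <- length(score)
  stopifnot(length(age) == n, length(disease) == n)
  if (nlevels(age) < 2) stop("need >= 2 age levels", call. = FALSE)
  if (nlevels(disease) < 2) stop("need >= 2 disease levels", call. = FALSE)
  X_null <- stats::model.matrix(~ age)
  X_alt <- stats::model.matrix(~ age + disease)
  if (qr(X_alt)$rank < ncol(X_alt)) {
    qa <- qr(X_alt)
    aliased <- colnames(X_alt)[qa$pivot[(qa$rank + 1):ncol(X_alt)]]
    stop("model error: age and disease confounded; aliased column(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  p_null <- ncol(X_null) - 1L
  p_alt <- ncol(X_alt) - 1L
  if (n <= p_alt + 1) stop("need N > p_alt + 1 samples", call. = FALSE)
  rss_null <- sum(stats::lm.fit(X_null, score)$residuals^2)
  rss_alt <- sum(stats::lm.fit(X_alt, score)$residuals^2)
  delta <- rss_null - rss_alt
  # an improvement at the level of floating-point cancellation is no
  # improvement: both models fit equally well and F is zero by convention
  if (delta <= 1e-10 * (sum(score^2) + .Machine$double.xmin)) {
    f <- 0
  } else {
    f <- (delta / (p_alt - p_null)) / (rss_alt / (n - p_alt - 1))
  }
  p <- stats::pf(f, p_alt - p_null, n - p_alt - 1, lower.tail = FALSE)
  out <- tibble::tibble(
    rss_null = rss_null, rss_alt = rss_alt,
    df_null = p_null, df_alt = p_alt, n = n,
    statistic = f, p.value = p, pass = p < threshold
  )
  class(out) <- c("age_decoupling", class(out))
  out
}

#' Age-decoupling F-tests over all components
#'
#' Applies [age_disease_ftest()] to each column of a score matrix.
#'
#' @param scores A `projected_scores` object or samples x components matrix.
#' @param age,disease Per-sample age and disease factors; default to the
#'   metadata carried by a `projected_scores` object (`age` column and
#'   `disease_code` / `disease_label`).
#' @param threshold Pass threshold (default 0.01).
#' @return An `age_decoupling` tibble with one row per component (leading
#'   `component` column).
#' @export
age_decoupling <- function(scores, age = NULL, disease = NULL, threshold = 0.01) {
  X <- .score_matrix(scores)
  if (is.null(age) || is.null(disease)) {
    md <- scores$metadata
    if (is.null(md)) stop("supply age and disease or use projected_scores", call. = FALSE)
    if (is.null(age)) age <- md$age
    if (is.null(disease)) {
      disease <- if (!is.null(md[["disease_code"]])) md[["disease_code"]] else md$disease_label
    }
  }
  comp <- colnames(X)
  if (is.null(comp)) comp <- paste0("PC", seq_len(ncol(X)))
  out <- purrr::map_dfr(seq_len(ncol(X)), function(j) {
    res <- age_disease_ftest(X[, j], age, disease, threshold)
    dplyr::bind_cols(tibble::tibble(component = comp[j]), res)
  })
  class(out) <- c("age_decoupling", class(out))
  out
}
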