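# in-code fixtures shared across test files

toy_metadata <- function(ids, age = NULL, sex = NULL, disease = NULL,
                         code = NULL) {
  n <- length(ids)
  tibble::tibble(
    sample_id = ids,
    age = if (is.null(age)) seq(60, 60 + n - 1) else age,
    sex = if (is.null(sex)) rep_len(c("M", "F"), n) else sex,
    disease_label = if (is.null(disease)) rep_len(c("control", "AD"), n) else disease,
    disease_code = code
  )
}

toy_study <- function(values, species = "human", ...) {
  ids <- colnames(values)
  expression_study(values, toy_metadata(ids, ...), species)
}

random_study <- function(n_genes, n_samples, species = "human", seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  vals <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples,
                 dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                 sprintf("s%03d", seq_len(n_samples))))
  toy_study(vals, species = species, ...)
}

# independent step-up BH oracle (sort, p*m/rank, enforce monotonicity)
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# exact hypergeometric upper-tail oracle via explicit choose() sums
hyper_tail_oracle <- function(overlap, set_in_model, model_size, tail_size) {
  jmax <- min(set_in_model, tail_size)
  if (overlap > jmax) return(0)
  sum(vapply(overlap:jmax, function(j) {
    choose(set_in_model, j) * choose(model_size - set_in_model, tail_size - j)
  }, numeric(1))) / choose(model_size, tail_size)
}

# a minimal pca_space built directly from a loading matrix (for ORA tests)
fake_pca <- function(loadings) {
  structure(
    list(gene_order = rownames(loadings), loadings = loadings,
         explained_fraction = rep(1 / ncol(loadings), ncol(loadings)),
         all_fractions = rep(1 / ncol(loadings), ncol(loadings)),
         sample_scores = matrix(0, 2, ncol(loadings),
                                dimnames = list(c("a", "b"), colnames(loadings))),
         n_components = ncol(loadings), species = "human", metadata = NULL),
    class = "pca_space"
  )
}

# small synthetic bundle for cheap end-to-end tests
small_bundle <- function(seed, ...) {
  simulate_cross_species(n_genes = 400, n_human_per_class = 15,
                         n_mouse_per_group = 4, planted_size = 80,
                         n_age_genes = 100, n_sex_genes = 40,
                         n_decoy_sets = 5, seed = seed, ...)
}
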