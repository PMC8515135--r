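test_that("retention rule takes the more restrictive criterion and can fail", {
  expect_identical(retain_components(c(0.50, 0.30, 0.15, 0.04, 0.01)), 3L)
  expect_identical(retain_components(c(0.96, 0.02, 0.02)), 1L)
  # cumulative never reached: fall back to all, then restrict by var_each
  expect_identical(retain_components(c(0.5, 0.3, 0.2), var_cum = 0.99), 3L)
  expect_error(retain_components(c(0.005, rep(0.005, 10)), var_each = 0.01),
               "retention error")
})

test_that("fitted loadings are orthonormal with a deterministic sign", {
  st <- zscore_genes(random_study(50, 10, seed = 21))
  m <- fit_pca(st)
  gram <- crossprod(m$loadings)
  expect_equal(gram, diag(ncol(m$loadings)), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(diff(m$explained_fraction) <= 1e-12))
  expect_equal(sum(m$all_fractions), 1, tolerance = 1e-12)
  for (j in seq_len(m$n_components)) {
    i <- which.max(abs(m$loadings[, j]))
    expect_gt(m$loadings[i, j], 0)
  }
})

test_that("self-projection returns the training scores and reconstruction matches", {
  st <- zscore_genes(random_study(80, 12, seed = 22))
  m <- fit_pca(st)
  proj <- project_into(m, st)
  expect_equal(proj$scores, m$sample_scores, tolerance = 1e-8)

  X <- t(st$values)
  R <- m$sample_scores %*% t(m$loadings)
  rel_err <- sum((X - R)^2) / sum(X^2)
  expect_equal(rel_err, 1 - sum(m$explained_fraction), tolerance = 1e-6)
})

test_that("projection equals an explicit triple-loop matrix product", {
  st <- zscore_genes(random_study(200, 20, seed = 23))
  m <- fit_pca(st)
  mouse <- zscore_genes(random_study(200, 12, species = "mouse", seed = 24))
  proj <- project_into(m, mouse)
  K <- m$n_components
  oracle <- matrix(0, 12, K)
  Y <- mouse$values[m$gene_order, ]
  for (s in 1:12) for (k in seq_len(K)) {
    acc <- 0
    for (g in seq_along(m$gene_order)) acc <- acc + Y[g, s] * m$loadings[g, k]
    oracle[s, k] <- acc
  }
  expect_equal(unname(proj$scores), oracle, tolerance = 1e-10)
  expect_equal(sum(proj$projected_fraction), 1, tolerance = 1e-12)
})

test_that("projected variance fractions ignore mouse sample order", {
  st <- zscore_genes(random_study(60, 10, seed = 25))
  m <- fit_pca(st)
  mouse <- zscore_genes(random_study(60, 8, species = "mouse", seed = 26))
  p1 <- project_into(m, mouse)
  set.seed(27)
  perm <- sample(ncol(mouse$values))
  mouse2 <- expression_study(mouse$values[, perm], mouse$metadata, "mouse")
  p2 <- project_into(m, mouse2)
  expect_equal(p1$projected_fraction, p2$projected_fraction, tolerance = 1e-12)
})

test_that("a profile equal to one loading column projects onto that component only", {
  st <- zscore_genes(random_study(40, 8, seed = 28))
  m <- fit_pca(st)
  prof <- m$loadings[, 2]
  vals <- matrix(prof, nrow = length(prof), ncol = 3,
                 dimnames = list(m$gene_order, paste0("mm", 1:3)))
  mouse <- toy_study(vals, species = "mouse")
  proj <- project_into(m, mouse)
  expect_equal(unname(proj$projected_fraction[2]), 1, tolerance = 1e-10)
  expect_equal(sum(proj$projected_fraction[-2]), 0, tolerance = 1e-10)
})

test_that("projection through a homolog map aligns rows to the model gene order", {
  b <- simulate_cross_species(n_genes = 120, n_human_per_class = 6,
                              n_mouse_per_group = 2, planted_size = 30,
                              n_age_genes = 40, n_sex_genes = 10,
                              shuffled_map = TRUE, seed = 31)
  hz <- zscore_genes(b$human); mz <- zscore_genes(b$mouse)
  m <- fit_pca(hz)
  proj <- project_into(m, mz, b$map)
  # manual alignment: reorder mouse rows by the map, then plain product
  partner <- setNames(b$map$mouse_gene, b$map$human_gene)
  Y <- mz$values[partner[m$gene_order], ]
  expect_equal(unname(proj$scores), unname(t(Y) %*% m$loadings),
               tolerance = 1e-12)
  # missing partner genes are reported
  mz_small <- keep_genes(mz, rownames(mz$values)[-1])
  expect_error(project_into(m, mz_small, b$map), "projection error")
})

test_that("phenotype regression finds planted terms and matches a hand OLS oracle", {
  st <- zscore_genes(random_study(60, 24, seed = 32,
                                  sex = rep(c("M", "M", "F", "F"), 6),
                                  disease = rep(c("control", "AD"), 12)))
  m <- fit_pca(st)
  # plant: overwrite first component's scores with the age vector
  m$sample_scores[, 1] <- st$metadata$age + rnorm(24, 0, 1e-6)
  assoc <- phenotype_regression(m)
  a1 <- assoc[assoc$component == "PC1", ]
  expect_lt(a1$p.value[a1$term == "age"], 1e-10)
  expect_gt(a1$p.value[a1$term == "disease"], 0.01)

  # consistent permutation of scores and metadata leaves statistics unchanged
  set.seed(33)
  perm <- sample(24)
  m2 <- m
  m2$sample_scores <- m$sample_scores[perm, ]
  m2$metadata <- m$metadata[perm, ]
  expect_equal(phenotype_regression(m2)$statistic, assoc$statistic,
               tolerance = 1e-8)

  # 8-sample case against explicit normal equations
  set.seed(34)
  md8 <- toy_metadata(sprintf("s%03d", 1:8),
                      age = c(61, 63, 70, 72, 75, 78, 80, 85),
                      sex = rep(c("M", "F"), 4),
                      disease = rep(c("control", "AD"), each = 4))
  vals8 <- matrix(rnorm(160), 20, 8,
                  dimnames = list(sprintf("g%03d", 1:20), md8$sample_id))
  st8 <- zscore_genes(expression_study(vals8, md8, "human"))
  m8 <- fit_pca(st8)
  assoc8 <- phenotype_regression(m8)
  X <- cbind(1, md8$age, as.integer(md8$sex == "M"),
             as.integer(md8$disease_label == "control"))
  # treatment coding sorts levels: AD = reference, control = 1
  for (j in seq_len(min(2, m8$n_components))) {
    y <- m8$sample_scores[, j]
    beta <- solve(t(X) %*% X, t(X) %*% y)
    res <- y - X %*% beta
    s2 <- sum(res^2) / (8 - 4)
    se <- sqrt(diag(s2 * solve(t(X) %*% X)))
    tvals <- beta / se
    got <- assoc8[assoc8$component == paste0("PC", j), ]
    expect_equal(got$statistic[got$term == "age"], tvals[2], tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(abs(got$statistic[got$term == "disease"]), abs(tvals[4]),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})
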