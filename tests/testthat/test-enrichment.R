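test_that("loading-tail ORA reproduces exact hypergeometric probabilities", {
  # G = 10, top tail of 2 holds 2 of a 4-gene set: p = C(4,2)/C(10,2) = 6/45
  genes <- sprintf("g%02d", 1:10)
  load <- matrix(seq(10, 1), ncol = 1, dimnames = list(genes, "PC1"))
  m <- fake_pca(load)
  sets <- gene_set_collection(list(S = c("g01", "g02", "g03", "g04")))
  res <- ora_tails(m, "PC1", sets, tail_frac = 0.2)
  top <- res[res$tail == "top", ]
  expect_identical(top$overlap, 2L)
  expect_equal(top$p.value, 6 / 45, tolerance = 1e-12)
  expect_equal(top$p.value,
               hyper_tail_oracle(2, 4, 10, 2), tolerance = 1e-12)

  # set identical to the tail: minimal p = 1 / C(G, tail)
  sets2 <- gene_set_collection(list(T2 = c("g01", "g02")))
  res2 <- ora_tails(m, "PC1", sets2, tail_frac = 0.2)
  expect_equal(res2$p.value[res2$tail == "top"], 1 / choose(10, 2),
               tolerance = 1e-12)
})

test_that("ORA is invariant to gene-order permutation and BH is monotone", {
  set.seed(71)
  genes <- sprintf("g%02d", 1:30)
  load <- matrix(rnorm(30), ncol = 1, dimnames = list(genes, "PC1"))
  sets <- gene_set_collection(
    setNames(lapply(1:6, function(i) sample(genes, 8)), paste0("s", 1:6)))
  m1 <- fake_pca(load)
  perm <- sample(30)
  m2 <- fake_pca(load[perm, , drop = FALSE])
  r1 <- ora_tails(m1, "PC1", sets)
  r2 <- ora_tails(m2, "PC1", sets)
  key <- function(r) r[order(r$tail, r$set), c("overlap", "p.value", "fdr")]
  expect_equal(key(r1), key(r2), tolerance = 1e-12)

  for (tl in c("top", "bottom")) {
    fam <- r1[r1$tail == tl, ]
    ord <- order(fam$p.value)
    expect_true(all(diff(fam$fdr[ord]) >= -1e-12))
    expect_equal(fam$fdr, bh_oracle(fam$p.value), tolerance = 1e-12)
    expect_true(all(fam$fdr >= fam$p.value - 1e-12))
  }
})

test_that("contributing genes and set-in-model accounting respect the model universe", {
  genes <- sprintf("g%02d", 1:10)
  load <- matrix(10:1, ncol = 1, dimnames = list(genes, "PC1"))
  m <- fake_pca(load)
  sets <- gene_set_collection(list(S = c("g01", "g09", "offmodel1", "offmodel2")))
  res <- ora_tails(m, "PC1", sets, tail_frac = 0.2)
  top <- res[res$tail == "top", ]
  expect_identical(top$set_in_model, 2L)   # off-model members excluded
  expect_identical(top$genes[[1]], "g01")
  bottom <- res[res$tail == "bottom", ]
  expect_identical(bottom$genes[[1]], "g09")
  # a set with no genes in the model is skipped with a message
  sets2 <- gene_set_collection(list(S = "g01", empty = c("x1", "x2")))
  expect_message(res2 <- ora_tails(m, "PC1", sets2), "skipped")
  expect_false("empty" %in% res2$set)
})

test_that("planted set enriches only in the matching loading tail", {
  b <- small_bundle(seed = 72)
  hz <- zscore_genes(b$human)
  m <- fit_pca(hz)
  al <- axis_alignment(m, b$truth)
  ald <- al[al$axis == "disease", ]
  comp <- ald$component[which.max(ald$cosine)]
  res <- ora_tails(m, comp, b$sets)
  planted <- res[res$set == "planted", ]
  expect_lt(planted$fdr[planted$tail == "top"], 0.05)
  expect_gt(planted$fdr[planted$tail == "bottom"], 0.05)
})

test_that("pooled t statistic matches hand arithmetic on a 4+4 toy case", {
  x <- c(1, 2, 3, 4); y <- c(3, 4, 5, 6)
  vals <- rbind(g1 = c(x, y, 5, 6))
  colnames(vals) <- sprintf("m%02d", 1:10)
  md <- tibble::tibble(sample_id = colnames(vals),
                       age = rep(4, 10), sex = rep("M", 10),
                       disease_label = c(rep("WT", 4), rep("HET", 4), "HO", "HO"))
  st <- expression_study(vals, md, "mouse")
  res <- gene_level_tests(st, genes = "g1")
  sp2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / 6
  t_hand <- (mean(y) - mean(x)) / sqrt(sp2 * (1 / 4 + 1 / 4))
  got <- res[res$comparison == "HET_vs_WT", ]
  expect_equal(got$statistic, t_hand, tolerance = 1e-10)
  # identical distributions are not significant
  expect_false(any(res$significant))
})

test_that("a shift planted in homozygotes separates the vs-WT comparisons", {
  ho_hits <- 0L; het_hits <- 0L
  for (s in 1:20) {
    set.seed(700 + s)
    n <- 6
    vals <- rbind(g1 = c(rnorm(n), rnorm(n), rnorm(n, mean = 2)))
    colnames(vals) <- sprintf("m%02d", 1:(3 * n))
    md <- tibble::tibble(sample_id = colnames(vals), age = 8, sex = "F",
                         disease_label = rep(c("WT", "HET", "HO"), each = n))
    st <- expression_study(vals, md, "mouse")
    res <- gene_level_tests(st, genes = "g1")
    if (res$fdr[res$comparison == "HO_vs_WT"] < 0.05) ho_hits <- ho_hits + 1L
    if (res$fdr[res$comparison == "HET_vs_WT"] < 0.05) het_hits <- het_hits + 1L
  }
  expect_gte(ho_hits, 12L)
  expect_lte(het_hits, 4L)
})

test_that("secreted filtering keeps only annotated secreted significant genes", {
  res <- tibble::tibble(
    gene = rep(c("C3", "TUB", "LGALS3"), each = 2),
    comparison = rep(c("HET_vs_WT", "HO_vs_WT"), 3),
    statistic = 0, p.value = 1,
    fdr = c(0.01, 0.5, 0.01, 0.2, 0.04, 0.9),
    significant = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE)
  )
  annot <- tibble::tibble(gene = c("C3", "TUB"),
                          secreted = c(TRUE, FALSE), notes = "")
  expect_message(out <- secreted_filter(res, annot), "not covered")
  expect_identical(out, "C3")

  res_none <- dplyr::mutate(res, significant = FALSE)
  expect_identical(secreted_filter(res_none, annot), character(0))
})
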