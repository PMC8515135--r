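test_that("expression round-trip through TSV preserves values exactly", {
  st <- random_study(7, 4, seed = 11)
  f <- withr::local_tempfile(fileext = ".tsv")
  m <- withr::local_tempfile(fileext = ".tsv")
  write_expression(st, f, m)
  back <- read_expression(f, m, species = "human")
  expect_identical(dim(back), c(7L, 4L))
  expect_identical(rownames(back$values), rownames(st$values))
  expect_equal(back$values, st$values, tolerance = 0)
  expect_equal(back$metadata$age, st$metadata$age)
})

test_that("malformed expression inputs are rejected", {
  f <- withr::local_tempfile(fileext = ".tsv")
  m <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts1", "g1\t1\t2", "g2\t3\t4"), f)
  writeLines(c("sample_id\tage\tsex\tdisease_label",
               "s1\t70\tM\tcontrol"), m)
  expect_error(read_expression(f, m), "duplicated sample")

  st <- random_study(3, 2, seed = 1)
  write_expression(st, f, m)
  writeLines(c("sample_id\tage\tsex\tdisease_label",
               "s001\t70\tM\tcontrol"), m)  # s002 missing
  expect_error(read_expression(f, m), "missing from metadata")

  md_bad <- toy_metadata(c("s001", "s002"))
  vals <- matrix(1:4, 2, 2, dimnames = list(c("g1", "g1"), c("s001", "s002")))
  expect_error(expression_study(vals, md_bad, "human"), "duplicated gene")
  vals2 <- matrix(c(1, NA, 3, 4), 2, 2,
                  dimnames = list(c("g1", "g2"), c("s001", "s002")))
  expect_error(expression_study(vals2, md_bad, "human"), "missing values")
})

test_that("collapse_probes takes per-sample medians over a gene's probes", {
  vals <- matrix(c(1, 3, 3, 5), 2, 2, byrow = FALSE,
                 dimnames = list(c("p1", "p2"), c("s1", "s2")))
  st <- toy_study(vals)
  out <- collapse_probes(st, c(p1 = "gA", p2 = "gA"))
  expect_equal(unname(out$values["gA", ]), c(2, 4))

  # single-probe genes pass through unchanged
  vals3 <- rbind(vals, p3 = c(9, 10))
  st3 <- toy_study(vals3)
  out3 <- collapse_probes(st3, c(p1 = "gA", p2 = "gA", p3 = "gB"))
  expect_equal(unname(out3$values["gB", ]), c(9, 10))

  # 5 probes -> 1 gene equals a naive sort-based median per column
  set.seed(42)
  v5 <- matrix(rnorm(15), 5, 3,
               dimnames = list(paste0("p", 1:5), paste0("s", 1:3)))
  st5 <- toy_study(v5)
  out5 <- collapse_probes(st5, setNames(rep("g", 5), paste0("p", 1:5)))
  naive_median <- function(x) { s <- sort(x); s[(length(s) + 1) / 2] }
  expect_equal(unname(out5$values["g", ]),
               unname(apply(v5, 2, naive_median)), tolerance = 1e-12)
})

test_that("collapse_probes drops unmapped probes and is idempotent", {
  st <- random_study(4, 2, seed = 2)
  map <- setNames(c("gA", "gA", "gB"), c("g001", "g002", "g003"))  # g004 unmapped
  expect_message(out <- collapse_probes(st, map), "1 unmapped")
  expect_identical(rownames(out$values), c("gA", "gB"))
  ident <- setNames(rownames(out$values), rownames(out$values))
  expect_equal(collapse_probes(out, ident)$values, out$values)
  expect_error(collapse_probes(st, c(zzz = "g")), "no probes map")
})

test_that("GMT parsing, validation and round-trip preserve memberships", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("S1\tdesc\tA\tB", "S2\tother\tC"), f)
  gs <- read_gmt(f)
  expect_setequal(gs[["S1"]], c("A", "B"))
  expect_identical(unname(attr(gs, "descriptions")["S1"]), "desc")

  writeLines(c("S1\tdesc\tA", "broken_line"), f)
  expect_error(read_gmt(f), "line 2")

  set.seed(3)
  sets <- gene_set_collection(
    setNames(lapply(1:68, function(i) sort(sample(LETTERS, 5))),
             sprintf("set%02d", 1:68)))
  write_gmt(sets, f)
  back <- read_gmt(f)
  expect_identical(names(back), names(sets))
  for (nm in names(sets)) expect_setequal(back[[nm]], sets[[nm]])

  expect_error(gene_set_collection(list(a = character(0))), "non-empty")
  expect_error(gene_set_collection(list("A")), "unique")
})

test_that("homolog map flags one-to-many pairs and restricts to a bijection", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("human\tmouse", "H1\tM1", "H2\tM2", "H2\tM3", "H4\tM4"), f)
  map <- read_homolog_map(f)
  expect_false(any(map$one_to_one[map$human_gene == "H2"]))
  expect_true(all(map$one_to_one[map$human_gene %in% c("H1", "H4")]))
  oo <- one_to_one_pairs(map)
  expect_false(anyDuplicated(oo$human_gene) > 0)
  expect_false(anyDuplicated(oo$mouse_gene) > 0)
})

test_that("annotation table reading validates keys and types", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tsecreted\tnotes", "C3\tTRUE\tcomplement", "TUB\tFALSE\t"), f)
  an <- read_annotation(f)
  expect_identical(an$gene, c("C3", "TUB"))
  expect_identical(an$secreted, c(TRUE, FALSE))
  writeLines(c("gene\tsecreted", "C3\tTRUE", "C3\tFALSE"), f)
  expect_error(read_annotation(f), "duplicated gene")
})
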