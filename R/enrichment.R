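#' Loading-tail over-representation analysis
#'
#' Tests whether each gene set is over-represented among the genes with the
#' most positive (top) and most negative (bottom) loadings on a component,
#' relative to the set's membership among all genes in the model. Each tail
#' holds `ceiling(tail_frac * G)` genes (ties at the boundary broken by gene
#' id for determinism); the test is the one-sided Fisher exact test
#' (hypergeometric upper tail) and p-values are Benjamini-Hochberg adjusted
#' across sets within each (component, tail) family. Sets with no gene in
#' the model are skipped with a message.
#'
#' @param model A `pca_space`.
#' @param component Component id (e.g. `"PC9"`) or index.
#' @param sets A `gene_set_collection`.
#' @param tail_frac Tail fraction of the loading vector (default 0.20).
#' @return An `ora_result` tibble: `component`, `tail`, `set`, `overlap`,
#'   `tail_size`, `set_in_model`, `model_size`, `p.value`, `fdr`, `genes`
#'   (list-column of contributing genes).
#' @export
ora_tails <- function(model, component, sets, tail_frac = 0.20) {
  if (is.numeric(component)) component <- colnames(model$loadings)[component]
  if (!component %in% colnames(model$loadings)) {
    stop("component not in retained set: ", component, call. = FALSE)
  }
  genes <- model$gene_order
  loading <- model$loadings[, component]
  g <- length(genes)
  t_size <- as.integer(ceiling(tail_frac * g - 1e-9))  # guard float round-up
  top <- genes[order(-loading, genes)][seq_len(t_size)]
  bottom <- genes[order(loading, genes)][seq_len(t_size)]
  tails <- list(top = top, bottom = bottom)
  out <- purrr::map_dfr(names(tails), function(tl) {
    tail_genes <- tails[[tl]]
    rows <- purrr::map_dfr(names(sets), function(nm) {
      in_model <- intersect(sets[[nm]], genes)
      if (length(in_model) == 0) {
        message("ora_tails: set '", nm, "' has no genes in model; skipped")
        return(NULL)
      }
      hit <- intersect(tail_genes, in_model)
      p <- stats::phyper(length(hit) - 1, length(in_model),
                         g - length(in_model), t_size, lower.tail = FALSE)
      tibble::tibble(
        component = component, tail = tl, set = nm,
        overlap = length(hit), tail_size = t_size,
        set_in_model = length(in_model), model_size = g,
        p.value = p, genes = list(sort(hit))
      )
    })
    if (nrow(rows) > 0) rows$fdr <- stats::p.adjust(rows$p.value, method = "BH")
    rows
  })
  out <- out[, c("component", "tail", "set", "overlap", "tail_size",
                 "set_in_model", "model_size", "p.value", "fdr", "genes")]
  class(out) <- c("ora_result", class(out))
  out
}

#' Gene-level group comparisons in the mouse study
#'
#' Two-sided two-sample t-tests (pooled variance by default) comparing
#' heterozygous and homozygous disease-model animals against wild-type
#' controls on a gene subset. P-values are BH-adjusted over the family of
#' all (gene x vs-WT comparison) tests; the HET-vs-HO comparison is computed
#' for reference but excluded from the family and from the significance
#' flag. A gene is significant when at least one vs-WT comparison has
#' FDR < `alpha`.
#'
#' @param mouse An [expression_study()] (typically z-scored) with mouse
#'   disease labels mappable to WT/HET/HO.
#' @param genes Character vector of genes to test (default: all genes).
#' @param label_map Named integer vector mapping labels to doses 0/1/2.
#' @param alpha FDR threshold for the significance flag (default 0.05).
#' @param var_equal Pooled-variance t-test when `TRUE` (default); Welch
#'   otherwise.
#' @return A `gene_level_result` tibble: `gene`, `comparison`, `statistic`,
#'   `p.value`, `fdr` (`NA` outside the vs-WT family), `significant` (per
#'   gene, same value on all its rows).
#' @export
gene_level_tests <- function(mouse, genes = NULL,
                             label_map = c(WT = 0L, HET = 1L, HO = 2L),
                             alpha = 0.05, var_equal = TRUE) {
  dose <- encode_phenotype(mouse$metadata, label_map)
  if (is.null(genes)) genes <- rownames(mouse$values)
  missing_g <- setdiff(genes, rownames(mouse$values))
  if (length(missing_g) > 0) {
    stop("gene(s) absent from study: ", paste(utils::head(missing_g, 5),
         collapse = ", "), call. = FALSE)
  }
  groups <- list(WT = which(dose == 0), HET = which(dose == 1),
                 HO = which(dose == 2))
  comparisons <- list(HET_vs_WT = c("HET", "WT"), HO_vs_WT = c("HO", "WT"),
                      HO_vs_HET = c("HO", "HET"))
  out <- purrr::map_dfr(genes, function(gn) {
    x <- mouse$values[gn, ]
    purrr::map_dfr(names(comparisons), function(cp) {
      gs <- comparisons[[cp]]
      a <- x[groups[[gs[1]]]]; b <- x[groups[[gs[2]]]]
      if (length(a) < 2 || length(b) < 2) {
        stop("group with < 2 samples in comparison ", cp, call. = FALSE)
      }
      tt <- stats::t.test(a, b, var.equal = var_equal)
      tibble::tibble(gene = gn, comparison = cp,
                     statistic = unname(tt$statistic), p.value = tt$p.value)
    })
  })
  family <- out$comparison %in% c("HET_vs_WT", "HO_vs_WT")
  out$fdr <- NA_real_
  out$fdr[family] <- stats::p.adjust(out$p.value[family], method = "BH")
  sig_by_gene <- tapply(out$fdr[family] < alpha, out$gene[family], any)
  out$significant <- unname(sig_by_gene[out$gene])
  class(out) <- c("gene_level_result", class(out))
  out
}

#' Filter significant genes to secreted factors
#'
#' Keeps the significant genes whose annotation marks them as encoding a
#' secreted protein — a proxy for therapeutically accessible receptor-ligand
#' interactions. Significant genes missing from the annotation table are
#' excluded with a message.
#'
#' @param result A `gene_level_result` from [gene_level_tests()].
#' @param annot Annotation tibble with columns `gene` and `secreted` (see
#'   [read_annotation()]).
#' @return Sorted character vector of secreted significant genes.
#' @export
secreted_filter <- function(result, annot) {
  sig <- unique(result$gene[result$significant])
  if (length(sig) == 0) return(character(0))
  uncovered <- setdiff(sig, annot$gene)
  if (length(uncovered) > 0) {
    message("secreted_filter: ", length(uncovered),
            " significant gene(s) not covered by annotation; excluded")
    sig <- setdiff(sig, uncovered)
  }
  secreted <- annot$gene[annot$secreted]
  sort(intersect(sig, secreted))
}
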