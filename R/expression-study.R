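#' Construct an expression study
#'
#' An `expression_study` bundles a log-scale gene-by-sample expression matrix
#' with per-sample metadata for one species. It is the container every
#' pipeline stage consumes: rows are genes (or probes, before collapsing),
#' columns are samples, and each sample carries age, sex and a disease label.
#'
#' @param values Numeric matrix, genes in rows, samples in columns. Row names
#'   are gene identifiers, column names sample identifiers.
#' @param metadata Data frame with one row per sample. Required columns:
#'   `sample_id`, `age` (numeric, study units), `sex` (`"M"`/`"F"`),
#'   `disease_label` (category string). Optional: `disease_code` (integer
#'   dose/severity encoding; may be absent for human studies, where labels are
#'   used instead).
#' @param species `"human"` or `"mouse"`.
#'
#' @return An object of class `expression_study`: a list with elements
#'   `values` (matrix), `metadata` (tibble, ordered as the matrix columns) and
#'   `species`.
#'
#' @details Invariants enforced: matrix dimensions match the identifier lists,
#' gene and sample identifiers are unique, every sample has a metadata record,
#' and the matrix holds no missing values. Gene identifiers are opaque
#' strings; matching everywhere in the package is exact and case-sensitive.
#'
#' @examples
#' m <- matrix(rnorm(6), 3, 2, dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' md <- tibble::tibble(sample_id = c("s1", "s2"), age = c(70, 80),
#'                      sex = c("M", "F"), disease_label = c("control", "AD"))
#' expression_study(m, md, "human")
#' @export
expression_study <- function(values, metadata, species = c("human", "mouse")) {
  species <- match.arg(species)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (genes x samples)", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must carry gene row names and sample column names", call. = FALSE)
  }
  metadata <- tibble::as_tibble(metadata)
  required <- c("sample_id", "age", "sex", "disease_label")
  missing_cols <- setdiff(required, names(metadata))
  if (length(missing_cols) > 0) {
    stop("metadata is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicated gene identifiers in expression matrix", call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicated sample identifiers in expression matrix", call. = FALSE)
  }
  if (anyNA(values)) {
    stop("expression matrix contains missing values", call. = FALSE)
  }
  absent <- setdiff(colnames(values), metadata$sample_id)
  if (length(absent) > 0) {
    stop("sample(s) in matrix absent from metadata: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  if (anyNA(metadata$age) || anyNA(metadata$sex) || anyNA(metadata$disease_label)) {
    stop("metadata has missing age, sex or disease_label entries", call. = FALSE)
  }
  # order metadata as the matrix columns so positional access is safe
  metadata <- metadata[match(colnames(values), metadata$sample_id), , drop = FALSE]
  structure(
    list(values = values, metadata = metadata, species = species),
    class = "expression_study"
  )
}

#' @export
print.expression_study <- function(x, ...) {
  cat("<expression_study> ", x$species, ": ",
      nrow(x$values), " genes x ", ncol(x$values), " samples\n", sep = "")
  cat("  disease labels:",
      paste(names(table(x$metadata$disease_label)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expression_study <- function(x) dim(x$values)

#' Gene identifiers of a study
#' @param study An `expression_study`.
#' @return Character vector of gene identifiers in matrix row order.
#' @export
gene_ids <- function(study) rownames(study$values)

#' Sample identifiers of a study
#' @param study An `expression_study`.
#' @return Character vector of sample identifiers in matrix column order.
#' @export
sample_ids <- function(study) colnames(study$values)

#' Subset a study to a set of genes
#'
#' @param study An `expression_study`.
#' @param genes Character vector of gene identifiers to keep; order is
#'   preserved from the study, not from `genes`.
#' @return The subsetted `expression_study`.
#' @export
keep_genes <- function(study, genes) {
  keep <- rownames(study$values) %in% genes
  if (!any(keep)) stop("no genes left after subsetting", call. = FALSE)
  expression_study(study$values[keep, , drop = FALSE], study$metadata, study$species)
}

#' Tidy an expression study into long form
#'
#' @param x An `expression_study`.
#' @param ... Unused.
#' @return A tibble with columns `gene`, `sample_id`, `value` joined with the
#'   per-sample metadata.
#' @method tidy expression_study
#' @export
tidy.expression_study <- function(x, ...) {
  long <- tibble::tibble(
    gene = rep(rownames(x$values), times = ncol(x$values)),
    sample_id = rep(colnames(x$values), each = nrow(x$values)),
    value = as.vector(x$values)
  )
  dplyr::left_join(long, x$metadata, by = "sample_id")
}
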