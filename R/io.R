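#' Read a tab-delimited expression matrix with sample metadata
#'
#' The matrix file has a header row of sample identifiers and a first column
#' of gene (or probe) identifiers; values are log-scale normalized
#' intensities. The metadata file is a TSV keyed by `sample_id`.
#'
#' @param path Path to the expression matrix TSV.
#' @param metadata_path Path to the per-sample metadata TSV.
#' @param species `"human"` or `"mouse"`.
#' @return A validated [expression_study()]; row order is preserved.
#' @seealso [write_expression()]
#' @export
read_expression <- function(path, metadata_path, species = c("human", "mouse")) {
  species <- match.arg(species)
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  samples <- header[-1]
  if (anyDuplicated(samples)) {
    stop("format error: duplicated sample column id in ", path, call. = FALSE)
  }
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("format error: expected >= 2 columns in ", path, call. = FALSE)
  genes <- as.character(tab[[1]])
  values <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(values)) {
    stop("format error: non-numeric expression values in ", path, call. = FALSE)
  }
  dimnames(values) <- list(genes, samples)
  metadata <- tibble::as_tibble(
    utils::read.delim(metadata_path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  )
  if (!"sample_id" %in% names(metadata)) {
    stop("metadata error: no sample_id column in ", metadata_path, call. = FALSE)
  }
  absent <- setdiff(samples, metadata$sample_id)
  if (length(absent) > 0) {
    stop("metadata error: sample(s) missing from metadata: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  expression_study(values, metadata, species)
}

#' Write an expression study to TSV files
#'
#' @param study An [expression_study()].
#' @param path Output path for the matrix TSV (gene column first).
#' @param metadata_path Output path for the metadata TSV.
#' @return `study`, invisibly.
#' @export
write_expression <- function(study, path, metadata_path) {
  # %.17g guarantees the decimal text reads back to the identical double
  chr <- matrix(sprintf("%.17g", study$values), nrow = nrow(study$values),
                dimnames = dimnames(study$values))
  tab <- data.frame(gene = rownames(study$values), chr,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(study$metadata), metadata_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(study)
}

#' Collapse probe-level rows to gene-level rows by median
#'
#' When multiple probes map to one gene, the per-sample median expression
#' across that gene's probes is used. Probes absent from the mapping are
#' dropped with a message reporting the count.
#'
#' @param study An [expression_study()] whose rows are probe identifiers.
#' @param probe_to_gene Named character vector (names = probe ids, values =
#'   gene ids) or a data frame with columns `probe` and `gene`.
#' @return An [expression_study()] with one row per gene. Idempotent on an
#'   already-collapsed study given an identity mapping.
#' @export
collapse_probes <- function(study, probe_to_gene) {
  if (is.data.frame(probe_to_gene)) {
    map <- stats::setNames(as.character(probe_to_gene$gene),
                           as.character(probe_to_gene$probe))
  } else {
    map <- probe_to_gene
  }
  probes <- rownames(study$values)
  mapped <- probes %in% names(map)
  if (sum(!mapped) > 0) {
    message("collapse_probes: dropping ", sum(!mapped), " unmapped probe(s)")
  }
  if (!any(mapped)) stop("input error: no probes map to any gene", call. = FALSE)
  vals <- study$values[mapped, , drop = FALSE]
  gene <- unname(map[rownames(vals)])
  idx <- split(seq_len(nrow(vals)), gene)
  collapsed <- t(vapply(idx, function(i) {
    apply(vals[i, , drop = FALSE], 2, stats::median)
  }, numeric(ncol(vals))))
  # preserve first-appearance order of genes rather than split()'s sorted order
  first <- vapply(idx, min, integer(1))
  collapsed <- collapsed[order(first), , drop = FALSE]
  colnames(collapsed) <- colnames(vals)
  expression_study(collapsed, study$metadata, study$species)
}

#' Read a GMT gene-set collection
#'
#' One set per line: name, description, then tab-separated member
#' identifiers. Membership is case-sensitive.
#'
#' @param path Path to the GMT file.
#' @return A `gene_set_collection`: a named list of character vectors with a
#'   `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad) > 0) {
    stop("parse error: malformed GMT line ", bad[1], " in ", path, call. = FALSE)
  }
  names_ <- vapply(parts, `[[`, character(1), 1)
  descr <- vapply(parts, `[[`, character(1), 2)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  gene_set_collection(stats::setNames(sets, names_), stats::setNames(descr, names_))
}

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors of gene identifiers.
#' @param descriptions Optional named character vector of set descriptions.
#' @return A `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    stop("set names must be present and unique", call. = FALSE)
  }
  if (any(lengths(sets) == 0)) stop("sets must be non-empty", call. = FALSE)
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(rep("", length(sets)), names(sets))
  }
  structure(sets, descriptions = descriptions, class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("<gene_set_collection> ", length(x), " sets, sizes ",
      min(lengths(x)), "-", max(lengths(x)), "\n", sep = "")
  invisible(x)
}

#' Write a gene-set collection to GMT
#'
#' @param sets A `gene_set_collection`.
#' @param path Output path.
#' @return `sets`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  descr <- attr(sets, "descriptions")
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, descr[[nm]], sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(sets)
}

#' Read a human-to-mouse homolog map
#'
#' A 2-3 column TSV with a header; the first two columns are the human and
#' mouse gene identifiers of each homolog pair. Pairs in which either gene
#' appears more than once are flagged as not one-to-one.
#'
#' @param path Path to the TSV.
#' @return A `homolog_map` tibble with columns `human_gene`, `mouse_gene`,
#'   `one_to_one`.
#' @export
read_homolog_map <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("parse error: homolog map needs >= 2 columns", call. = FALSE)
  homolog_map(as.character(tab[[1]]), as.character(tab[[2]]))
}

#' Construct a homolog map
#'
#' @param human_gene,mouse_gene Character vectors of paired identifiers.
#' @return A `homolog_map` tibble; `one_to_one` is `TRUE` for pairs whose
#'   human and mouse genes each occur exactly once in the map.
#' @export
homolog_map <- function(human_gene, mouse_gene) {
  stopifnot(length(human_gene) == length(mouse_gene))
  map <- tibble::tibble(human_gene = human_gene, mouse_gene = mouse_gene)
  map$one_to_one <- !(duplicated(map$human_gene) | duplicated(map$human_gene, fromLast = TRUE) |
                      duplicated(map$mouse_gene) | duplicated(map$mouse_gene, fromLast = TRUE))
  class(map) <- c("homolog_map", class(map))
  map
}

#' Restrict a homolog map to its one-to-one pairs
#'
#' After restriction the map is a bijection between its human and mouse gene
#' sets, the property cross-species row alignment relies on.
#'
#' @param map A `homolog_map`.
#' @return The restricted `homolog_map`.
#' @export
one_to_one_pairs <- function(map) {
  out <- map[map$one_to_one, , drop = FALSE]
  if (nrow(out) == 0) stop("no one-to-one homolog pairs", call. = FALSE)
  out
}

#' Read a gene annotation table
#'
#' TSV with columns `gene`, `secreted` (logical or 0/1) and optionally
#' `notes`; used to mark genes encoding secreted factors.
#'
#' @param path Path to the TSV.
#' @return A tibble with columns `gene`, `secreted`, `notes`.
#' @export
read_annotation <- function(path) {
  tab <- tibble::as_tibble(
    utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  )
  if (!all(c("gene", "secreted") %in% names(tab))) {
    stop("parse error: annotation table needs columns gene, secreted", call. = FALSE)
  }
  if (anyDuplicated(tab$gene)) {
    stop("parse error: duplicated gene keys in annotation table", call. = FALSE)
  }
  tab$secreted <- as.logical(tab$secreted)
  if (!"notes" %in% names(tab)) tab$notes <- ""
  tab[, c("gene", "secreted", "notes")]
}
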