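#' Expression dataset container
#'
#' A light container for a genes-by-samples matrix of normalized, log-scale
#' expression values, optionally carrying a sample design (condition labels).
#' This is the substrate of network inference and of regulator influence
#' scoring.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids). Values are log-scale normalized
#'   expression; `NA` marks missing cells.
#' @param design Optional data frame with columns `sample` and `condition`
#'   mapping every sample id to exactly one condition label.
#' @return An object of class `expression_dataset` with fields `values`
#'   (the matrix) and `design` (a tibble or `NULL`).
#' @examples
#' m <- matrix(rnorm(6), 3, 2, dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
#' expression_dataset(m, data.frame(sample = c("s1", "s2"), condition = c("a", "b")))
#' @export
expression_dataset <- function(values, design = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix", class = "coregulon_type_error")
  }
  gene_ids <- rownames(values)
  sample_ids <- colnames(values)
  if (is.null(gene_ids) || is.null(sample_ids)) {
    abort("`values` must have gene rownames and sample colnames",
          class = "coregulon_type_error")
  }
  if (anyDuplicated(gene_ids)) {
    abort(paste0("duplicate gene ids: ",
                 paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", ")),
          class = "coregulon_duplicate_id_error")
  }
  if (anyDuplicated(sample_ids)) {
    abort(paste0("duplicate sample ids: ",
                 paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", ")),
          class = "coregulon_duplicate_id_error")
  }
  if (!is.null(design)) {
    design <- tibble::as_tibble(design)
    if (!all(c("sample", "condition") %in% names(design))) {
      abort("design must have columns `sample` and `condition`",
            class = "coregulon_design_error")
    }
    design <- design[, c("sample", "condition")]
    design$sample <- as.character(design$sample)
    design$condition <- as.character(design$condition)
    missing <- setdiff(design$sample, sample_ids)
    if (length(missing) > 0) {
      abort(paste0("design samples absent from matrix: ",
                   paste(missing, collapse = ", ")),
            class = "coregulon_design_error")
    }
    if (anyDuplicated(design$sample)) {
      abort("design maps a sample to more than one condition",
            class = "coregulon_design_error")
    }
    undesigned <- setdiff(sample_ids, design$sample)
    if (length(undesigned) > 0) {
      abort(paste0("samples missing from design: ",
                   paste(undesigned, collapse = ", ")),
            class = "coregulon_design_error")
    }
    design <- design[match(sample_ids, design$sample), ]
  }
  structure(list(values = values, design = design),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression_dataset> %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  if (!is.null(x$design)) {
    tab <- table(x$design$condition)
    cat("conditions:", paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
                             collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$values)

gene_ids <- function(expr) rownames(expr$values)
sample_ids <- function(expr) colnames(expr$values)

conditions_of <- function(expr) {
  if (is.null(expr$design)) {
    abort("dataset carries no design (condition labels)",
          class = "coregulon_design_error")
  }
  setNames(expr$design$condition, expr$design$sample)
}

#' Turn an expression dataset into a long tibble
#'
#' @param x An `expression_dataset`.
#' @param ... Unused.
#' @return A tibble with columns `gene`, `sample`, `expression`, and
#'   `condition` if a design is attached.
#' @method as_tibble expression_dataset
#' @export
as_tibble.expression_dataset <- function(x, ...) {
  out <- tibble::tibble(
    gene = rep(rownames(x$values), times = ncol(x$values)),
    sample = rep(colnames(x$values), each = nrow(x$values)),
    expression = as.vector(x$values)
  )
  if (!is.null(x$design)) {
    out$condition <- conditions_of(x)[out$sample]
  }
  out
}

#' Read an expression matrix (and optional design) from TSV
#'
#' Expects a tab-separated matrix: header row of sample ids, first column of
#' gene ids, numeric cells (`NA` marks missing).  The design file, when
#' given, is a two-column TSV (`sample`, `condition`).
#'
#' @param path Path to the matrix TSV.
#' @param design_path Optional path to the design TSV.
#' @param missing Missing-value policy: `"fail"` (error on any missing cell)
#'   or `"gene-mean"` (replace each missing cell with its gene's row mean).
#' @return An [expression_dataset()].
#' @export
read_expression <- function(path, design_path = NULL,
                            missing = c("fail", "gene-mean")) {
  missing <- match.arg(missing)
  # readr's own parse warning is redundant with the explicit problems()
  # check below
  tab <- suppressWarnings(read_tsv_strict(path, col_types = readr::cols(
    readr::col_character(), .default = readr::col_double()
  )))
  if (ncol(tab) < 2) {
    abort("expression file needs a gene-id column plus at least one sample",
          class = "coregulon_parse_error")
  }
  prob <- readr::problems(tab)
  if (nrow(prob) > 0) {
    abort(sprintf("non-numeric expression cell near row %d, column %d",
                  prob$row[1], prob$col[1]),
          class = "coregulon_parse_error")
  }
  genes <- tab[[1]]
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- genes
  if (missing == "gene-mean") {
    m <- impute_gene_mean(m)
  } else if (anyNA(m)) {
    abort("expression matrix contains missing values (policy \"fail\")",
          class = "coregulon_missing_error")
  }
  design <- if (!is.null(design_path)) read_design(design_path) else NULL
  expression_dataset(m, design)
}

#' @rdname read_expression
#' @export
read_design <- function(design_path) {
  d <- read_tsv_strict(design_path, col_types = readr::cols(
    .default = readr::col_character()
  ))
  if (!all(c("sample", "condition") %in% names(d))) {
    abort("design file must have columns `sample` and `condition`",
          class = "coregulon_design_error")
  }
  d
}

# Replace missing cells with the gene's observed row mean; a fully missing
# gene row stays NA and is an error upstream.
impute_gene_mean <- function(m) {
  miss <- which(is.na(m), arr.ind = TRUE)
  if (nrow(miss) == 0) return(m)
  row_means <- rowMeans(m, na.rm = TRUE)
  if (any(is.nan(row_means[unique(miss[, 1])]))) {
    abort("gene with all values missing cannot be gene-mean imputed",
          class = "coregulon_missing_error")
  }
  m[miss] <- row_means[miss[, 1]]
  m
}

#' Write an expression dataset to TSV
#'
#' @param expr An `expression_dataset`.
#' @param path Output path for the matrix TSV.
#' @param design_path Optional output path for the design TSV.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path, design_path = NULL) {
  tab <- tibble::as_tibble(expr$values, rownames = "gene")
  write_tsv_plain(tab, path)
  if (!is.null(design_path)) {
    if (is.null(expr$design)) {
      abort("dataset has no design to write", class = "coregulon_design_error")
    }
    write_tsv_plain(expr$design, design_path)
  }
  invisible(path)
}

#' Validate a regulator catalog against an expression dataset
#'
#' Regulators absent from the expression matrix are dropped with a warning;
#' the catalog is returned as a sorted character vector.
#'
#' @param regulators Character vector of regulator gene ids (or a one-column
#'   data frame / file read with [read_regulators()]).
#' @param expr An `expression_dataset` the catalog must live in.
#' @return Sorted character vector of regulators present in `expr`.
#' @export
regulator_catalog <- function(regulators, expr) {
  if (is.data.frame(regulators)) regulators <- regulators[[1]]
  regulators <- unique(as.character(regulators))
  absent <- setdiff(regulators, gene_ids(expr))
  if (length(absent) > 0) {
    warn(sprintf("%d regulator(s) absent from expression matrix dropped: %s",
                 length(absent), paste(head(absent, 5), collapse = ", ")))
    regulators <- setdiff(regulators, absent)
  }
  sort(regulators)
}

#' @rdname regulator_catalog
#' @param path File with one regulator id per line.
#' @export
read_regulators <- function(path) {
  ids <- readLines(path, warn = FALSE)
  ids <- ids[nzchar(trimws(ids))]
  unique(trimws(ids))
}
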