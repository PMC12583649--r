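#' Evidence set: TF-target and protein-interaction edges
#'
#' Bundles external regulatory evidence: directed regulator-to-target
#' binding/ChIP edges and unordered regulator-regulator protein-interaction
#' (PPI) pairs, each carrying a non-empty source tag.  Edges are
#' deduplicated; PPI pairs are stored unordered (canonical sorted order) and
#' self-loops are rejected.
#'
#' @param tf_target Data frame with columns `regulator`, `target`, `source`.
#' @param ppi Data frame with columns `regulator_a`, `regulator_b`, `source`.
#' @return An object of class `evidence_set` with tibble fields `tf_target`
#'   and `ppi`, and an attribute `n_dropped_self_loops`.
#' @export
evidence_set <- function(tf_target = NULL, ppi = NULL) {
  tf_target <- if (is.null(tf_target)) {
    tibble::tibble(regulator = character(), target = character(),
                   source = character())
  } else {
    tt <- tibble::as_tibble(tf_target)[, c("regulator", "target", "source")]
    tt <- dplyr::mutate(tt, dplyr::across(dplyr::everything(), as.character))
    dplyr::distinct(tt)
  }
  n_self <- 0L
  ppi <- if (is.null(ppi)) {
    tibble::tibble(regulator_a = character(), regulator_b = character(),
                   source = character())
  } else {
    pp <- tibble::as_tibble(ppi)[, c("regulator_a", "regulator_b", "source")]
    pp <- dplyr::mutate(pp, dplyr::across(dplyr::everything(), as.character))
    self <- pp$regulator_a == pp$regulator_b
    n_self <- sum(self)
    if (n_self > 0) {
      warn(sprintf("dropped %d self-loop PPI row(s)", n_self))
      pp <- pp[!self, , drop = FALSE]
    }
    # canonical unordered storage
    a <- pmin(pp$regulator_a, pp$regulator_b)
    b <- pmax(pp$regulator_a, pp$regulator_b)
    pp$regulator_a <- a
    pp$regulator_b <- b
    dplyr::distinct(pp)
  }
  if (any(!nzchar(tf_target$source)) || any(!nzchar(ppi$source))) {
    abort("evidence source tags must be non-empty strings",
          class = "coregulon_evidence_error")
  }
  structure(list(tf_target = tf_target, ppi = ppi),
            class = "evidence_set",
            n_dropped_self_loops = n_self)
}

#' @export
print.evidence_set <- function(x, ...) {
  cat(sprintf("<evidence_set> %d TF-target edges, %d PPI pairs\n",
              nrow(x$tf_target), nrow(x$ppi)))
  invisible(x)
}

#' Read evidence edge lists from TSV
#'
#' Both files are 3-column TSVs: `(regulator, target, source)` for binding /
#' ChIP evidence and `(regulator_a, regulator_b, source)` for protein
#' interactions.  Duplicate rows are collapsed; `(a,b)` and `(b,a)` PPI rows
#' become one unordered pair; self-loop PPI rows are dropped with a warning.
#'
#' @param tf_target_path Path to the TF-target edge list (or `NULL`).
#' @param ppi_path Path to the PPI edge list (or `NULL`).
#' @return An [evidence_set()].
#' @export
read_evidence <- function(tf_target_path = NULL, ppi_path = NULL) {
  tt <- NULL
  if (!is.null(tf_target_path)) {
    tt <- read_tsv_strict(tf_target_path,
                          col_types = readr::cols(.default = readr::col_character()))
    if (!all(c("regulator", "target", "source") %in% names(tt))) {
      abort("TF-target evidence needs columns regulator, target, source",
            class = "coregulon_parse_error")
    }
  }
  pp <- NULL
  if (!is.null(ppi_path)) {
    pp <- read_tsv_strict(ppi_path,
                          col_types = readr::cols(.default = readr::col_character()))
    if (!all(c("regulator_a", "regulator_b", "source") %in% names(pp))) {
      abort("PPI evidence needs columns regulator_a, regulator_b, source",
            class = "coregulon_parse_error")
    }
  }
  evidence_set(tf_target = tt, ppi = pp)
}

#' Write an evidence set to TSV edge lists
#'
#' @param evidence An `evidence_set`.
#' @param tf_target_path,ppi_path Output paths (either may be `NULL`).
#' @return Invisibly, the evidence set.
#' @export
write_evidence <- function(evidence, tf_target_path = NULL, ppi_path = NULL) {
  if (!is.null(tf_target_path)) {
    write_tsv_plain(dplyr::arrange(evidence$tf_target, .data$regulator,
                                   .data$target, .data$source),
                    tf_target_path)
  }
  if (!is.null(ppi_path)) {
    write_tsv_plain(dplyr::arrange(evidence$ppi, .data$regulator_a,
                                   .data$regulator_b, .data$source),
                    ppi_path)
  }
  invisible(evidence)
}

ppi_keys <- function(evidence) {
  pair_key(evidence$ppi$regulator_a, evidence$ppi$regulator_b)
}

tf_target_keys <- function(evidence) {
  paste(evidence$tf_target$regulator, evidence$tf_target$target, sep = "->")
}
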