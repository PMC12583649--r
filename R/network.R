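#' Regulatory network of local programs
#'
#' A regulatory network maps each target gene to one local program: a
#' co-activator set `A` and a co-repressor set `I` of regulators, with a
#' discrete fit score in `[0, 2]` (0 = perfect) and an evidence-support
#' fraction in `[0, 1]`.  Regulator sets are stored as canonical
#' `;`-joined sorted strings so that serialization round-trips exactly.
#'
#' @param programs Data frame with columns `target`, `activators`,
#'   `repressors` (each a `;`-joined id string, `""` for the empty set),
#'   `fit_score`, `evidence_support`.
#' @param candidates Optional tibble of retained per-target candidate
#'   programs (same columns minus `evidence_support`), used by evidence
#'   integration to re-select programs.
#' @return An object of class `regulatory_network`.
#' @export
regulatory_network <- function(programs, candidates = NULL) {
  programs <- tibble::as_tibble(programs)
  needed <- c("target", "activators", "repressors", "fit_score",
              "evidence_support")
  if (!all(needed %in% names(programs))) {
    abort(paste("programs must have columns", paste(needed, collapse = ", ")),
          class = "coregulon_network_error")
  }
  programs <- programs[, needed]
  programs$target <- as.character(programs$target)
  if (anyDuplicated(programs$target)) {
    abort("a target gene may carry only one selected program",
          class = "coregulon_network_error")
  }
  # canonicalize set strings and check invariants
  programs$activators <- vapply(programs$activators,
                                function(k) set_key(key_to_set(k)), character(1),
                                USE.NAMES = FALSE)
  programs$repressors <- vapply(programs$repressors,
                                function(k) set_key(key_to_set(k)), character(1),
                                USE.NAMES = FALSE)
  for (i in seq_len(nrow(programs))) {
    a <- key_to_set(programs$activators[i])
    r <- key_to_set(programs$repressors[i])
    if (length(a) == 0 && length(r) == 0) {
      abort(sprintf("program for %s has neither activators nor repressors",
                    programs$target[i]), class = "coregulon_network_error")
    }
    if (length(intersect(a, r)) > 0) {
      abort(sprintf("program for %s lists a regulator as both activator and repressor",
                    programs$target[i]), class = "coregulon_network_error")
    }
  }
  if (any(programs$fit_score < 0 | programs$fit_score > 2)) {
    abort("fit_score must lie in [0, 2]", class = "coregulon_network_error")
  }
  if (any(programs$evidence_support < 0 | programs$evidence_support > 1)) {
    abort("evidence_support must lie in [0, 1]", class = "coregulon_network_error")
  }
  structure(list(programs = dplyr::arrange(programs, .data$target),
                 candidates = candidates),
            class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<regulatory_network> %d targets, %d regulators, %d interactions\n",
              g$n_targets, g$n_regulators, g$n_interactions))
  invisible(x)
}

#' Regulon view: which genes each regulator activates or represses
#'
#' The transpose of the program table: for each regulator `r`, `A^r` is the
#' set of targets whose program lists `r` as activator and `I^r` the set of
#' targets listing it as repressor.
#'
#' @param network A `regulatory_network`.
#' @return A tibble with columns `regulator`, `role` (`"activates"` /
#'   `"represses"`), `target` — one row per network interaction.
#' @export
regulon_view <- function(network) {
  p <- network$programs
  long <- dplyr::bind_rows(
    tibble::tibble(regulator = lapply(p$activators, key_to_set),
                   role = "activates", target = p$target),
    tibble::tibble(regulator = lapply(p$repressors, key_to_set),
                   role = "represses", target = p$target)
  )
  long <- tidyr::unnest(long, "regulator")
  dplyr::arrange(long, .data$regulator, .data$role, .data$target)
}

#' Targets of one regulator, split by role
#'
#' @param network A `regulatory_network`.
#' @param regulator A regulator id appearing in at least one program.
#' @return A list with character vectors `activated` (`A^r`) and
#'   `repressed` (`I^r`).
#' @export
regulator_targets <- function(network, regulator) {
  rv <- regulon_view(network)
  rv <- rv[rv$regulator == regulator, , drop = FALSE]
  if (nrow(rv) == 0) {
    abort(sprintf("regulator %s appears in no program", regulator),
          class = "coregulon_network_error")
  }
  list(activated = rv$target[rv$role == "activates"],
       repressed = rv$target[rv$role == "represses"])
}

network_regulators <- function(network) {
  sort(unique(unlist(lapply(
    c(network$programs$activators, network$programs$repressors), key_to_set
  ))))
}

#' @describeIn regulatory_network `tidy()` returns the interaction (edge)
#'   table: one row per regulator-target interaction with its role and the
#'   program's scores.
#' @param x A `regulatory_network`.
#' @param ... Unused.
#' @method tidy regulatory_network
#' @export
tidy.regulatory_network <- function(x, ...) {
  rv <- regulon_view(x)
  dplyr::left_join(rv, x$programs[, c("target", "fit_score", "evidence_support")],
                   by = "target")
}

#' @describeIn regulatory_network `glance()` returns one-row network
#'   summary counts.
#' @method glance regulatory_network
#' @export
glance.regulatory_network <- function(x, ...) {
  rv <- regulon_view(x)
  tibble::tibble(
    n_targets = nrow(x$programs),
    n_regulators = length(unique(rv$regulator)),
    n_interactions = nrow(rv),
    mean_fit_score = mean(x$programs$fit_score),
    mean_evidence_support = mean(x$programs$evidence_support)
  )
}

#' Serialize / deserialize a regulatory network program table
#'
#' The on-disk form is a TSV with columns `target`, `activators`,
#' `repressors` (`;`-joined, empty string for the empty set), `fit_score`,
#' `evidence_support`.  `read_network(write_network(x))` reproduces `x`
#' exactly.
#'
#' @param network A `regulatory_network`.
#' @param path Output / input path.
#' @return `write_network` returns `path` invisibly; `read_network` returns
#'   a `regulatory_network`.
#' @export
write_network <- function(network, path) {
  p <- network$programs
  p$fit_score <- num_chr(p$fit_score, digits = 17)
  p$evidence_support <- num_chr(p$evidence_support, digits = 17)
  write_tsv_plain(p, path)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  tab <- read_tsv_strict(path, col_types = readr::cols(
    target = readr::col_character(),
    activators = readr::col_character(),
    repressors = readr::col_character(),
    fit_score = readr::col_double(),
    evidence_support = readr::col_double()
  ))
  tab$activators[is.na(tab$activators)] <- ""
  tab$repressors[is.na(tab$repressors)] <- ""
  regulatory_network(tab)
}
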