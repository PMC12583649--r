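#' Re-select local programs using external evidence
#'
#' Each target's retained candidate programs are re-scored as
#' `integrated_score = (1 - fit_score / 2) + lambda * evidence_support`
#' and the maximizer is selected.  A program's `evidence_support` is the
#' mean of (a) the fraction of its regulator-to-target edges present in
#' the TF-target evidence and (b) the fraction of its within-program
#' regulator pairs present in the PPI evidence; a component with an empty
#' denominator (no regulator pairs in a one-regulator program) is dropped
#' from the mean.  With `lambda = 0` selection reduces to fit-only
#' selection.  Ties are broken as in [infer_network()].
#'
#' @param network A `regulatory_network` from [infer_network()] carrying
#'   candidate programs.
#' @param evidence An [evidence_set()].
#' @param lambda Evidence weight (>= 0).
#' @param keep_top Number of candidate programs considered per gene
#'   (default: all retained).
#' @return A `regulatory_network` with re-selected programs and recorded
#'   `evidence_support`.
#' @export
integrate_evidence <- function(network, evidence, lambda = 1.0,
                               keep_top = Inf) {
  if (lambda < 0) {
    abort("lambda must be >= 0", class = "coregulon_config_error")
  }
  cand <- network$candidates
  if (is.null(cand) || nrow(cand) == 0) {
    abort("network carries no candidate programs; run infer_network() first",
          class = "coregulon_network_error")
  }
  tf_keys <- tf_target_keys(evidence)
  pp_keys <- ppi_keys(evidence)
  if (is.finite(keep_top)) {
    cand <- dplyr::group_by(cand, .data$target)
    cand <- dplyr::slice_head(cand, n = keep_top)
    cand <- dplyr::ungroup(cand)
  }
  cand$evidence_support <- vapply(seq_len(nrow(cand)), function(i) {
    program_evidence_support(
      key_to_set(cand$activators[i]), key_to_set(cand$repressors[i]),
      cand$target[i], tf_keys, pp_keys
    )
  }, numeric(1))
  cand$integrated_score <- (1 - cand$fit_score / 2) +
    lambda * cand$evidence_support
  cand <- dplyr::arrange(cand, .data$target,
                         dplyr::desc(.data$integrated_score),
                         .data$fit_score, .data$size,
                         .data$activators, .data$repressors)
  sel <- dplyr::slice_head(dplyr::group_by(cand, .data$target), n = 1)
  sel <- dplyr::ungroup(sel)
  out <- regulatory_network(
    sel[, c("target", "activators", "repressors", "fit_score",
            "evidence_support")],
    candidates = network$candidates
  )
  attr(out, "lambda") <- lambda
  out
}

# Evidence support of one program: mean of the available fractions.
program_evidence_support <- function(activators, repressors, target,
                                     tf_keys, pp_keys) {
  regs <- c(activators, repressors)
  edge_frac <- mean(paste(regs, target, sep = "->") %in% tf_keys)
  fracs <- edge_frac
  if (length(regs) >= 2) {
    pairs <- combn(sort(regs), 2)
    pair_frac <- mean(pair_key(pairs[1, ], pairs[2, ]) %in% pp_keys)
    fracs <- c(fracs, pair_frac)
  }
  mean(fracs)
}

#' Evidence enrichment of a network (hypergeometric upper tail)
#'
#' Quantifies how strongly the network's edges overlap an external
#' evidence layer, against a hypergeometric null of drawing the network's
#' edges uniformly from a defined universe.
#'
#' * `mode = "ppi"`: the universe is all unordered pairs of network
#'   regulators; the network's draws are its co-regulator pairs (pairs
#'   co-occurring in at least one program); marked elements are evidenced
#'   PPI pairs inside the universe.
#' * `mode = "tfbs"`: the universe is all network-regulator-by-network-
#'   target pairs; draws are the network's regulator-target interactions;
#'   marked elements are evidenced TF-target pairs inside the universe.
#'
#' The p-value is `P(X >= overlap)` for `X` hypergeometric.
#'
#' @param network A `regulatory_network`.
#' @param evidence An [evidence_set()].
#' @param mode `"ppi"` or `"tfbs"`.
#' @return A one-row tibble: `mode`, `n_network`, `n_marked`,
#'   `n_universe`, `overlap`, `p_value`.
#' @export
evidence_enrichment_test <- function(network, evidence,
                                     mode = c("ppi", "tfbs")) {
  mode <- match.arg(mode)
  if (mode == "ppi") {
    regs <- network_regulators(network)
    if (length(regs) < 2) {
      abort("ppi universe is empty (fewer than two network regulators)",
            class = "coregulon_input_error")
    }
    all_pairs <- combn(regs, 2)
    universe <- pair_key(all_pairs[1, ], all_pairs[2, ])
    drawn <- unique(unlist(lapply(
      seq_len(nrow(network$programs)), function(i) {
        mem <- sort(c(key_to_set(network$programs$activators[i]),
                      key_to_set(network$programs$repressors[i])))
        if (length(mem) < 2) return(character(0))
        pr <- combn(mem, 2)
        pair_key(pr[1, ], pr[2, ])
      })))
    marked <- intersect(ppi_keys(evidence), universe)
  } else {
    regs <- network_regulators(network)
    tgts <- network$programs$target
    if (length(regs) == 0 || length(tgts) == 0) {
      abort("tfbs universe is empty", class = "coregulon_input_error")
    }
    universe_n <- length(regs) * length(tgts)
    rv <- regulon_view(network)
    drawn <- unique(paste(rv$regulator, rv$target, sep = "->"))
    ev <- unique(tf_target_keys(evidence))
    marked <- ev[ev %in% paste(rep(regs, times = length(tgts)),
                               rep(tgts, each = length(regs)), sep = "->")]
    overlap <- length(intersect(drawn, marked))
    p <- phyper(overlap - 1, length(marked), universe_n - length(marked),
                length(drawn), lower.tail = FALSE)
    return(tibble::tibble(mode = mode, n_network = length(drawn),
                          n_marked = length(marked), n_universe = universe_n,
                          overlap = overlap, p_value = p))
  }
  overlap <- length(intersect(drawn, marked))
  p <- phyper(overlap - 1, length(marked), length(universe) - length(marked),
              length(drawn), lower.tail = FALSE)
  tibble::tibble(mode = mode, n_network = length(drawn),
                 n_marked = length(marked), n_universe = length(universe),
                 overlap = overlap, p_value = p)
}
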