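#' Infer a regulatory network from an expression compendium
#'
#' Hybrid LICORN-style inference.  The matrix is discretized
#' ([discretize()]) and co-regulator candidate sets are mined from the
#' regulators' discrete profiles ([mine_candidates()]).  Each target gene
#' is then assigned a local program `(A, I)` of co-activators and
#' co-repressors.
#'
#' Two stages produce per-target programs:
#'
#' 1. *Discrete search.*  Mined candidate sets are combined into
#'    `(A, I)` pairs (either side, but not both, may be empty).  A pair
#'    is admitted when its discrete fit — the mean absolute difference
#'    between predicted and observed discrete target state
#'    ([score_program()]) — does not exceed `fit_cutoff`.  Admitted
#'    pairs are ranked by the correlation between the target's
#'    standardized expression and the pair's net regulator signal (mean
#'    standardized expression of `A` minus mean of `I`), minus
#'    `size_penalty` per member; the `max_programs_per_gene` best are
#'    retained as candidates for evidence integration.
#' 2. *Numerical selection* (the hybrid step, `score_method =
#'    "hybrid"`).  The selected program is refined by best-subset
#'    regression of the target's standardized expression on the
#'    `subset_shortlist` regulators with the strongest marginal
#'    correlation: all subsets up to `max_program_size` members are
#'    scored by BIC (plus `bic_penalty` per coefficient) and the best
#'    subset's members are assigned to `A` or `I` by the sign of their
#'    regression coefficients.  The refined program replaces the
#'    discrete winner when it is admissible under `fit_cutoff`.
#'    `score_method = "discrete"` skips refinement and selects the
#'    best-ranked discrete pair.
#'
#' Ties are broken deterministically everywhere: rank score, then
#' discrete fit ascending, then program size ascending, then
#' lexicographic on the program key.
#'
#' @param expr An [expression_dataset()] (the reference compendium).
#' @param regulators Character vector of regulator ids (see
#'   [regulator_catalog()]).
#' @param min_support Support threshold passed to [mine_candidates()].
#' @param max_set_size Largest co-regulator set mined.
#' @param z_threshold Discretization cut (SD units).
#' @param max_programs_per_gene Candidate programs kept per target.
#' @param fit_cutoff Largest admissible discrete fit score; targets with
#'   no admissible program are omitted (reported via the
#'   `omitted_targets` attribute).
#' @param size_penalty Complexity penalty per program member subtracted
#'   from the correlation rank score of discrete-search pairs.
#' @param score_method `"hybrid"` (best-subset numerical refinement;
#'   default) or `"discrete"`.
#' @param min_score Minimum rank score for discrete-search pairs in
#'   hybrid mode; pairs whose net regulator signal does not correlate
#'   positively with the target are dropped.
#' @param subset_shortlist Regulators entering best-subset refinement.
#' @param max_program_size Largest refined program.
#' @param bic_penalty Extra per-coefficient penalty added to `log(n)` in
#'   the subset criterion; larger values favour sparser programs.
#' @param max_coact,max_corep Per-target discrete shortlist sizes.
#' @param allow_regulator_targets If `TRUE`, regulator genes may also
#'   receive programs as targets of other regulators.
#' @return A [regulatory_network()] with per-target candidates attached
#'   (`evidence_support` is 0 until [integrate_evidence()] runs).
#' @export
infer_network <- function(expr, regulators,
                          min_support = 0.05,
                          max_set_size = 4,
                          z_threshold = 1.0,
                          max_programs_per_gene = 10,
                          fit_cutoff = 0.8,
                          size_penalty = 0.05,
                          score_method = c("hybrid", "discrete"),
                          min_score = 0,
                          subset_shortlist = 10,
                          max_program_size = 5,
                          bic_penalty = 1,
                          max_coact = 10,
                          max_corep = 10,
                          allow_regulator_targets = FALSE) {
  score_method <- match.arg(score_method)
  if (ncol(expr$values) < 8) {
    warn("fewer than 8 samples: discrete support estimates will be unstable")
  }
  regulators <- regulator_catalog(regulators, expr)
  disc <- discretize(expr, z_threshold = z_threshold)
  cands <- mine_candidates(disc, regulators, min_support = min_support,
                           max_set_size = max_set_size)
  if (nrow(cands) == 0) {
    abort("no co-regulator candidate set meets min_support",
          class = "coregulon_inference_error")
  }
  targets <- if (allow_regulator_targets) rownames(disc) else
    setdiff(rownames(disc), regulators)

  cs <- collective_state_matrix(cands$members, disc)
  keys <- cands$key
  sizes <- cands$size
  n_s <- ncol(disc)

  # standardized continuous matrix and per-candidate-set mean signal
  mz <- expr$values
  mu <- rowMeans(mz); sdv <- apply(mz, 1, sd)
  mz <- (mz - mu) / ifelse(sdv > 0, sdv, 1)
  cc <- matrix(0, length(keys), n_s)
  for (i in seq_along(keys)) {
    mem <- cands$members[[i]]
    cc[i, ] <- if (length(mem) == 1) mz[mem, ] else
      colMeans(mz[mem, , drop = FALSE])
  }

  # subset enumeration reused across targets (sizes ascending)
  shortn <- min(subset_shortlist, length(regulators))
  maxk <- min(max_program_size, shortn)
  subset_idx <- unlist(lapply(seq_len(maxk), function(k)
    combn(shortn, k, simplify = FALSE)), recursive = FALSE)

  discrete_fit <- function(a_mem, i_mem, obs) {
    s_a <- if (length(a_mem) == 0) rep(0L, n_s) else
      as.integer(sign(apply(disc[a_mem, , drop = FALSE], 2, median)))
    s_i <- if (length(i_mem) == 0) rep(0L, n_s) else
      as.integer(sign(apply(disc[i_mem, , drop = FALSE], 2, median)))
    mean(abs(sign(s_a - s_i) - obs))
  }

  programs <- vector("list", length(targets))
  cand_rows <- vector("list", length(targets))
  omitted <- character(0)
  for (gi in seq_along(targets)) {
    g <- targets[gi]
    obs <- disc[g, ]
    zg <- mz[g, ]
    rho <- as.vector(stats::cor(t(cc), zg))
    rho[is.na(rho)] <- 0
    if (score_method == "hybrid") {
      short_a <- order(-rho, sizes, keys)[seq_len(min(max_coact, length(keys)))]
      short_i <- order(rho, sizes, keys)[seq_len(min(max_corep, length(keys)))]
    } else {
      fit_act <- rowMeans(abs(sweep(cs, 2, obs)))
      fit_rep <- rowMeans(abs(sweep(-cs, 2, obs)))
      short_a <- order(fit_act, sizes, keys)[seq_len(min(max_coact, length(keys)))]
      short_i <- order(fit_rep, sizes, keys)[seq_len(min(max_corep, length(keys)))]
    }

    # enumerate combos: (a, -), (-, i), (a, i) with disjoint member sets
    a_idx <- c(short_a, rep(NA_integer_, length(short_i)),
               rep(short_a, each = length(short_i)))
    i_idx <- c(rep(NA_integer_, length(short_a)), short_i,
               rep(short_i, times = length(short_a)))
    a_key <- ifelse(is.na(a_idx), "", keys[a_idx])
    i_key <- ifelse(is.na(i_idx), "", keys[i_idx])
    keep <- mapply(function(ak, ik) {
      length(intersect(key_to_set(ak), key_to_set(ik))) == 0
    }, a_key, i_key, USE.NAMES = FALSE)
    a_idx <- a_idx[keep]; i_idx <- i_idx[keep]
    a_key <- a_key[keep]; i_key <- i_key[keep]
    zero <- rep(0L, n_s)
    fit <- vapply(seq_along(a_idx), function(ci) {
      pa <- if (is.na(a_idx[ci])) zero else cs[a_idx[ci], ]
      pr <- if (is.na(i_idx[ci])) zero else cs[i_idx[ci], ]
      mean(abs(sign(pa - pr) - obs))
    }, numeric(1))
    size <- lengths(lapply(a_key, key_to_set)) +
      lengths(lapply(i_key, key_to_set))
    zeron <- rep(0, n_s)
    raw <- vapply(seq_along(a_idx), function(ci) {
      u <- (if (is.na(a_idx[ci])) zeron else cc[a_idx[ci], ]) -
        (if (is.na(i_idx[ci])) zeron else cc[i_idx[ci], ])
      if (sd(u) == 0) return(0)
      stats::cor(u, zg)
    }, numeric(1))
    score <- if (score_method == "hybrid") raw - size_penalty * size else
      -(fit + size_penalty * size)

    tab <- tibble::tibble(target = g, activators = a_key, repressors = i_key,
                          fit_score = fit, size = as.integer(size),
                          rank_score = score)
    tab <- tab[tab$fit_score <= fit_cutoff, , drop = FALSE]
    if (score_method == "hybrid") {
      tab <- tab[tab$rank_score > min_score, , drop = FALSE]
    }
    if (nrow(tab) > 0) {
      tab <- dplyr::distinct(tab, .data$activators, .data$repressors,
                             .keep_all = TRUE)
      tab <- dplyr::arrange(tab, dplyr::desc(.data$rank_score),
                            .data$fit_score, .data$size,
                            .data$activators, .data$repressors)
      tab <- head(tab, max_programs_per_gene)
    }

    if (score_method == "hybrid") {
      shortlist <- regulators[order(-abs(as.vector(
        stats::cor(t(mz[regulators, , drop = FALSE]), zg))), regulators)]
      shortlist <- shortlist[seq_len(shortn)]
      bs <- best_subset_program(zg, mz, shortlist, subset_idx, bic_penalty)
      if (!is.null(bs)) {
        bs_fit <- discrete_fit(bs$activators, bs$repressors, obs)
        if (bs_fit <= fit_cutoff) {
          bs_row <- tibble::tibble(
            target = g, activators = set_key(bs$activators),
            repressors = set_key(bs$repressors), fit_score = bs_fit,
            size = length(bs$activators) + length(bs$repressors),
            rank_score = Inf   # refined program ranks first
          )
          tab <- dplyr::bind_rows(bs_row, tab)
          tab <- dplyr::distinct(tab, .data$activators, .data$repressors,
                                 .keep_all = TRUE)
          tab <- head(tab, max_programs_per_gene)
        }
      }
    }
    if (nrow(tab) == 0) {
      omitted <- c(omitted, g)
      next
    }
    cand_rows[[gi]] <- tab
    programs[[gi]] <- dplyr::mutate(head(tab, 1), evidence_support = 0)
  }
  programs <- dplyr::bind_rows(programs)
  if (nrow(programs) == 0) {
    abort("no target received a program under fit_cutoff",
          class = "coregulon_inference_error")
  }
  programs <- programs[, c("target", "activators", "repressors", "fit_score",
                           "evidence_support")]
  net <- regulatory_network(programs,
                            candidates = dplyr::bind_rows(cand_rows))
  attr(net, "omitted_targets") <- omitted
  attr(net, "params") <- list(min_support = min_support,
                              max_set_size = max_set_size,
                              z_threshold = z_threshold,
                              max_programs_per_gene = max_programs_per_gene,
                              fit_cutoff = fit_cutoff,
                              size_penalty = size_penalty,
                              score_method = score_method,
                              min_score = min_score,
                              subset_shortlist = subset_shortlist,
                              max_program_size = max_program_size,
                              bic_penalty = bic_penalty,
                              max_coact = max_coact, max_corep = max_corep)
  net
}

# Best-subset regression of a target on shortlisted regulators.  Subsets are
# scored by n*log(RSS/n) + k*(log(n) + bic_penalty); the winner's members
# become activators (positive coefficient) or repressors (negative).
# Returns NULL when no subset beats the intercept-only model.
best_subset_program <- function(zg, mz, shortlist, subset_idx, bic_penalty) {
  n <- length(zg)
  best_bic <- n * log(mean(zg^2))
  best <- NULL
  for (ss in subset_idx) {
    if (max(ss) > length(shortlist)) next
    mem <- shortlist[ss]
    x <- cbind(1, t(mz[mem, , drop = FALSE]))
    fit <- stats::.lm.fit(x, zg)
    rss <- sum(fit$residuals^2)
    # numerically exact fits share bic = -Inf; size-ascending enumeration
    # with strict improvement then keeps the smallest exact subset
    bic <- if (rss < n * 1e-20) -Inf else
      n * log(rss / n) + (length(mem) + 1) * (log(n) + bic_penalty)
    if (bic < best_bic - 1e-9) {
      best_bic <- bic
      coefs <- fit$coefficients[-1]
      best <- list(activators = sort(mem[coefs > 0]),
                   repressors = sort(mem[coefs <= 0]))
    }
  }
  best
}

#' Edge-level comparison of an inferred network against a reference
#'
#' Interactions are `(regulator, target, role)` triples from
#' [regulon_view()]; precision, recall and F1 are computed over those
#' triples.
#'
#' @param inferred,reference `regulatory_network` objects.
#' @return A one-row tibble: `n_inferred`, `n_reference`, `n_correct`,
#'   `precision`, `recall`, `f1`.
#' @export
network_recovery <- function(inferred, reference) {
  ek <- function(net) {
    rv <- regulon_view(net)
    paste(rv$regulator, rv$target, rv$role, sep = "|")
  }
  a <- ek(inferred); b <- ek(reference)
  n_ok <- length(intersect(a, b))
  prec <- if (length(a) > 0) n_ok / length(a) else 0
  rec <- if (length(b) > 0) n_ok / length(b) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  tibble::tibble(n_inferred = length(a), n_reference = length(b),
                 n_correct = n_ok, precision = prec, recall = rec, f1 = f1)
}
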