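#' Simulation configuration
#'
#' Parameters of the synthetic expression generator.  The generator plants a
#' small node of cooperating regulators whose latent activity — not
#' necessarily their own mRNA — shifts in the stimulated condition, driving
#' a dedicated block of co-activated targets, on top of a background of
#' randomly wired targets.  Defaults describe the reference study design
#' used throughout the package's validation: 30 regulators, 300 targets,
#' two conditions of 20 samples each, an activity shift of 2 on a 3-member
#' planted node, and unit additive noise on a log-like expression scale.
#'
#' @param n_regulators Number of regulator genes.
#' @param n_targets Number of target genes.
#' @param n_samples_per_condition Samples per condition.
#' @param n_conditions Number of conditions (>= 2).
#' @param planted_node_size Number of cooperating planted regulators.
#' @param delta Activity shift added to planted regulators in conditions
#'   with effect 1 (activity units, i.e. SD units of baseline activity).
#' @param sigma Additive Gaussian noise SD on expression (>= 0; 0 gives the
#'   noiseless limit used in identifiability checks).
#' @param edge_weight_range Length-2 positive range of regulatory edge
#'   weights, drawn uniformly.
#' @param activators_per_target,repressors_per_target Length-2 integer
#'   ranges for background-target program sizes.
#' @param planted_block_size Number of targets co-activated by the whole
#'   planted node.
#' @param evidence_coverage Fraction of true TF-target edges emitted as
#'   evidence.
#' @param evidence_fpr Spurious evidence edges, as a fraction of the number
#'   of true edges.
#' @param n_random_ppi Random (non-planted) PPI evidence pairs.
#' @param decouple_mrna If `TRUE`, planted regulators' own mRNA omits the
#'   activity shift while their targets still respond to the shifted
#'   activity — regulators influential without mRNA up-regulation.
#' @param condition_effects Named numeric vector of per-condition shift
#'   multipliers (names become condition labels).  Default for two
#'   conditions: `c(baseline = 0, stimulated = 1)`.  Supplying, e.g.,
#'   `c(baseline = 0, stimulated = 1, stim_inhibA = 0)` models an inhibitor
#'   that abolishes the planted shift.
#' @param seed Integer seed; identical configuration and seed give
#'   byte-identical datasets.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_regulators = 30,
                       n_targets = 300,
                       n_samples_per_condition = 20,
                       n_conditions = 2,
                       planted_node_size = 3,
                       delta = 2,
                       sigma = 1,
                       edge_weight_range = c(0.8, 1.2),
                       activators_per_target = c(1, 3),
                       repressors_per_target = c(0, 2),
                       planted_block_size = 30,
                       evidence_coverage = 0.8,
                       evidence_fpr = 0.1,
                       n_random_ppi = 10,
                       decouple_mrna = FALSE,
                       condition_effects = NULL,
                       seed = 1L) {
  assert_scalar_count(n_regulators, "n_regulators")
  assert_scalar_count(n_targets, "n_targets")
  assert_scalar_count(n_samples_per_condition, "n_samples_per_condition", min = 2L)
  assert_scalar_count(n_conditions, "n_conditions", min = 2L)
  assert_scalar_count(planted_node_size, "planted_node_size", min = 0L)
  assert_scalar_count(planted_block_size, "planted_block_size", min = 0L)
  assert_scalar_count(n_random_ppi, "n_random_ppi", min = 0L)
  assert_fraction(evidence_coverage, "evidence_coverage")
  assert_fraction(evidence_fpr, "evidence_fpr")
  if (planted_node_size > n_regulators) {
    abort("planted_node_size exceeds n_regulators",
          class = "coregulon_config_error")
  }
  if (planted_block_size > n_targets) {
    abort("planted_block_size exceeds n_targets",
          class = "coregulon_config_error")
  }
  if (!is.numeric(sigma) || sigma < 0) {
    abort("sigma must be >= 0", class = "coregulon_config_error")
  }
  if (length(edge_weight_range) != 2 || any(edge_weight_range <= 0) ||
      edge_weight_range[1] > edge_weight_range[2]) {
    abort("edge_weight_range must be an increasing positive pair",
          class = "coregulon_config_error")
  }
  if (is.null(condition_effects)) {
    if (n_conditions == 2) {
      condition_effects <- c(baseline = 0, stimulated = 1)
    } else {
      nm <- c("baseline", "stimulated",
              paste0("condition", seq_len(n_conditions - 2) + 2))
      condition_effects <- setNames(c(0, rep(1, n_conditions - 1)), nm)
    }
  }
  if (length(condition_effects) != n_conditions ||
      is.null(names(condition_effects)) ||
      anyDuplicated(names(condition_effects))) {
    abort("condition_effects must be a named vector of length n_conditions",
          class = "coregulon_config_error")
  }
  cfg <- list(
    n_regulators = as.integer(n_regulators),
    n_targets = as.integer(n_targets),
    n_samples_per_condition = as.integer(n_samples_per_condition),
    n_conditions = as.integer(n_conditions),
    planted_node_size = as.integer(planted_node_size),
    delta = as.numeric(delta),
    sigma = as.numeric(sigma),
    edge_weight_range = as.numeric(edge_weight_range),
    activators_per_target = as.integer(activators_per_target),
    repressors_per_target = as.integer(repressors_per_target),
    planted_block_size = as.integer(planted_block_size),
    evidence_coverage = as.numeric(evidence_coverage),
    evidence_fpr = as.numeric(evidence_fpr),
    n_random_ppi = as.integer(n_random_ppi),
    decouple_mrna = isTRUE(decouple_mrna),
    condition_effects = condition_effects,
    seed = as.integer(seed)
  )
  structure(cfg, class = "sim_config")
}

# Uniform draw from an integer range; safe when the range is degenerate
# (sample(0, 1) would otherwise error).
sample_range <- function(rng) {
  vals <- rng[1]:rng[2]
  vals[sample.int(length(vals), 1)]
}

reg_ids_for <- function(n) {
  paste0("R", formatC(seq_len(n), width = max(2, nchar(n)), flag = "0"))
}

target_ids_for <- function(n) {
  paste0("G", formatC(seq_len(n), width = max(3, nchar(n)), flag = "0"))
}

#' Simulate an expression dataset with planted regulatory structure
#'
#' Generative model, per sample `s`: regulator activity
#' `a[r, s] ~ N(0, 1)`, plus `delta * effect(condition(s))` for planted
#' regulators; regulator mRNA is activity plus `N(0, sigma)` noise (with
#' the planted shift omitted from mRNA when `decouple_mrna`); each target
#' `g` carries an activator set `A` and repressor set `I` with positive
#' weights, and expression
#' `x[g, s] = sum(w[A] * a[A, s]) - sum(w[I] * a[I, s]) + N(0, sigma)`.
#' Planted regulators co-activate a dedicated block of targets and carry
#' pairwise PPI evidence.  Evidence is a coverage-fraction sample of true
#' TF-target edges plus spurious ones.
#'
#' @param config A [sim_config()].
#' @return A list with elements `expression` ([expression_dataset()]),
#'   `evidence` ([evidence_set()]), and `truth` (class `ground_truth`:
#'   `true_network`, `planted_regulators`, `true_activity`,
#'   `condition_labels`, `weights`, `config`).
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  n_reg <- config$n_regulators
  n_tgt <- config$n_targets
  regs <- reg_ids_for(n_reg)
  tgts <- target_ids_for(n_tgt)
  conds <- names(config$condition_effects)
  n_s <- config$n_samples_per_condition * config$n_conditions
  samples <- paste0("S", formatC(seq_len(n_s), width = max(2, nchar(n_s)),
                                 flag = "0"))
  cond_of <- rep(conds, each = config$n_samples_per_condition)
  planted <- regs[seq_len(config$planted_node_size)]

  # --- topology -------------------------------------------------------------
  set.seed(sub_seed(config$seed, "topology"))
  prog_act <- vector("list", n_tgt)
  prog_rep <- vector("list", n_tgt)
  block <- seq_len(config$planted_block_size)
  for (i in seq_len(n_tgt)) {
    if (i %in% block && length(planted) > 0) {
      prog_act[[i]] <- planted
      prog_rep[[i]] <- character(0)
      next
    }
    na <- sample_range(config$activators_per_target)
    nr <- sample_range(config$repressors_per_target)
    if (na + nr == 0) na <- 1L
    members <- sample(regs, na + nr)
    prog_act[[i]] <- sort(members[seq_len(na)])
    prog_rep[[i]] <- sort(members[seq_len(nr) + na])
  }

  # --- weights --------------------------------------------------------------
  set.seed(sub_seed(config$seed, "weights"))
  weights <- purrr::map2_dfr(seq_len(n_tgt), tgts, function(i, g) {
    members <- c(prog_act[[i]], prog_rep[[i]])
    tibble::tibble(
      target = g, regulator = members,
      role = rep(c("activates", "represses"),
                 c(length(prog_act[[i]]), length(prog_rep[[i]]))),
      weight = runif(length(members), config$edge_weight_range[1],
                     config$edge_weight_range[2])
    )
  })

  # --- activities -----------------------------------------------------------
  set.seed(sub_seed(config$seed, "activities"))
  activity <- matrix(rnorm(n_reg * n_s), n_reg, n_s,
                     dimnames = list(regs, samples))
  shift <- config$delta * config$condition_effects[cond_of]
  if (length(planted) > 0) {
    activity[planted, ] <- activity[planted, , drop = FALSE] +
      matrix(shift, length(planted), n_s, byrow = TRUE)
  }

  # --- noise / expression ---------------------------------------------------
  set.seed(sub_seed(config$seed, "noise"))
  mrna_signal <- activity
  if (config$decouple_mrna && length(planted) > 0) {
    mrna_signal[planted, ] <- mrna_signal[planted, , drop = FALSE] -
      matrix(shift, length(planted), n_s, byrow = TRUE)
  }
  reg_expr <- mrna_signal + matrix(rnorm(n_reg * n_s, sd = config$sigma),
                                   n_reg, n_s)
  tgt_expr <- matrix(0, n_tgt, n_s, dimnames = list(tgts, samples))
  for (i in seq_len(n_tgt)) {
    w_rows <- weights[weights$target == tgts[i], , drop = FALSE]
    sgn <- ifelse(w_rows$role == "activates", 1, -1)
    tgt_expr[i, ] <- colSums(
      (w_rows$weight * sgn) * activity[w_rows$regulator, , drop = FALSE]
    )
  }
  tgt_expr <- tgt_expr + matrix(rnorm(n_tgt * n_s, sd = config$sigma), n_tgt, n_s)
  expr <- expression_dataset(
    rbind(reg_expr, tgt_expr),
    design = tibble::tibble(sample = samples, condition = cond_of)
  )

  # --- ground truth ---------------------------------------------------------
  true_network <- regulatory_network(tibble::tibble(
    target = tgts,
    activators = vapply(prog_act, set_key, character(1)),
    repressors = vapply(prog_rep, set_key, character(1)),
    fit_score = 0,
    evidence_support = 0
  ))
  truth <- structure(list(
    true_network = true_network,
    planted_regulators = planted,
    true_activity = activity,
    condition_labels = setNames(cond_of, samples),
    weights = weights,
    config = config
  ), class = "ground_truth")

  # --- evidence -------------------------------------------------------------
  evidence <- corrupt_evidence(truth, coverage = config$evidence_coverage,
                               fpr = config$evidence_fpr,
                               seed = sub_seed(config$seed, "evidence"),
                               n_random_ppi = config$n_random_ppi)

  list(expression = expr, evidence = evidence, truth = truth)
}

#' Simulate a query dataset on an existing ground-truth network
#'
#' Draws a fresh two-(or more-)condition dataset from the same regulatory
#' topology and edge weights as an existing simulation, emulating the
#' study design in which a query experiment is mapped onto a reference
#' network inferred from an independent compendium.  Activities, mRNA
#' noise and condition structure are re-drawn under `seed`; the
#' `decouple_mrna` flag reproduces post-transcriptional activation
#' (planted regulators' targets shift while their own mRNA does not).
#'
#' @param truth A `ground_truth` from [simulate_dataset()].
#' @param n_samples_per_condition Samples per condition in the query.
#' @param condition_effects Named shift-multiplier vector (see
#'   [sim_config()]); default `c(baseline = 0, stimulated = 1)`.
#' @param delta,sigma Activity shift and noise SD; default: the values of
#'   the generating configuration.
#' @param decouple_mrna See [sim_config()].
#' @param seed Integer seed for the query draw.
#' @return A list with `expression` (an [expression_dataset()]) and
#'   `activity` (true regulator activities of the query samples).
#' @export
simulate_query <- function(truth, n_samples_per_condition = 20,
                           condition_effects = c(baseline = 0, stimulated = 1),
                           delta = NULL, sigma = NULL,
                           decouple_mrna = FALSE, seed = 1L) {
  cfg <- truth$config
  delta <- delta %||% cfg$delta
  sigma <- sigma %||% cfg$sigma
  regs <- rownames(truth$true_activity)
  tgts <- truth$true_network$programs$target
  planted <- truth$planted_regulators
  conds <- names(condition_effects)
  n_s <- n_samples_per_condition * length(condition_effects)
  samples <- paste0("Q", formatC(seq_len(n_s), width = max(2, nchar(n_s)),
                                 flag = "0"))
  cond_of <- rep(conds, each = n_samples_per_condition)

  set.seed(sub_seed(seed, "activities"))
  activity <- matrix(rnorm(length(regs) * n_s), length(regs), n_s,
                     dimnames = list(regs, samples))
  shift <- delta * condition_effects[cond_of]
  if (length(planted) > 0) {
    activity[planted, ] <- activity[planted, , drop = FALSE] +
      matrix(shift, length(planted), n_s, byrow = TRUE)
  }
  set.seed(sub_seed(seed, "noise"))
  mrna_signal <- activity
  if (isTRUE(decouple_mrna) && length(planted) > 0) {
    mrna_signal[planted, ] <- mrna_signal[planted, , drop = FALSE] -
      matrix(shift, length(planted), n_s, byrow = TRUE)
  }
  reg_expr <- mrna_signal + matrix(rnorm(length(regs) * n_s, sd = sigma),
                                   length(regs), n_s)
  tgt_expr <- matrix(0, length(tgts), n_s, dimnames = list(tgts, samples))
  for (i in seq_along(tgts)) {
    w_rows <- truth$weights[truth$weights$target == tgts[i], , drop = FALSE]
    sgn <- ifelse(w_rows$role == "activates", 1, -1)
    tgt_expr[i, ] <- colSums(
      (w_rows$weight * sgn) * activity[w_rows$regulator, , drop = FALSE]
    )
  }
  tgt_expr <- tgt_expr +
    matrix(rnorm(length(tgts) * n_s, sd = sigma), length(tgts), n_s)
  expr <- expression_dataset(
    rbind(reg_expr, tgt_expr),
    design = tibble::tibble(sample = samples, condition = cond_of)
  )
  list(expression = expr, activity = activity)
}

#' Derive a corrupted evidence layer from simulation ground truth
#'
#' Emits `round(coverage * n_true)` true TF-target edges, plus
#' `round(fpr * n_true)` spurious regulator-target pairs absent from the
#' true network, plus PPI evidence for every pair of planted regulators and
#' `n_random_ppi` random other regulator pairs.  Deterministic under `seed`.
#'
#' @param truth A `ground_truth` object from [simulate_dataset()].
#' @param coverage Fraction of true edges emitted.
#' @param fpr Spurious edges as a fraction of true edge count.
#' @param seed Integer seed.
#' @param n_random_ppi Random PPI pairs beyond the planted node.
#' @return An [evidence_set()].
#' @export
corrupt_evidence <- function(truth, coverage, fpr, seed,
                             n_random_ppi = 0L) {
  assert_fraction(coverage, "coverage")
  assert_fraction(fpr, "fpr")
  set.seed(as.integer(seed))
  edges <- tidy(truth$true_network)
  n_true <- nrow(edges)
  regs <- rownames(truth$true_activity)
  tgts <- truth$true_network$programs$target

  keep <- sort(sample.int(n_true, round(coverage * n_true)))
  tf_tab <- tibble::tibble(regulator = edges$regulator[keep],
                           target = edges$target[keep],
                           source = "sim_chip")

  n_fp <- round(fpr * n_true)
  if (n_fp > 0) {
    true_keys <- paste(edges$regulator, edges$target, sep = "->")
    fp_reg <- character(0); fp_tgt <- character(0)
    while (length(fp_reg) < n_fp) {
      need <- n_fp - length(fp_reg)
      r <- sample(regs, need * 2, replace = TRUE)
      g <- sample(tgts, need * 2, replace = TRUE)
      ok <- !(paste(r, g, sep = "->") %in% true_keys) &
        !(paste(r, g, sep = "->") %in% paste(fp_reg, fp_tgt, sep = "->"))
      fp_reg <- c(fp_reg, r[ok]); fp_tgt <- c(fp_tgt, g[ok])
    }
    tf_tab <- dplyr::bind_rows(tf_tab, tibble::tibble(
      regulator = fp_reg[seq_len(n_fp)], target = fp_tgt[seq_len(n_fp)],
      source = "sim_spurious"
    ))
  }

  ppi_tab <- NULL
  planted <- truth$planted_regulators
  if (length(planted) >= 2) {
    pr <- t(combn(sort(planted), 2))
    ppi_tab <- tibble::tibble(regulator_a = pr[, 1], regulator_b = pr[, 2],
                              source = "sim_ppi")
  }
  if (n_random_ppi > 0 && length(regs) >= 2) {
    ra <- character(0); rb <- character(0)
    guard <- 0L
    while (length(ra) < n_random_ppi && guard < 1000L) {
      p <- sample(regs, 2)
      k <- pair_key(p[1], p[2])
      seen <- if (is.null(ppi_tab)) character(0) else
        pair_key(ppi_tab$regulator_a, ppi_tab$regulator_b)
      if (!(k %in% c(seen, pair_key(ra, rb)))) {
        ra <- c(ra, min(p)); rb <- c(rb, max(p))
      }
      guard <- guard + 1L
    }
    ppi_tab <- dplyr::bind_rows(ppi_tab, tibble::tibble(
      regulator_a = ra, regulator_b = rb, source = "sim_ppi_random"
    ))
  }
  evidence_set(tf_target = tf_tab, ppi = ppi_tab)
}

#' Write / read simulation ground truth as JSON
#'
#' The JSON document stores the true program table, planted regulators,
#' edge weights, condition labels and the true activity matrix, so a
#' simulated study can be archived alongside its expression TSVs.
#'
#' @param truth A `ground_truth` object.
#' @param path JSON path.
#' @return `write_ground_truth` returns `path` invisibly;
#'   `read_ground_truth` a `ground_truth` (with `config` restored as a
#'   plain list).
#' @export
write_ground_truth <- function(truth, path) {
  doc <- list(
    programs = truth$true_network$programs,
    planted_regulators = truth$planted_regulators,
    weights = truth$weights,
    condition_labels = as.list(truth$condition_labels),
    true_activity = list(
      regulators = rownames(truth$true_activity),
      samples = colnames(truth$true_activity),
      values = unname(apply(truth$true_activity, 1, identity, simplify = FALSE))
    ),
    config = unclass(truth$config)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  vals <- doc$true_activity$values
  act <- if (is.matrix(vals)) vals else
    do.call(rbind, lapply(vals, as.numeric))
  dimnames(act) <- list(doc$true_activity$regulators, doc$true_activity$samples)
  structure(list(
    true_network = regulatory_network(tibble::as_tibble(doc$programs)),
    planted_regulators = as.character(doc$planted_regulators),
    true_activity = act,
    condition_labels = unlist(doc$condition_labels),
    weights = tibble::as_tibble(doc$weights),
    config = doc$config
  ), class = "ground_truth")
}
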