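#' Per-sample influence of one regulator
#'
#' Welch-type contrast between the expression of the genes a regulator
#' activates (`A^r`) and the genes it represses (`I^r`) within a single
#' sample:
#' `(mean(E[A^r]) - mean(E[I^r])) / sqrt(var(E[A^r])/|A^r| + var(E[I^r])/|I^r|)`
#' with unbiased variances.  Positive influence means activated targets sit
#' above repressed targets, the signature of an active regulator.
#'
#' @param expr_column Named numeric vector: one sample's expression, names
#'   are gene ids covering `activated` and `repressed`.
#' @param activated,repressed Character vectors `A^r` and `I^r`.
#' @return Numeric influence value, or `NA` with an explanatory
#'   `"flag"` attribute (`"zero-denominator"`) when both groups are
#'   constant.
#' @examples
#' v <- c(a1 = 1, a2 = 2, a3 = 3, i1 = -1, i2 = 0, i3 = 1)
#' sample_influence(v, c("a1", "a2", "a3"), c("i1", "i2", "i3"))  # ~2.449
#' @export
sample_influence <- function(expr_column, activated, repressed) {
  ea <- expr_column[activated]
  ei <- expr_column[repressed]
  if (length(ea) < 2 || length(ei) < 2) {
    abort("each regulon side needs >= 2 profiled genes for a variance",
          class = "coregulon_influence_error")
  }
  den <- sqrt(var(ea) / length(ea) + var(ei) / length(ei))
  if (den == 0) {
    return(structure(NA_real_, flag = "zero-denominator"))
  }
  (mean(ea) - mean(ei)) / den
}

#' Regulator eligibility under the minimum-regulon-size rule
#'
#' A regulator gets an influence value only if it activates or represses at
#' least `min_targets` genes (default 5).  `rule = "combined"` reads the
#' requirement as `|A^r| + |I^r| >= min_targets`; `rule = "per_side"`
#' requires each nonempty side to reach it.
#'
#' @param n_activated,n_repressed Regulon side sizes.
#' @param min_targets Minimum gene count (default 5).
#' @param rule `"combined"` or `"per_side"`.
#' @return Logical.
#' @export
influence_eligible <- function(n_activated, n_repressed, min_targets = 5,
                               rule = c("combined", "per_side")) {
  rule <- match.arg(rule)
  if (rule == "combined") {
    (n_activated + n_repressed) >= min_targets
  } else {
    sides <- c(n_activated, n_repressed)
    all(sides[sides > 0] >= min_targets) && sum(sides) > 0
  }
}

#' Influence matrix: regulators by samples
#'
#' Maps a query expression dataset onto a reference regulatory network and
#' computes the per-sample influence of every eligible regulator.  The
#' query matrix is first per-gene standardized (flag `standardize`), since
#' the reference network typically comes from a different compendium.
#' Query genes absent from a regulon are dropped from it; the overlap
#' fraction between query genes and network targets is reported.
#'
#' One-sided regulons (`A^r` or `I^r` empty) are undefined under the
#' two-group contrast; with `one_sided = "fallback"` the nonempty side is
#' contrasted against all profiled genes that are not targets of the
#' regulator (flagged `one-sided-fallback`); `one_sided = "strict"`
#' excludes such regulators.
#'
#' @param expr Query [expression_dataset()].
#' @param network Reference `regulatory_network`.
#' @param min_targets,rule Eligibility rule (see [influence_eligible()]).
#' @param one_sided `"fallback"` or `"strict"`.
#' @param standardize Per-gene center/scale the query before scoring.
#' @param missing Imputation policy for missing cells (`"fail"` or
#'   `"gene-mean"`).
#' @return An `influence_matrix` object: fields `values` (regulators x
#'   samples, `NA` for ineligible), `eligibility` (tibble: regulator,
#'   n_activated, n_repressed, status), `design`, `overlap_fraction`.
#' @export
influence_matrix <- function(expr, network, min_targets = 5,
                             rule = c("combined", "per_side"),
                             one_sided = c("fallback", "strict"),
                             standardize = TRUE,
                             missing = c("fail", "gene-mean")) {
  rule <- match.arg(rule)
  one_sided <- match.arg(one_sided)
  missing <- match.arg(missing)
  m <- expr$values
  if (anyNA(m)) {
    if (missing == "fail") {
      abort("query matrix contains missing values (policy \"fail\")",
            class = "coregulon_missing_error")
    }
    m <- impute_gene_mean(m)
  }
  net_targets <- network$programs$target
  overlap <- mean(net_targets %in% rownames(m))
  if (overlap == 0) {
    abort("query dataset shares no genes with network targets",
          class = "coregulon_input_error")
  }
  if (standardize) {
    mu <- rowMeans(m)
    s <- apply(m, 1, sd)
    m <- (m - mu) / ifelse(s > 0, s, 1)
  }
  rv <- regulon_view(network)
  rv <- rv[rv$target %in% rownames(m), , drop = FALSE]
  regs <- sort(unique(rv$regulator))
  profiled <- rownames(m)

  elig <- vector("list", length(regs))
  vals <- matrix(NA_real_, length(regs), ncol(m),
                 dimnames = list(regs, colnames(m)))
  for (ri in seq_along(regs)) {
    r <- regs[ri]
    a <- rv$target[rv$regulator == r & rv$role == "activates"]
    i <- rv$target[rv$regulator == r & rv$role == "represses"]
    status <- "eligible"
    if (!influence_eligible(length(a), length(i), min_targets, rule)) {
      status <- "too-few-targets"
    } else if (length(a) == 0 || length(i) == 0) {
      if (one_sided == "strict") {
        status <- "one-sided-excluded"
      } else {
        status <- "one-sided-fallback"
        opposing <- setdiff(profiled, c(a, i))
        if (length(a) == 0) a <- opposing else i <- opposing
      }
    }
    elig[[ri]] <- tibble::tibble(
      regulator = r,
      n_activated = sum(rv$regulator == r & rv$role == "activates"),
      n_repressed = sum(rv$regulator == r & rv$role == "represses"),
      status = status
    )
    if (status %in% c("eligible", "one-sided-fallback")) {
      na <- length(a); ni <- length(i)
      ma <- m[a, , drop = FALSE]; mi <- m[i, , drop = FALSE]
      mean_a <- colMeans(ma); mean_i <- colMeans(mi)
      var_a <- (colSums(ma^2) - na * mean_a^2) / (na - 1)
      var_i <- (colSums(mi^2) - ni * mean_i^2) / (ni - 1)
      den <- sqrt(var_a / na + var_i / ni)
      v <- (mean_a - mean_i) / den
      v[den == 0 | !is.finite(v)] <- NA_real_   # constant or single-gene side
      vals[ri, ] <- v
    }
  }
  structure(list(values = vals,
                 eligibility = dplyr::bind_rows(elig),
                 design = expr$design,
                 overlap_fraction = overlap),
            class = "influence_matrix")
}

#' @export
print.influence_matrix <- function(x, ...) {
  cat(sprintf("<influence_matrix> %d regulators x %d samples (%d eligible)\n",
              nrow(x$values), ncol(x$values),
              sum(x$eligibility$status %in% c("eligible", "one-sided-fallback"))))
  invisible(x)
}

#' Activity call from an influence value
#'
#' A regulator is active in a sample only when its activated targets exceed
#' its repressed targets as the network model expects — a strictly positive
#' influence (Welch t) value.
#'
#' @param influence Numeric influence value(s).
#' @return Logical: `TRUE` iff strictly positive (`NA` stays `NA`).
#' @export
is_active <- function(influence) {
  influence > 0
}

#' @describeIn influence_matrix `tidy()` returns the long
#'   regulator-by-sample influence table (with condition labels when the
#'   query carried a design).
#' @param x An `influence_matrix`.
#' @param ... Unused.
#' @method tidy influence_matrix
#' @export
tidy.influence_matrix <- function(x, ...) {
  out <- tibble::tibble(
    regulator = rep(rownames(x$values), times = ncol(x$values)),
    sample = rep(colnames(x$values), each = nrow(x$values)),
    influence = as.vector(x$values)
  )
  out <- dplyr::left_join(out, x$eligibility[, c("regulator", "status")],
                          by = "regulator")
  if (!is.null(x$design)) {
    out <- dplyr::left_join(out, x$design, by = "sample")
  }
  out$active <- is_active(out$influence)
  out
}

#' @describeIn influence_matrix `glance()` returns one-row summary counts.
#' @method glance influence_matrix
#' @export
glance.influence_matrix <- function(x, ...) {
  tibble::tibble(
    n_regulators = nrow(x$values),
    n_samples = ncol(x$values),
    n_eligible = sum(x$eligibility$status == "eligible"),
    n_one_sided = sum(x$eligibility$status == "one-sided-fallback"),
    n_too_few = sum(x$eligibility$status == "too-few-targets"),
    overlap_fraction = x$overlap_fraction
  )
}

#' Write an influence matrix (plus eligibility sidecar) to TSV
#'
#' @param infl An `influence_matrix`.
#' @param path Matrix TSV path (regulators x samples).
#' @param eligibility_path Optional sidecar TSV path.
#' @return `path`, invisibly.
#' @export
write_influence <- function(infl, path, eligibility_path = NULL) {
  tab <- tibble::as_tibble(infl$values, rownames = "regulator")
  write_tsv_plain(tab, path)
  if (!is.null(eligibility_path)) {
    write_tsv_plain(infl$eligibility, eligibility_path)
  }
  invisible(path)
}
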