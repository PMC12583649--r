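#' Welch two-sample test
#'
#' Standard Welch unequal-variance t statistic with Welch-Satterthwaite
#' degrees of freedom and a two-sided p-value; `delta` is
#' `mean(values_b) - mean(values_a)` so that positive values mean "higher
#' in B".
#'
#' @param values_a,values_b Numeric vectors, each of length >= 2 with
#'   finite variance.
#' @return A one-row tibble: `delta`, `t_value`, `df`, `p_value`.
#' @export
welch_two_sample <- function(values_a, values_b) {
  if (length(values_a) < 2 || length(values_b) < 2) {
    abort("each group needs at least 2 values", class = "coregulon_test_error")
  }
  if (var(values_a) == 0 && var(values_b) == 0) {
    # degenerate: no variance anywhere; t is 0/0 -> define as no evidence
    return(tibble::tibble(delta = mean(values_b) - mean(values_a),
                          t_value = 0, df = NA_real_, p_value = 1))
  }
  ht <- t.test(values_b, values_a, var.equal = FALSE)
  tibble::tibble(delta = mean(values_b) - mean(values_a),
                 t_value = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p_value = ht$p.value)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement;
#' the adjusted values map back to the input positions.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]` (`NA` allowed and
#'   propagated).
#' @return Adjusted p-values, same length and order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bh_adjust <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1)) {
    abort("p-values must lie in [0, 1]", class = "coregulon_test_error")
  }
  p.adjust(p_values, method = "BH")
}

#' Differentially influential regulators (DIRs) between two conditions
#'
#' Per eligible regulator, a Welch test compares its influence values
#' between `condition_a` and `condition_b`; p-values are BH-adjusted
#' across regulators.  A regulator is classified `up` when
#' `adj_p < max_adj_p` and `delta > min_delta` (strictly), `down`
#' symmetrically, else `ns`.  `delta` is the raw difference of condition
#' mean influences (B minus A).
#'
#' With `moderate = TRUE` the per-feature variances are shrunk toward a
#' common prior (empirical-Bayes squeeze) and moderated t statistics with
#' augmented degrees of freedom replace the Welch test — useful at small
#' group sizes where per-feature variances are noisy.
#'
#' @param infl An [influence_matrix()] whose query carried a design.
#' @param condition_a,condition_b Condition labels; the contrast is B vs A.
#' @param max_adj_p Adjusted-p cut (default 0.05).
#' @param min_delta Influence-difference cut (default 0.5, strict).
#' @param moderate Use empirical-Bayes variance moderation instead of
#'   per-feature Welch tests (default `FALSE`).
#' @return A tibble with one row per tested regulator: `feature_id`,
#'   `n_targets`, `mean_a`, `mean_b`, `delta`, `t_value`, `p_value`,
#'   `adj_p`, `class`.
#' @export
identify_dirs <- function(infl, condition_a, condition_b,
                          max_adj_p = 0.05, min_delta = 0.5,
                          moderate = FALSE) {
  if (is.null(infl$design)) {
    abort("influence matrix carries no design", class = "coregulon_design_error")
  }
  cond <- setNames(infl$design$condition, infl$design$sample)
  check_contrast(cond, condition_a, condition_b)
  sa <- names(cond)[cond == condition_a]
  sb <- names(cond)[cond == condition_b]
  usable <- infl$eligibility$status %in% c("eligible", "one-sided-fallback")
  regs <- rownames(infl$values)[usable]
  n_targets <- with(infl$eligibility,
                    setNames(n_activated + n_repressed, regulator))
  rows <- purrr::map_dfr(regs, function(r) {
    va <- infl$values[r, sa]; vb <- infl$values[r, sb]
    va <- va[!is.na(va)]; vb <- vb[!is.na(vb)]
    if (length(va) < 2 || length(vb) < 2) return(NULL)
    w <- welch_two_sample(va, vb)
    tibble::tibble(feature_id = r, n_targets = unname(n_targets[r]),
                   mean_a = mean(va), mean_b = mean(vb),
                   delta = w$delta, t_value = w$t_value, p_value = w$p_value,
                   n_a = length(va), n_b = length(vb),
                   s2 = (sum((va - mean(va))^2) + sum((vb - mean(vb))^2)) /
                     (length(va) + length(vb) - 2))
  })
  if (nrow(rows) == 0) {
    abort("no regulator testable in this contrast",
          class = "coregulon_test_error")
  }
  if (moderate) {
    mod <- moderated_stats(rows$delta, rows$s2, rows$n_a, rows$n_b)
    rows$t_value <- mod$t
    rows$p_value <- mod$p
  }
  rows$n_a <- rows$n_b <- rows$s2 <- NULL
  rows$adj_p <- bh_adjust(rows$p_value)
  rows$class <- classify_change(rows$delta, rows$adj_p, max_adj_p, min_delta)
  dplyr::arrange(rows, .data$adj_p, dplyr::desc(abs(.data$delta)),
                 .data$feature_id)
}

#' Differentially expressed genes (DEGs) between two conditions
#'
#' Per gene, a Welch test on log2-scale expression; `log2_fc` is the
#' condition-mean difference (B minus A).  BH across genes; `up` when
#' `adj_p < max_adj_p` and fold change strictly exceeds `min_fold_change`
#' (i.e. `log2_fc > log2(min_fold_change)`), `down` symmetrically.
#'
#' @param expr A log2-scale [expression_dataset()] with a design.
#' @param condition_a,condition_b Condition labels; the contrast is B vs A.
#' @param max_adj_p Adjusted-p cut (default 0.05).
#' @param min_fold_change Fold-change cut on the natural scale
#'   (default 1.5, strict).
#' @param moderate Use empirical-Bayes variance moderation instead of
#'   per-gene Welch tests (default `FALSE`).
#' @return A tibble with one row per gene: `feature_id`, `mean_a`,
#'   `mean_b`, `log2_fc`, `t_value`, `p_value`, `adj_p`, `class`.
#' @export
identify_degs <- function(expr, condition_a, condition_b,
                          max_adj_p = 0.05, min_fold_change = 1.5,
                          moderate = FALSE) {
  cond <- conditions_of(expr)
  check_contrast(cond, condition_a, condition_b)
  sa <- names(cond)[cond == condition_a]
  sb <- names(cond)[cond == condition_b]
  m <- expr$values
  rows <- purrr::map_dfr(rownames(m), function(g) {
    w <- welch_two_sample(m[g, sa], m[g, sb])
    tibble::tibble(feature_id = g, mean_a = mean(m[g, sa]),
                   mean_b = mean(m[g, sb]), log2_fc = w$delta,
                   t_value = w$t_value, p_value = w$p_value)
  })
  if (moderate) {
    s2 <- (rowSums((m[, sa] - rowMeans(m[, sa, drop = FALSE]))^2) +
             rowSums((m[, sb] - rowMeans(m[, sb, drop = FALSE]))^2)) /
      (length(sa) + length(sb) - 2)
    mod <- moderated_stats(rows$mean_b - rows$mean_a,
                           unname(s2[rows$feature_id]),
                           length(sa), length(sb))
    rows$t_value <- mod$t
    rows$p_value <- mod$p
  }
  rows$adj_p <- bh_adjust(rows$p_value)
  rows$class <- classify_change(rows$log2_fc, rows$adj_p, max_adj_p,
                                log2(min_fold_change))
  dplyr::arrange(rows, .data$adj_p, dplyr::desc(abs(.data$log2_fc)),
                 .data$feature_id)
}

# Empirical-Bayes moderated two-group statistics: per-feature pooled
# variances are squeezed toward a common prior (limma's squeezeVar) and the
# t statistic gains the prior degrees of freedom.
moderated_stats <- function(delta, s2, n_a, n_b) {
  df_res <- n_a + n_b - 2
  sq <- limma::squeezeVar(s2, df = df_res)
  t <- delta / sqrt(sq$var.post * (1 / n_a + 1 / n_b))
  df_total <- df_res + sq$df.prior
  df_total <- pmin(df_total, 1e6)
  list(t = t, p = 2 * pt(-abs(t), df = df_total))
}

check_contrast <- function(cond, condition_a, condition_b) {
  for (cc in c(condition_a, condition_b)) {
    n <- sum(cond == cc)
    if (n == 0) {
      abort(sprintf("condition %s not present in design", cc),
            class = "coregulon_design_error")
    }
    if (n < 2) {
      abort(sprintf("condition %s has fewer than 2 samples", cc),
            class = "coregulon_design_error")
    }
  }
}

# Strict threshold classification shared by DIRs and DEGs.
classify_change <- function(delta, adj_p, max_adj_p, min_delta) {
  dplyr::case_when(
    adj_p < max_adj_p & delta > min_delta ~ "up",
    adj_p < max_adj_p & delta < -min_delta ~ "down",
    .default = "ns"
  )
}

#' Hypergeometric over-representation of a gene set in a query list
#'
#' Upper-tail hypergeometric probability `P(X >= overlap)` of seeing at
#' least the observed overlap when `|query|` genes are drawn from the
#' universe with `|gene_set|` marked.
#'
#' @param query_genes Character vector (e.g. DEGs), a subset of `universe`.
#' @param gene_set Character vector (annotation set), subset of `universe`.
#' @param universe Character vector of all considered genes.
#' @return A one-row tibble: `overlap`, `n_query`, `n_set`, `n_universe`,
#'   `gene_ratio`, `p_value`.
#' @export
hypergeom_enrichment <- function(query_genes, gene_set, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) {
    abort("empty universe", class = "coregulon_test_error")
  }
  query_genes <- unique(query_genes)
  gene_set <- unique(gene_set)
  if (length(query_genes) == 0) {
    abort("empty query", class = "coregulon_test_error")
  }
  bad <- c(setdiff(query_genes, universe), setdiff(gene_set, universe))
  if (length(bad) > 0) {
    abort(paste0("genes outside the universe: ",
                 paste(head(bad, 5), collapse = ", ")),
          class = "coregulon_test_error")
  }
  k <- length(intersect(query_genes, gene_set))
  p <- phyper(k - 1, length(gene_set),
              length(universe) - length(gene_set),
              length(query_genes), lower.tail = FALSE)
  tibble::tibble(overlap = k, n_query = length(query_genes),
                 n_set = length(gene_set), n_universe = length(universe),
                 gene_ratio = k / length(query_genes), p_value = p)
}

#' Batch over-representation across a gene-set collection
#'
#' Applies [hypergeom_enrichment()] to every set in a collection, adjusts
#' p-values with BH across sets, and reports gene ratios
#' (overlap / query size).
#'
#' @param query_genes Character vector of query genes.
#' @param collection Named list of character vectors (e.g. read with
#'   [read_gmt()]).
#' @param universe Character vector of all considered genes.
#' @return A tibble with one row per set: `set_name`, the
#'   [hypergeom_enrichment()] columns, and `adj_p`.
#' @export
enrich_gene_sets <- function(query_genes, collection, universe) {
  if (length(collection) == 0 || is.null(names(collection))) {
    abort("collection must be a non-empty named list",
          class = "coregulon_test_error")
  }
  out <- purrr::imap_dfr(collection, function(genes, nm) {
    res <- hypergeom_enrichment(query_genes,
                                intersect(genes, universe), universe)
    dplyr::bind_cols(tibble::tibble(set_name = nm), res)
  })
  out$adj_p <- bh_adjust(out$p_value)
  dplyr::arrange(out, .data$p_value, .data$set_name)
}

#' Read a gene-set collection in GMT format
#'
#' Tab-separated lines: set name, description, then member genes.
#'
#' @param path GMT file path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  setNames(lapply(parts, function(p) unique(p[-(1:2)])),
           vapply(parts, `[[`, character(1), 1))
}
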