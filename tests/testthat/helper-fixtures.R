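# Shared fixture builders; everything is generated in code.

toy_expr <- function(values, conditions = NULL) {
  if (is.null(conditions)) return(expression_dataset(values))
  expression_dataset(values, tibble::tibble(sample = colnames(values),
                                            condition = conditions))
}

# A discrete matrix built directly from integer states.
toy_disc <- function(states) {
  structure(states, class = c("discrete_matrix", class(states)))
}

# Small deterministic network from a compact spec list:
# list(g1 = list(a = c("r1"), i = c("r2")), ...)
toy_network <- function(spec, fit = 0, support = 0) {
  regulatory_network(tibble::tibble(
    target = names(spec),
    activators = vapply(spec, function(p)
      paste(sort(p$a %||% character(0)), collapse = ";"), character(1)),
    repressors = vapply(spec, function(p)
      paste(sort(p$i %||% character(0)), collapse = ";"), character(1)),
    fit_score = fit,
    evidence_support = support
  ))
}

`%||%` <- rlang::`%||%`

# Independent oracle for the per-sample regulator influence: a direct
# transcription of the Welch-type regulon contrast.
influence_oracle <- function(a_vals, i_vals) {
  (mean(a_vals) - mean(i_vals)) /
    sqrt(sd(a_vals)^2 / length(a_vals) + sd(i_vals)^2 / length(i_vals))
}

# Independent oracle for Benjamini-Hochberg: literal step-up definition,
# adj_(i) = min_{j >= i} min(1, n * p_(j) / j) on the sorted vector.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- pmin(1, n * ps / seq_len(n))
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- adj
  out
}

# Exact upper-tail hypergeometric by enumeration over the overlap count.
hyper_oracle <- function(overlap, n_set, n_universe, n_query) {
  ks <- overlap:min(n_set, n_query)
  sum(choose(n_set, ks) * choose(n_universe - n_set, n_query - ks)) /
    choose(n_universe, n_query)
}

# Brute-force connected components (BFS) for small undirected graphs.
components_oracle <- function(nodes, edges_from, edges_to) {
  comp <- setNames(rep(NA_integer_, length(nodes)), nodes)
  cid <- 0L
  for (start in nodes) {
    if (!is.na(comp[start])) next
    cid <- cid + 1L
    queue <- start
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      nb <- c(edges_to[edges_from == v], edges_from[edges_to == v])
      queue <- c(queue, setdiff(nb, names(comp)[!is.na(comp)]))
    }
  }
  split(names(comp), comp)
}
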