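#' Discretize an expression matrix into under/baseline/over states
#'
#' Each gene is standardized across samples (mean, unbiased SD); a sample
#' gets state `+1` when its standardized value is `>= z_threshold`, `-1`
#' when `<= -z_threshold`, else `0`.  Zero-variance genes map to all-0.
#' This three-state coding is the substrate of the LICORN-style local
#' program search.
#'
#' @param expr An [expression_dataset()] (or a bare genes-by-samples matrix).
#' @param z_threshold Standardized-score cut for calling a state (default 1
#'   SD).
#' @return An integer matrix of the same shape with values in `{-1, 0, 1}`,
#'   class `discrete_matrix`.
#' @examples
#' m <- matrix(c(1, 2, 3, 4, 5), 1, 5,
#'             dimnames = list("g", paste0("s", 1:5)))
#' discretize(expression_dataset(m))  # +1 only at 5, -1 only at 1
#' @export
discretize <- function(expr, z_threshold = 1.0) {
  m <- if (inherits(expr, "expression_dataset")) expr$values else expr
  if (ncol(m) < 2) {
    abort("discretization needs at least two samples per gene",
          class = "coregulon_input_error")
  }
  mu <- rowMeans(m)
  s <- apply(m, 1, sd)
  z <- (m - mu) / ifelse(s > 0, s, Inf)   # zero-variance rows -> z = 0
  d <- matrix(0L, nrow(m), ncol(m), dimnames = dimnames(m))
  d[z >= z_threshold] <- 1L
  d[z <= -z_threshold] <- -1L
  structure(d, class = c("discrete_matrix", class(d)))
}

#' Collective state of a regulator set in one sample
#'
#' The median of the member states, mapped back to `{-1, 0, +1}` (an even
#' split with midpoint 0 returns 0).  The empty set has collective state 0.
#'
#' @param members Character vector of regulator ids.
#' @param disc A `discrete_matrix` containing those rows.
#' @param sample Sample id or column index.
#' @return An integer in `{-1, 0, 1}`.
#' @export
collective_state <- function(members, disc, sample) {
  if (length(members) == 0) return(0L)
  as.integer(sign(median(disc[members, sample])))
}

# Vectorized collective states: one row per set in `sets` (list of id
# vectors), columns = samples of `disc`.
collective_state_matrix <- function(sets, disc) {
  out <- matrix(0L, length(sets), ncol(disc),
                dimnames = list(NULL, colnames(disc)))
  for (i in seq_along(sets)) {
    mem <- sets[[i]]
    if (length(mem) == 1) {
      out[i, ] <- disc[mem, ]
    } else if (length(mem) > 1) {
      out[i, ] <- as.integer(sign(apply(disc[mem, , drop = FALSE], 2, median)))
    }
  }
  out
}

#' Predicted target state from collective activator and repressor states
#'
#' `sign(sA - sI)`: activators up or repressors down push the target up;
#' concordant activator and repressor states cancel.
#'
#' @param s_activators,s_repressors Collective states in `{-1, 0, 1}`.
#' @return Predicted target state in `{-1, 0, 1}`.
#' @export
predict_target <- function(s_activators, s_repressors) {
  as.integer(sign(s_activators - s_repressors))
}

#' Score a local program against a target's discrete profile
#'
#' Mean absolute difference, over samples, between the program's predicted
#' state (`predict_target` of the collective activator and repressor
#' states) and the target's observed discrete state.  Range `[0, 2]`;
#' 0 is a perfect fit.
#'
#' @param target Target gene id.
#' @param activators,repressors Character vectors of regulator ids (either
#'   may be empty, not both).
#' @param disc A `discrete_matrix` containing the target and regulators.
#' @return The fit score (numeric scalar).
#' @export
score_program <- function(target, activators, repressors, disc) {
  obs <- disc[target, ]
  s_a <- vapply(colnames(disc), function(s)
    collective_state(activators, disc, s), integer(1))
  s_i <- vapply(colnames(disc), function(s)
    collective_state(repressors, disc, s), integer(1))
  mean(abs(predict_target(s_a, s_i) - obs))
}
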