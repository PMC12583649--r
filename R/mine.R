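#' Mine co-regulator candidate sets by level-wise (apriori) search
#'
#' A regulator set is *jointly active* in a sample when all members are `+1`
#' or all members are `-1` there; its support is the fraction of such
#' samples.  All sets up to `max_set_size` with support `>= min_support`
#' are returned via an apriori level-wise search (support is anti-monotone:
#' every subset of a frequent set is frequent).  Ordering is deterministic:
#' support descending, then lexicographic on the `;`-joined member key.
#'
#' @param disc A `discrete_matrix` (see [discretize()]).
#' @param regulators Character vector of regulator ids present in `disc`.
#' @param min_support Minimum joint-activity support (fraction of samples).
#' @param max_set_size Largest set size explored.
#' @return A tibble with columns `key` (`;`-joined sorted members),
#'   `members` (list-column), `size`, `support`.
#' @export
mine_candidates <- function(disc, regulators, min_support = 0.1,
                            max_set_size = 4) {
  assert_fraction(min_support, "min_support")
  missing <- setdiff(regulators, rownames(disc))
  if (length(missing) > 0) {
    abort(paste0("regulators absent from discrete matrix: ",
                 paste(head(missing, 5), collapse = ", ")),
          class = "coregulon_input_error")
  }
  regulators <- sort(regulators)
  n_s <- ncol(disc)
  up <- disc[regulators, , drop = FALSE] == 1L
  dn <- disc[regulators, , drop = FALSE] == -1L

  support_of <- function(members) {
    u <- up[members, , drop = FALSE]
    d <- dn[members, , drop = FALSE]
    k <- length(members)
    (sum(colSums(u) == k) + sum(colSums(d) == k)) / n_s
  }

  # level 1
  supp1 <- (rowSums(up) + rowSums(dn)) / n_s
  frequent <- list()
  level <- lapply(regulators[supp1 >= min_support], identity)
  level_supp <- supp1[supp1 >= min_support]
  if (length(level) > 0) {
    frequent[[1]] <- tibble::tibble(
      key = unlist(level), members = level, size = 1L,
      support = as.numeric(level_supp)
    )
  }
  k <- 1L
  while (k < max_set_size && length(level) > 1) {
    prev_keys <- vapply(level, set_key, character(1))
    cand <- list()
    # join step: members sorted; merge sets sharing the first k-1 items
    for (i in seq_along(level)) {
      for (j in seq_along(level)) {
        if (j <= i) next
        a <- level[[i]]; b <- level[[j]]
        if (k == 1L || identical(a[seq_len(k - 1)], b[seq_len(k - 1)])) {
          merged <- sort(union(a, b))
          if (length(merged) == k + 1) {
            # prune: every k-subset must be frequent
            subs <- vapply(seq_len(k + 1), function(d)
              set_key(merged[-d]), character(1))
            if (all(subs %in% prev_keys)) cand[[set_key(merged)]] <- merged
          }
        }
      }
    }
    if (length(cand) == 0) break
    supp <- vapply(cand, support_of, numeric(1))
    keep <- supp >= min_support
    level <- unname(cand[keep])
    level_supp <- unname(supp[keep])
    k <- k + 1L
    if (length(level) > 0) {
      frequent[[k]] <- tibble::tibble(
        key = vapply(level, set_key, character(1)),
        members = level, size = k, support = level_supp
      )
    }
  }
  out <- dplyr::bind_rows(frequent)
  if (nrow(out) == 0) {
    return(tibble::tibble(key = character(), members = list(),
                          size = integer(), support = numeric()))
  }
  dplyr::arrange(out, dplyr::desc(.data$support), .data$key)
}
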