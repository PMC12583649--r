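#' Build the co-regulatory graph of differentially influential regulators
#'
#' Nodes are regulators classified `up` or `down` in the DIR table; each
#' node carries its target count (`|A^r union I^r|`), its influence
#' difference and its class.  An edge joins two nodes when they co-occur
#' in at least `min_shared_targets` local programs, and carries one or
#' more types:
#' * `ppi_evidence` — the pair has a protein-interaction record;
#' * `transcriptional_evidence` — either regulator's own gene is an
#'   evidenced target of the other (direction recorded);
#' * `inferred_only` — co-occurrence without external evidence.
#'
#' @param network A `regulatory_network`.
#' @param dirs DIR table from [identify_dirs()] computed on this network.
#' @param evidence An [evidence_set()].
#' @param min_shared_targets Minimum shared-program count for an edge.
#' @return A `coreg_graph`: `nodes` tibble (`regulator`, `n_targets`,
#'   `delta_influence`, `class`) and `edges` tibble (`from`, `to`,
#'   `shared_target_count`, logical type columns, `tr_direction`).
#' @export
build_coreg_graph <- function(network, dirs, evidence,
                              min_shared_targets = 1) {
  dirs_sig <- dirs[dirs$class %in% c("up", "down"), , drop = FALSE]
  rv <- regulon_view(network)
  n_targets <- vapply(dirs_sig$feature_id, function(r)
    length(unique(rv$target[rv$regulator == r])), integer(1))
  nodes <- tibble::tibble(
    regulator = dirs_sig$feature_id,
    n_targets = unname(n_targets),
    delta_influence = dirs_sig$delta,
    class = dirs_sig$class
  )
  nodes <- dplyr::arrange(nodes, .data$regulator)

  edges <- tibble::tibble(from = character(), to = character(),
                          shared_target_count = integer(),
                          ppi_evidence = logical(),
                          transcriptional_evidence = logical(),
                          inferred_only = logical(),
                          tr_direction = character())
  if (nrow(nodes) >= 2) {
    # shared-program counts among node regulators
    progs <- network$programs
    node_set <- nodes$regulator
    pair_counts <- list()
    for (i in seq_len(nrow(progs))) {
      mem <- intersect(c(key_to_set(progs$activators[i]),
                         key_to_set(progs$repressors[i])), node_set)
      if (length(mem) < 2) next
      pr <- combn(sort(mem), 2)
      for (j in seq_len(ncol(pr))) {
        k <- pair_key(pr[1, j], pr[2, j])
        pair_counts[[k]] <- (pair_counts[[k]] %||% 0L) + 1L
      }
    }
    keep <- names(pair_counts)[unlist(pair_counts) >= min_shared_targets]
    if (length(keep) > 0) {
      pp <- ppi_keys(evidence)
      tfk <- tf_target_keys(evidence)
      parts <- strsplit(keep, "|", fixed = TRUE)
      edges <- purrr::map_dfr(seq_along(keep), function(ii) {
        a <- parts[[ii]][1]; b <- parts[[ii]][2]
        has_ppi <- keep[ii] %in% pp
        ab <- paste(a, b, sep = "->") %in% tfk
        ba <- paste(b, a, sep = "->") %in% tfk
        tr_dir <- if (ab && ba) "both" else if (ab) "a->b" else
          if (ba) "b->a" else NA_character_
        tibble::tibble(
          from = a, to = b,
          shared_target_count = as.integer(pair_counts[[keep[ii]]]),
          ppi_evidence = has_ppi,
          transcriptional_evidence = ab || ba,
          inferred_only = !has_ppi && !(ab || ba),
          tr_direction = tr_dir
        )
      })
      edges <- dplyr::arrange(edges, .data$from, .data$to)
    }
  }
  structure(list(nodes = nodes, edges = edges), class = "coreg_graph")
}

#' @export
print.coreg_graph <- function(x, ...) {
  cat(sprintf("<coreg_graph> %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' @describeIn build_coreg_graph `tidy()` returns the edge table with node
#'   classes joined on.
#' @param x A `coreg_graph`.
#' @param ... Unused.
#' @method tidy coreg_graph
#' @export
tidy.coreg_graph <- function(x, ...) {
  e <- x$edges
  e <- dplyr::left_join(e, dplyr::rename(x$nodes, from = "regulator",
                                         from_class = "class")[,
                          c("from", "from_class")], by = "from")
  dplyr::left_join(e, dplyr::rename(x$nodes, to = "regulator",
                                    to_class = "class")[, c("to", "to_class")],
                   by = "to")
}

#' @describeIn build_coreg_graph `glance()` returns one-row graph counts.
#' @method glance coreg_graph
#' @export
glance.coreg_graph <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x$nodes),
    n_up = sum(x$nodes$class == "up"),
    n_down = sum(x$nodes$class == "down"),
    n_edges = nrow(x$edges),
    n_ppi_edges = sum(x$edges$ppi_evidence),
    n_transcriptional_edges = sum(x$edges$transcriptional_evidence),
    n_inferred_only_edges = sum(x$edges$inferred_only)
  )
}

#' Extract the largest regulatory node of co-influenced regulators
#'
#' Restricts the co-regulatory graph to nodes of the requested class and
#' returns the largest connected component (ties broken by the
#' lexicographically smallest member).  Mirrors the notion of a
#' cooperating master-regulator node.
#'
#' @param graph A `coreg_graph`.
#' @param direction `"up"` or `"down"`.
#' @return A list with `members` (sorted character vector) and `size`.
#' @export
extract_regulatory_node <- function(graph, direction = c("up", "down")) {
  direction <- match.arg(direction)
  keep <- graph$nodes$regulator[graph$nodes$class == direction]
  if (length(keep) == 0) return(list(members = character(0), size = 0L))
  e <- graph$edges[graph$edges$from %in% keep & graph$edges$to %in% keep, ,
                   drop = FALSE]
  g <- igraph::graph_from_data_frame(e[, c("from", "to")], directed = FALSE,
                                     vertices = data.frame(name = keep))
  comp <- igraph::components(g)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    firsts <- vapply(best, function(ci)
      min(names(comp$membership)[comp$membership == ci]), character(1))
    best <- best[order(firsts)][1]
  }
  members <- sort(names(comp$membership)[comp$membership == best])
  list(members = members, size = length(members))
}

#' Mean group influence of a regulator node
#'
#' The arithmetic mean of the members' influence differences — a summary
#' of how strongly a cooperating node shifts between conditions.
#'
#' @param members Character vector of node members.
#' @param dirs DIR table containing those regulators.
#' @return Numeric scalar.
#' @export
mean_group_influence <- function(members, dirs) {
  if (length(members) == 0) {
    abort("empty node has no mean group influence",
          class = "coregulon_input_error")
  }
  missing <- setdiff(members, dirs$feature_id)
  if (length(missing) > 0) {
    abort(paste0("members absent from DIR table: ",
                 paste(missing, collapse = ", ")),
          class = "coregulon_input_error")
  }
  mean(dirs$delta[match(members, dirs$feature_id)])
}

#' Export / import a co-regulatory graph
#'
#' `format = "graphml"` writes GraphML with node attributes
#' (`n_targets`, `delta_influence`, `class`) and typed edges; evidenced
#' transcriptional edges are directed (per `tr_direction`), co-occurrence
#' and PPI edges undirected.  `format = "sif"` writes one row per edge
#' *type*.  `import_graphml()` re-reads a written GraphML file into an
#' identical `coreg_graph`.
#'
#' @param graph A `coreg_graph`.
#' @param path Output path.
#' @param format `"graphml"` or `"sif"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(graph, path, format = c("graphml", "sif")) {
  format <- match.arg(format)
  if (format == "sif") {
    lines <- character(0)
    e <- graph$edges
    for (i in seq_len(nrow(e))) {
      if (e$ppi_evidence[i]) {
        lines <- c(lines, paste(e$from[i], "ppi_evidence", e$to[i], sep = "\t"))
      }
      if (e$transcriptional_evidence[i]) {
        src <- if (identical(e$tr_direction[i], "b->a")) e$to[i] else e$from[i]
        dst <- if (identical(e$tr_direction[i], "b->a")) e$from[i] else e$to[i]
        lines <- c(lines,
                   paste(src, "transcriptional_evidence", dst, sep = "\t"))
      }
      if (e$inferred_only[i]) {
        lines <- c(lines, paste(e$from[i], "inferred_only", e$to[i], sep = "\t"))
      }
    }
    # isolated nodes still appear as single-column rows
    iso <- setdiff(graph$nodes$regulator, c(graph$edges$from, graph$edges$to))
    writeLines(c(lines, iso), path)
    return(invisible(path))
  }
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  n <- graph$nodes
  e <- graph$edges
  out <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    "<graphml xmlns=\"http://graphml.graphdrawing.org/xmlns\">",
    "  <key id=\"n_targets\" for=\"node\" attr.name=\"n_targets\" attr.type=\"int\"/>",
    "  <key id=\"delta_influence\" for=\"node\" attr.name=\"delta_influence\" attr.type=\"double\"/>",
    "  <key id=\"class\" for=\"node\" attr.name=\"class\" attr.type=\"string\"/>",
    "  <key id=\"shared_target_count\" for=\"edge\" attr.name=\"shared_target_count\" attr.type=\"int\"/>",
    "  <key id=\"ppi_evidence\" for=\"edge\" attr.name=\"ppi_evidence\" attr.type=\"boolean\"/>",
    "  <key id=\"transcriptional_evidence\" for=\"edge\" attr.name=\"transcriptional_evidence\" attr.type=\"boolean\"/>",
    "  <key id=\"inferred_only\" for=\"edge\" attr.name=\"inferred_only\" attr.type=\"boolean\"/>",
    "  <key id=\"tr_direction\" for=\"edge\" attr.name=\"tr_direction\" attr.type=\"string\"/>",
    "  <graph id=\"coreg\" edgedefault=\"undirected\">"
  )
  for (i in seq_len(nrow(n))) {
    out <- c(out, sprintf(
      paste0("    <node id=\"%s\"><data key=\"n_targets\">%d</data>",
             "<data key=\"delta_influence\">%s</data>",
             "<data key=\"class\">%s</data></node>"),
      esc(n$regulator[i]), n$n_targets[i],
      num_chr(n$delta_influence[i], 17), n$class[i]))
  }
  for (i in seq_len(nrow(e))) {
    directed <- e$transcriptional_evidence[i] &&
      identical(e$tr_direction[i], "b->a")
    src <- if (directed) e$to[i] else e$from[i]
    dst <- if (directed) e$from[i] else e$to[i]
    dir_attr <- if (e$transcriptional_evidence[i] &&
                    !identical(e$tr_direction[i], "both")) " directed=\"true\""
      else ""
    out <- c(out, sprintf(
      paste0("    <edge source=\"%s\" target=\"%s\"%s>",
             "<data key=\"shared_target_count\">%d</data>",
             "<data key=\"ppi_evidence\">%s</data>",
             "<data key=\"transcriptional_evidence\">%s</data>",
             "<data key=\"inferred_only\">%s</data>",
             "<data key=\"tr_direction\">%s</data></edge>"),
      esc(src), esc(dst), dir_attr,
      e$shared_target_count[i],
      tolower(e$ppi_evidence[i]), tolower(e$transcriptional_evidence[i]),
      tolower(e$inferred_only[i]),
      ifelse(is.na(e$tr_direction[i]), "", e$tr_direction[i])))
  }
  out <- c(out, "  </graph>", "</graphml>")
  writeLines(out, path)
  invisible(path)
}

#' @rdname export_graph
#' @export
import_graphml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "g")
  node_xml <- xml2::xml_find_all(doc, ".//g:node", ns)
  get_data <- function(x, key) {
    xml2::xml_text(xml2::xml_find_first(
      x, sprintf(".//g:data[@key='%s']", key), ns))
  }
  nodes <- purrr::map_dfr(node_xml, function(x) tibble::tibble(
    regulator = xml2::xml_attr(x, "id"),
    n_targets = as.integer(get_data(x, "n_targets")),
    delta_influence = as.numeric(get_data(x, "delta_influence")),
    class = get_data(x, "class")
  ))
  edge_xml <- xml2::xml_find_all(doc, ".//g:edge", ns)
  edges <- purrr::map_dfr(edge_xml, function(x) {
    src <- xml2::xml_attr(x, "source")
    dst <- xml2::xml_attr(x, "target")
    a <- min(src, dst); b <- max(src, dst)
    tr_raw <- get_data(x, "tr_direction")
    tibble::tibble(
      from = a, to = b,
      shared_target_count = as.integer(get_data(x, "shared_target_count")),
      ppi_evidence = get_data(x, "ppi_evidence") == "true",
      transcriptional_evidence =
        get_data(x, "transcriptional_evidence") == "true",
      inferred_only = get_data(x, "inferred_only") == "true",
      tr_direction = ifelse(nzchar(tr_raw), tr_raw, NA_character_)
    )
  })
  if (nrow(edges) == 0) {
    edges <- tibble::tibble(from = character(), to = character(),
                            shared_target_count = integer(),
                            ppi_evidence = logical(),
                            transcriptional_evidence = logical(),
                            inferred_only = logical(),
                            tr_direction = character())
  } else {
    edges <- dplyr::arrange(edges, .data$from, .data$to)
  }
  nodes <- if (nrow(nodes) == 0) {
    tibble::tibble(regulator = character(), n_targets = integer(),
                   delta_influence = numeric(), class = character())
  } else dplyr::arrange(nodes, .data$regulator)
  structure(list(nodes = nodes, edges = edges), class = "coreg_graph")
}

#' Target sub-matrix and regulation-direction table for chosen regulators
#'
#' Rows are the union of the chosen regulators' regulon genes intersected
#' with DEG-classified (`up`/`down`) genes, ordered by class then
#' decreasing `|log2_fc|`; each row is annotated `+1` (activated) or `-1`
#' (repressed) per regulator-gene relation (a gene may carry both, from
#' different regulators).  Optionally truncated to the `top_n` most
#' regulated targets.
#'
#' @param network A `regulatory_network`.
#' @param degs DEG table from [identify_degs()].
#' @param regulators Character vector of regulators in the network.
#' @param expr Optional [expression_dataset()] supplying the expression
#'   sub-matrix for the selected rows.
#' @param top_n Optional row cap (e.g. 50).
#' @return A list: `directions` (tibble `gene`, `regulator`, `direction`,
#'   `class`, `log2_fc`), `genes` (ordered), and `matrix` (genes x
#'   samples, `NULL` without `expr`).
#' @export
target_matrix <- function(network, degs, regulators, expr = NULL,
                          top_n = NULL) {
  missing <- setdiff(regulators, network_regulators(network))
  if (length(missing) > 0) {
    abort(paste0("regulators not in network: ",
                 paste(missing, collapse = ", ")),
          class = "coregulon_network_error")
  }
  rv <- regulon_view(network)
  rv <- rv[rv$regulator %in% regulators, , drop = FALSE]
  deg_sig <- degs[degs$class %in% c("up", "down"), , drop = FALSE]
  rows <- dplyr::inner_join(rv, deg_sig, by = c(target = "feature_id"))
  if (nrow(rows) == 0) {
    return(list(directions = tibble::tibble(gene = character(),
                                            regulator = character(),
                                            direction = integer(),
                                            class = character(),
                                            log2_fc = numeric()),
                genes = character(0), matrix = NULL))
  }
  directions <- tibble::tibble(
    gene = rows$target,
    regulator = rows$regulator,
    direction = ifelse(rows$role == "activates", 1L, -1L),
    class = rows$class,
    log2_fc = rows$log2_fc
  )
  ord <- dplyr::distinct(directions, .data$gene, .data$class, .data$log2_fc)
  ord <- dplyr::arrange(ord, .data$class != "up",
                        dplyr::desc(abs(.data$log2_fc)), .data$gene)
  genes <- ord$gene
  if (!is.null(top_n) && length(genes) > top_n) genes <- genes[seq_len(top_n)]
  directions <- directions[directions$gene %in% genes, , drop = FALSE]
  directions <- directions[order(match(directions$gene, genes)), , drop = FALSE]
  m <- NULL
  if (!is.null(expr)) {
    present <- genes[genes %in% rownames(expr$values)]
    m <- expr$values[present, , drop = FALSE]
  }
  list(directions = directions, genes = genes, matrix = m)
}
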