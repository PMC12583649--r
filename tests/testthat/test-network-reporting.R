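dirs_table <- function(ids, deltas, classes) {
  tibble::tibble(feature_id = ids, n_targets = 5L, mean_a = 0,
                 mean_b = deltas, delta = deltas, t_value = deltas,
                 p_value = 0.01, adj_p = 0.01, class = classes)
}

test_that("co-regulatory edges carry shared-target counts and types", {
  spec <- setNames(lapply(1:30, function(i) list(a = c("r1", "r2"))),
                   paste0("g", 1:30))
  net <- toy_network(spec)
  dirs <- dirs_table(c("r1", "r2"), c(1.2, 0.9), c("up", "up"))
  ev <- evidence_set(ppi = data.frame(regulator_a = "r1", regulator_b = "r2",
                                      source = "ppi"))
  g <- build_coreg_graph(net, dirs, ev)
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$edges$shared_target_count, 30L)
  expect_true(g$edges$ppi_evidence)
  expect_false(g$edges$transcriptional_evidence)
  expect_false(g$edges$inferred_only)
  expect_equal(g$nodes$n_targets, c(30L, 30L))

  # no shared targets -> no edge; no evidence -> inferred_only
  net2 <- toy_network(list(g1 = list(a = "r1"), g2 = list(a = "r2")))
  g2 <- build_coreg_graph(net2, dirs, ev)
  expect_equal(nrow(g2$edges), 0)
  net3 <- toy_network(list(g1 = list(a = c("r1", "r2"))))
  g3 <- build_coreg_graph(net3, dirs, evidence_set())
  expect_true(g3$edges$inferred_only)

  # transcriptional evidence: one regulator's gene is a target of the other
  ev_tr <- evidence_set(tf_target = data.frame(regulator = "r1",
                                               target = "r2", source = "chip"))
  g4 <- build_coreg_graph(net3, dirs, ev_tr)
  expect_true(g4$edges$transcriptional_evidence)
  expect_equal(g4$edges$tr_direction, "a->b")
})

test_that("only up/down regulators become nodes; min_shared_targets filters", {
  net <- toy_network(list(g1 = list(a = c("r1", "r2")),
                          g2 = list(a = c("r1", "r3"))))
  dirs <- dirs_table(c("r1", "r2", "r3"), c(1, 0.9, 0.1),
                     c("up", "up", "ns"))
  g <- build_coreg_graph(net, dirs, evidence_set())
  expect_setequal(g$nodes$regulator, c("r1", "r2"))
  g2 <- build_coreg_graph(net, dirs, evidence_set(), min_shared_targets = 2)
  expect_equal(nrow(g2$edges), 0)
})

test_that("regulatory-node extraction finds the largest up component", {
  nodes <- letters[1:6]
  net <- toy_network(list(g1 = list(a = c("a", "b")),
                          g2 = list(a = c("b", "c")),
                          g3 = list(a = c("d", "e"))))
  dirs <- dirs_table(nodes, rep(1, 6), rep("up", 6))
  g <- build_coreg_graph(net, dirs, evidence_set())
  node <- extract_regulatory_node(g, "up")
  expect_equal(node$members, c("a", "b", "c"))
  expect_equal(node$size, 3L)

  # fully connected set of six up regulators -> one six-member node
  specs <- lapply(combn(nodes, 2, simplify = FALSE), function(p) list(a = p))
  names(specs) <- paste0("g", seq_along(specs))
  g6 <- build_coreg_graph(toy_network(specs), dirs, evidence_set())
  expect_equal(extract_regulatory_node(g6, "up")$size, 6L)

  # no up nodes -> empty node
  dn <- dirs_table(nodes, rep(-1, 6), rep("down", 6))
  gg <- build_coreg_graph(net, dn, evidence_set())
  expect_equal(extract_regulatory_node(gg, "up")$size, 0L)
})

test_that("component extraction matches brute-force BFS on random graphs", {
  set.seed(42)
  for (rep in 1:10) {
    n <- sample(4:12, 1)
    ids <- paste0("r", seq_len(n))
    npairs <- combn(ids, 2)
    pick <- runif(ncol(npairs)) < 0.2
    spec <- lapply(which(pick), function(j) list(a = npairs[, j]))
    if (length(spec) == 0) spec <- list(list(a = ids[1:2]))
    names(spec) <- paste0("g", seq_along(spec))
    net <- toy_network(spec)
    dirs <- dirs_table(ids, rep(1, n), rep("up", n))
    g <- build_coreg_graph(net, dirs, evidence_set())
    got <- extract_regulatory_node(g, "up")
    comps <- components_oracle(g$nodes$regulator, g$edges$from, g$edges$to)
    sizes <- lengths(comps)
    expect_equal(got$size, max(sizes))
    best <- comps[sizes == max(sizes)]
    firsts <- vapply(best, min, character(1))
    expect_equal(got$members, sort(best[[order(firsts)[1]]]))
  }
})

test_that("mean group influence averages member deltas", {
  dirs <- dirs_table(c("x", "y", "z"), c(1, 2, 3), rep("up", 3))
  expect_equal(mean_group_influence(c("x", "y", "z"), dirs), 2)
  expect_equal(mean_group_influence("y", dirs), 2)
  expect_error(mean_group_influence(character(0), dirs),
               class = "coregulon_input_error")
  expect_error(mean_group_influence("nope", dirs),
               class = "coregulon_input_error")
})

test_that("GraphML round-trips and SIF rows count edge types", {
  net <- toy_network(list(g1 = list(a = c("r1", "r2")),
                          g2 = list(a = c("r2", "r3"))))
  dirs <- dirs_table(c("r1", "r2", "r3"), c(1.5, 0.8, -0.9),
                     c("up", "up", "down"))
  ev <- evidence_set(
    tf_target = data.frame(regulator = "r2", target = "r1", source = "chip"),
    ppi = data.frame(regulator_a = "r1", regulator_b = "r2", source = "ppi")
  )
  g <- build_coreg_graph(net, dirs, ev)
  f <- withr::local_tempfile(fileext = ".graphml")
  export_graph(g, f, "graphml")
  back <- import_graphml(f)
  expect_equal(back$nodes, g$nodes)
  expect_equal(back$edges, g$edges)

  sif <- withr::local_tempfile(fileext = ".sif")
  export_graph(g, sif, "sif")
  rows <- readLines(sif)
  n_types <- sum(g$edges$ppi_evidence) +
    sum(g$edges$transcriptional_evidence) + sum(g$edges$inferred_only)
  iso <- setdiff(g$nodes$regulator, c(g$edges$from, g$edges$to))
  expect_equal(length(rows), n_types + length(iso))
  # directed transcriptional evidence keeps its source regulator first
  tr <- rows[grepl("transcriptional_evidence", rows)]
  expect_equal(tr, "r2\ttranscriptional_evidence\tr1")

  # empty graph exports valid documents
  empty <- build_coreg_graph(net, dirs_table("rX", 0.1, "ns"), ev)
  export_graph(empty, f, "graphml")
  expect_equal(import_graphml(f)$nodes, empty$nodes)
  export_graph(empty, sif, "sif")
  expect_equal(length(readLines(sif)), 0)
})

test_that("target matrices align regulon genes with DEG classes", {
  net <- toy_network(list(g1 = list(a = "r1", i = "r2"),
                          g2 = list(i = "r1"), g3 = list(a = "r2"),
                          g4 = list(a = "r1")))
  degs <- tibble::tibble(
    feature_id = paste0("g", 1:4), mean_a = 0, mean_b = 0,
    log2_fc = c(2, -1.5, 0.2, 1.0), t_value = 0, p_value = 0.01,
    adj_p = c(0.01, 0.01, 0.8, 0.01),
    class = c("up", "down", "ns", "up")
  )
  m <- matrix(rnorm(4 * 3), 4, 3,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
  tm <- target_matrix(net, degs, "r1", expr = toy_expr(m))
  # rows: up genes by |log2_fc| desc (g1 then g4), then down (g2)
  expect_equal(tm$genes, c("g1", "g4", "g2"))
  expect_equal(tm$directions$direction[tm$directions$gene == "g1"], 1L)
  expect_equal(tm$directions$direction[tm$directions$gene == "g2"], -1L)
  expect_equal(rownames(tm$matrix), tm$genes)

  # a gene in A of one member and I of another carries both annotations
  tm2 <- target_matrix(net, degs, c("r1", "r2"))
  g1_rows <- tm2$directions[tm2$directions$gene == "g1", ]
  expect_setequal(g1_rows$direction, c(1L, -1L))

  # top-n truncation
  tm3 <- target_matrix(net, degs, c("r1", "r2"), top_n = 2)
  expect_length(tm3$genes, 2)
  expect_error(target_matrix(net, degs, "rZ"),
               class = "coregulon_network_error")
  # empty selection stays valid
  deg_ns <- dplyr::mutate(degs, class = "ns")
  tm4 <- target_matrix(net, deg_ns, "r1")
  expect_length(tm4$genes, 0)
})
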