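test_that("welch test reproduces hand-computed statistics", {
  out <- welch_two_sample(c(1, 2, 3), c(3, 4, 5))
  expect_equal(out$delta, 2)
  expect_equal(out$t_value, 2 / sqrt(2 / 3), tolerance = 1e-12)  # ~2.4495
  expect_equal(out$p_value, t.test(c(3, 4, 5), c(1, 2, 3))$p.value)

  same <- welch_two_sample(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t_value, 0)
  expect_equal(same$delta, 0)

  sw <- welch_two_sample(c(3, 4, 5), c(1, 2, 3))
  expect_equal(sw$t_value, -out$t_value)
  expect_equal(sw$delta, -out$delta)
  expect_error(welch_two_sample(1, c(1, 2)), class = "coregulon_test_error")
})

test_that("BH adjustment matches the brute-force step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), class = "coregulon_test_error")

  set.seed(77)
  for (rep in 1:200) {
    p <- round(runif(sample(1:8, 1)), 3)
    adj <- bh_adjust(p)
    expect_equal(adj, bh_oracle(p), tolerance = 1e-12)
    # adjustment never decreases a p-value and stays in [0, 1]
    expect_true(all(adj >= p - 1e-15) && all(adj <= 1))
    # constant vectors are fixed points of the step-up adjustment
    expect_equal(bh_adjust(rep(max(adj), 4)), rep(max(adj), 4))
  }
})

test_that("DIR classification follows the strict delta and adj-p rules", {
  # construct an influence matrix with known condition separation
  net <- toy_network(list(g1 = list(a = "r1"), g2 = list(a = "r1"),
                          g3 = list(a = "r1"), g4 = list(i = "r1"),
                          g5 = list(i = "r1")))
  set.seed(8)
  m <- matrix(rnorm(8 * 12), 8, 12,
              dimnames = list(paste0("g", 1:8), paste0("s", 1:12)))
  m[1:3, 7:12] <- m[1:3, 7:12] + 3   # activated targets shift in condition b
  expr <- toy_expr(m, conditions = rep(c("a", "b"), each = 6))
  infl <- influence_matrix(expr, net, standardize = FALSE)
  dirs <- identify_dirs(infl, "a", "b")
  expect_equal(dirs$class[dirs$feature_id == "r1"], "up")
  expect_equal(dirs$delta, dirs$mean_b - dirs$mean_a)
  expect_true(all(dirs$adj_p >= dirs$p_value))

  # threshold strictness: delta exactly at the cut is ns
  expect_equal(unname(coregulon:::classify_change(0.5, 0.01, 0.05, 0.5)), "ns")
  expect_equal(unname(coregulon:::classify_change(0.7, 0.03, 0.05, 0.5)), "up")
  expect_equal(unname(coregulon:::classify_change(-0.7, 0.03, 0.05, 0.5)),
               "down")
  expect_equal(unname(coregulon:::classify_change(0.7, 0.05, 0.05, 0.5)), "ns")
})

test_that("DEG classification applies the fold-change rule on log2 values", {
  set.seed(12)
  m <- matrix(rnorm(3 * 10, sd = 0.1), 3, 10,
              dimnames = list(c("up_g", "weak_g", "null_g"), paste0("s", 1:10)))
  m["up_g", 6:10] <- m["up_g", 6:10] + 1.0     # log2 fc 1 -> FC 2
  m["weak_g", 6:10] <- m["weak_g", 6:10] + 0.5 # FC 1.41 < 1.5 -> ns
  expr <- toy_expr(m, conditions = rep(c("a", "b"), each = 5))
  degs <- identify_degs(expr, "a", "b")
  cls <- setNames(degs$class, degs$feature_id)
  expect_equal(unname(cls["up_g"]), "up")
  expect_equal(unname(cls["weak_g"]), "ns")
  expect_equal(unname(cls["null_g"]), "ns")
  expect_equal(degs$log2_fc[degs$feature_id == "up_g"], 1, tolerance = 0.2)
  expect_error(identify_degs(expr, "a", "zz"),
               class = "coregulon_design_error")
})

test_that("hypergeometric enrichment matches closed forms", {
  universe <- paste0("u", 1:20)
  gs <- universe[1:5]
  out <- hypergeom_enrichment(gs, gs, universe)
  expect_equal(out$overlap, 5)
  expect_equal(out$p_value, 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(out$gene_ratio, 1)

  # gene set = universe -> p = 1; zero overlap -> p = 1
  expect_equal(hypergeom_enrichment(gs, universe, universe)$p_value, 1)
  expect_equal(hypergeom_enrichment(universe[1:4], universe[11:14],
                                    universe)$p_value, 1)
  expect_error(hypergeom_enrichment(character(0), gs, universe),
               class = "coregulon_test_error")
  expect_error(hypergeom_enrichment("zz", gs, universe),
               class = "coregulon_test_error")
})

test_that("batch enrichment adjusts across sets and reports gene ratios", {
  universe <- paste0("u", 1:40)
  collection <- list(hit = universe[1:8], miss = universe[31:38],
                     part = universe[c(1:4, 21:24)])
  q <- universe[1:10]
  out <- enrich_gene_sets(q, collection, universe)
  expect_equal(nrow(out), 3)
  expect_equal(out$adj_p, bh_adjust(out$p_value))
  expect_equal(out$gene_ratio[out$set_name == "hit"], 8 / 10)
  expect_lt(out$p_value[out$set_name == "hit"],
            out$p_value[out$set_name == "miss"])

  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tu1\tu2\tu3", "setB\tdesc\tu4"), f)
  gmt <- read_gmt(f)
  expect_equal(gmt, list(setA = c("u1", "u2", "u3"), setB = "u4"))
})

test_that("DIR tests keep their type-I error under the null", {
  # small-scale calibration check; the full 50-run version backs the
  # acceptance suite
  fracs <- sapply(1:10, function(sd) {
    sim <- simulate_dataset(sim_config(n_regulators = 15, n_targets = 120,
                                       n_samples_per_condition = 10,
                                       planted_block_size = 15,
                                       delta = 0, seed = sd))
    infl <- influence_matrix(sim$expression, sim$truth$true_network)
    dirs <- identify_dirs(infl, "baseline", "stimulated")
    mean(dirs$adj_p < 0.05)
  })
  se <- sqrt(0.05 * 0.95 / (10 * 15))
  expect_lte(mean(fracs), 0.05 + 3 * se)
})

test_that("variance moderation preserves effect ordering and calibration", {
  sim <- simulate_dataset(sim_config(n_regulators = 12, n_targets = 80,
                                     n_samples_per_condition = 6,
                                     planted_block_size = 12, seed = 33))
  infl <- influence_matrix(sim$expression, sim$truth$true_network)
  plain <- identify_dirs(infl, "baseline", "stimulated")
  mod <- identify_dirs(infl, "baseline", "stimulated", moderate = TRUE)
  ord <- match(plain$feature_id, mod$feature_id)
  expect_equal(mod$delta[ord], plain$delta)   # effect estimates unchanged
  expect_gt(cor(rank(abs(plain$t_value)), rank(abs(mod$t_value[ord]))), 0.8)
  planted <- sim$truth$planted_regulators
  expect_true(all(mod$class[match(planted, mod$feature_id)] == "up"))

  degs_m <- identify_degs(sim$expression, "baseline", "stimulated",
                          moderate = TRUE)
  degs_p <- identify_degs(sim$expression, "baseline", "stimulated")
  expect_equal(degs_m$log2_fc[match(degs_p$feature_id, degs_m$feature_id)],
               degs_p$log2_fc)
  expect_true(all(degs_m$p_value >= 0 & degs_m$p_value <= 1))
})
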