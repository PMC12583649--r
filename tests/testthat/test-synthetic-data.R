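test_that("identical config and seed give identical datasets", {
  cfg <- sim_config(n_regulators = 8, n_targets = 30,
                    n_samples_per_condition = 5, planted_block_size = 5,
                    seed = 99)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$expression$values, s2$expression$values)
  expect_identical(s1$evidence$tf_target, s2$evidence$tf_target)
  expect_identical(s1$truth$true_activity, s2$truth$true_activity)
})

test_that("noiseless single-activator target equals its regulator's activity", {
  cfg <- sim_config(n_regulators = 4, n_targets = 5,
                    n_samples_per_condition = 4, sigma = 0,
                    planted_node_size = 0, planted_block_size = 0,
                    activators_per_target = c(1, 1),
                    repressors_per_target = c(0, 0),
                    edge_weight_range = c(1, 1), seed = 3)
  sim <- simulate_dataset(cfg)
  w <- sim$truth$weights
  for (i in seq_len(nrow(w))) {
    expect_equal(unname(sim$expression$values[w$target[i], ]),
                 unname(sim$truth$true_activity[w$regulator[i], ]),
                 tolerance = 1e-12)
  }
})

test_that("planted regulators' activity shift matches delta in expectation", {
  diffs <- sapply(1:20, function(sd) {
    sim <- simulate_dataset(sim_config(seed = sd))
    act <- sim$truth$true_activity[sim$truth$planted_regulators, , drop = FALSE]
    cond <- sim$truth$condition_labels
    mean(act[, cond == "stimulated"]) - mean(act[, cond == "baseline"])
  })
  # 20-seed average of the condition contrast; MC error ~ 1/sqrt(20*3*20)
  expect_equal(mean(diffs), 2, tolerance = 0.1)
})

test_that("decoupled mRNA hides the shift from the regulator's own gene", {
  hits <- sapply(1:10, function(sd) {
    sim <- simulate_dataset(sim_config(seed = sd, decouple_mrna = TRUE))
    planted <- sim$truth$planted_regulators
    m <- sim$expression$values
    cond <- sim$truth$condition_labels
    ps <- sapply(planted, function(r)
      t.test(m[r, cond == "stimulated"], m[r, cond == "baseline"])$p.value)
    # planted-node targets still shift
    blk <- sim$truth$true_network$programs$target[1]
    p_tgt <- t.test(m[blk, cond == "stimulated"],
                    m[blk, cond == "baseline"])$p.value
    c(all(ps > 0.05), p_tgt < 0.05)
  })
  expect_gte(mean(hits[1, ]), 0.7)   # regulator mRNA ns in most seeds
  expect_gte(mean(hits[2, ]), 0.9)   # targets respond regardless
})

test_that("corrupt_evidence hits the requested coverage and fpr exactly", {
  sim <- simulate_dataset(sim_config(n_regulators = 10, n_targets = 50,
                                     n_samples_per_condition = 5,
                                     planted_block_size = 5, seed = 4))
  n_true <- nrow(tidy(sim$truth$true_network))

  full <- corrupt_evidence(sim$truth, coverage = 1, fpr = 0, seed = 1)
  expect_setequal(
    paste(full$tf_target$regulator, full$tf_target$target),
    paste(tidy(sim$truth$true_network)$regulator,
          tidy(sim$truth$true_network)$target)
  )
  empty <- corrupt_evidence(sim$truth, coverage = 0, fpr = 0, seed = 1)
  expect_equal(nrow(empty$tf_target), 0)

  half <- corrupt_evidence(sim$truth, coverage = 0.5, fpr = 0.1, seed = 1)
  expect_equal(sum(half$tf_target$source == "sim_chip"), round(0.5 * n_true))
  expect_equal(sum(half$tf_target$source == "sim_spurious"),
               round(0.1 * n_true))
  true_keys <- paste(tidy(sim$truth$true_network)$regulator,
                     tidy(sim$truth$true_network)$target)
  spur <- half$tf_target[half$tf_target$source == "sim_spurious", ]
  expect_false(any(paste(spur$regulator, spur$target) %in% true_keys))
})

test_that("planted node members carry pairwise PPI evidence", {
  sim <- simulate_dataset(sim_config(n_regulators = 10, n_targets = 40,
                                     n_samples_per_condition = 5,
                                     planted_block_size = 10, seed = 6))
  planted <- sort(sim$truth$planted_regulators)
  pairs <- t(combn(planted, 2))
  keys <- paste(sim$evidence$ppi$regulator_a, sim$evidence$ppi$regulator_b)
  expect_true(all(paste(pairs[, 1], pairs[, 2]) %in% keys))
})

test_that("query datasets reuse topology and honour the decouple flag", {
  sim <- simulate_dataset(sim_config(n_regulators = 8, n_targets = 40,
                                     n_samples_per_condition = 8,
                                     planted_block_size = 10, seed = 12))
  q1 <- simulate_query(sim$truth, n_samples_per_condition = 10, seed = 5)
  q2 <- simulate_query(sim$truth, n_samples_per_condition = 10, seed = 5)
  expect_identical(q1$expression$values, q2$expression$values)
  expect_setequal(rownames(q1$expression$values),
                  rownames(sim$expression$values))
  # noiseless query reproduces the linear response exactly
  q0 <- simulate_query(sim$truth, n_samples_per_condition = 6, sigma = 0,
                       seed = 2)
  w <- sim$truth$weights
  g <- w$target[1]
  wg <- w[w$target == g, ]
  pred <- colSums((wg$weight * ifelse(wg$role == "activates", 1, -1)) *
                    q0$activity[wg$regulator, , drop = FALSE])
  expect_equal(unname(q0$expression$values[g, ]), unname(pred),
               tolerance = 1e-12)
})

test_that("ground truth serializes to JSON and back", {
  sim <- simulate_dataset(sim_config(n_regulators = 6, n_targets = 15,
                                     n_samples_per_condition = 4,
                                     planted_block_size = 4, seed = 8))
  f <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(sim$truth, f)
  back <- read_ground_truth(f)
  expect_equal(back$true_network$programs, sim$truth$true_network$programs)
  expect_equal(back$planted_regulators, sim$truth$planted_regulators)
  expect_equal(back$true_activity, sim$truth$true_activity)
  expect_equal(back$condition_labels, sim$truth$condition_labels)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(planted_node_size = 40),
               class = "coregulon_config_error")
  expect_error(sim_config(sigma = -1), class = "coregulon_config_error")
  expect_error(sim_config(evidence_coverage = 1.5),
               class = "coregulon_config_error")
  expect_error(sim_config(n_conditions = 3,
                          condition_effects = c(a = 0, b = 1)),
               class = "coregulon_config_error")
})
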