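test_that("discretization standardizes per gene with the unbiased SD", {
  m <- matrix(c(1, 2, 3, 4, 5), 1, 5,
              dimnames = list("g", paste0("s", 1:5)))
  d <- discretize(toy_expr(m))
  # z = (x - 3) / sqrt(2.5): z(5) = 1.2649, z(4) = 0.6325, z(3) = 0
  expect_equal(unname(d["g", ]), c(-1L, 0L, 0L, 0L, 1L))

  const <- matrix(7, 1, 4, dimnames = list("g", paste0("s", 1:4)))
  expect_true(all(discretize(toy_expr(const)) == 0L))

  # z_threshold = 0: every sample gets a nonzero state (the exact-mean tie
  # resolves to the lower state)
  d0 <- discretize(toy_expr(m), z_threshold = 0)
  expect_equal(unname(d0["g", ]), c(-1L, -1L, -1L, 1L, 1L))
  expect_error(discretize(matrix(1, 2, 1, dimnames = list(c("a", "b"), "s"))),
               class = "coregulon_input_error")
})

test_that("collective state is the sign of the member median", {
  d <- toy_disc(matrix(c(1L, 1L, -1L, 1L, -1L, 0L), 3, 2,
                       dimnames = list(c("r1", "r2", "r3"), c("s1", "s2"))))
  expect_equal(collective_state(c("r1", "r2", "r3"), d, "s1"), 1L)
  expect_equal(collective_state(c("r1", "r3"), d, "s1"), 0L)   # {+1,-1}
  expect_equal(collective_state(character(0), d, "s1"), 0L)
  expect_equal(collective_state(c("r1", "r3"), d, "s2"), 1L)   # {+1,0} -> +1
})

test_that("predicted target state follows sign(activators - repressors)", {
  cases <- rbind(c(1, -1, 1), c(1, 1, 0), c(0, -1, 1), c(-1, 1, -1),
                 c(0, 0, 0), c(-1, 0, -1), c(0, 1, -1), c(1, 0, 1))
  for (i in seq_len(nrow(cases))) {
    expect_equal(predict_target(cases[i, 1], cases[i, 2]),
                 as.integer(cases[i, 3]))
  }
})

test_that("program fit score is the mean absolute prediction error", {
  states <- matrix(0L, 2, 10,
                   dimnames = list(c("r1", "g"), paste0("s", 1:10)))
  states["r1", ] <- c(1L, 1L, 1L, 0L, 0L, 0L, -1L, -1L, -1L, 0L)
  states["g", ]  <- c(1L, 1L, 1L, 0L, 0L, 0L, -1L, -1L, -1L, 0L)
  d <- toy_disc(states)
  expect_equal(score_program("g", "r1", character(0), d), 0)

  # 3 mismatches of magnitude 1 among 10 samples -> 0.3
  states["g", c(1, 4, 7)] <- c(0L, 1L, 0L)
  d <- toy_disc(states)
  expect_equal(score_program("g", "r1", character(0), d), 0.3)

  # all +1 predicted vs all -1 observed -> worst case 2
  states["r1", ] <- 1L
  states["g", ] <- -1L
  d <- toy_disc(states)
  expect_equal(score_program("g", "r1", character(0), d), 2)
})

test_that("candidate mining counts joint activity and is anti-monotone", {
  states <- matrix(0L, 3, 10,
                   dimnames = list(c("r1", "r2", "r3"), paste0("s", 1:10)))
  states["r1", 1:6] <- 1L
  states["r2", 1:6] <- 1L
  states["r3", 1:2] <- 1L
  got <- mine_candidates(toy_disc(states), c("r1", "r2", "r3"),
                         min_support = 0.5, max_set_size = 3)
  expect_true("r1;r2" %in% got$key)
  expect_equal(got$support[got$key == "r1;r2"], 0.6)
  expect_false(any(grepl("r3", got$key)))  # support 0.2 < 0.5

  # anti-monotonicity on random matrices
  set.seed(21)
  for (rep in 1:5) {
    regs <- paste0("r", 1:6)
    st <- matrix(sample(c(-1L, 0L, 1L), 6 * 20, replace = TRUE,
                        prob = c(0.25, 0.5, 0.25)), 6, 20,
                 dimnames = list(regs, paste0("s", 1:20)))
    out <- mine_candidates(toy_disc(st), regs, min_support = 0.1,
                           max_set_size = 3)
    for (k in which(out$size > 1)) {
      mem <- out$members[[k]]
      for (drop in seq_along(mem)) {
        sub_key <- paste(sort(mem[-drop]), collapse = ";")
        expect_true(sub_key %in% out$key)
        expect_gte(out$support[out$key == sub_key], out$support[k])
      }
    }
    # deterministic ordering: support desc then lexicographic
    expect_false(is.unsorted(rev(out$support)))
  }
})

test_that("noiseless single-activator networks are fully identifiable", {
  cfg <- sim_config(n_regulators = 10, n_targets = 40,
                    n_samples_per_condition = 10, sigma = 0,
                    planted_node_size = 0, planted_block_size = 0,
                    activators_per_target = c(1, 1),
                    repressors_per_target = c(0, 0),
                    edge_weight_range = c(1, 1), seed = 17)
  sim <- simulate_dataset(cfg)
  net <- infer_network(sim$expression, rownames(sim$truth$true_activity))
  rec <- network_recovery(net, sim$truth$true_network)
  expect_equal(rec$f1, 1)
  expect_equal(glance(net)$mean_fit_score, 0)
})

test_that("inference is deterministic and targets without signal are omitted", {
  cfg <- sim_config(n_regulators = 8, n_targets = 30,
                    n_samples_per_condition = 10, planted_block_size = 6,
                    seed = 23)
  sim <- simulate_dataset(cfg)
  regs <- rownames(sim$truth$true_activity)
  n1 <- infer_network(sim$expression, regs)
  n2 <- infer_network(sim$expression, regs)
  expect_identical(n1$programs, n2$programs)

  # a pure-noise gene under a strict cutoff is omitted while identifiable
  # (noiseless) targets keep their perfect-fit programs
  cfg0 <- sim_config(n_regulators = 8, n_targets = 20,
                     n_samples_per_condition = 10, sigma = 0,
                     planted_node_size = 0, planted_block_size = 0,
                     activators_per_target = c(1, 1),
                     repressors_per_target = c(0, 0),
                     edge_weight_range = c(1, 1), seed = 29)
  sim0 <- simulate_dataset(cfg0)
  m <- sim0$expression$values
  set.seed(1)
  m <- rbind(m, noise = rnorm(ncol(m)))
  expr2 <- expression_dataset(m, sim0$expression$design)
  net <- infer_network(expr2, rownames(sim0$truth$true_activity),
                       fit_cutoff = 0.1)
  expect_true("noise" %in% attr(net, "omitted_targets"))
  expect_false("noise" %in% net$programs$target)
  expect_equal(nrow(net$programs), 20)
})

test_that("regulators are not targets unless explicitly allowed", {
  cfg <- sim_config(n_regulators = 6, n_targets = 20,
                    n_samples_per_condition = 8, planted_block_size = 5,
                    seed = 31)
  sim <- simulate_dataset(cfg)
  regs <- rownames(sim$truth$true_activity)
  net <- infer_network(sim$expression, regs)
  expect_length(intersect(net$programs$target, regs), 0)
  net2 <- infer_network(sim$expression, regs, allow_regulator_targets = TRUE)
  expect_gt(length(intersect(net2$programs$target, regs)), 0)
})
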