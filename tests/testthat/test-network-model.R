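test_that("propagation transfers signal with the curated signs", {
  # zero fixed point: no stimulus, no activity
  net <- chain_net()
  p <- model_params(net, c(0.9, -0.8), n_steps = 2)
  expect_identical(unname(propagate(net, p)), c(0, 0, 0))

  # single-edge transfer
  net1 <- interactome(data.frame(from = "A", to = "B", sign = 1))
  p1 <- model_params(net1, 1, n_steps = 1)
  expect_equal(propagate(net1, p1, c(A = 1))[["B"]], tanh(1))

  # hand propagation of the three-node chain with one inhibiting edge:
  # y_B = tanh(w1), y_C = tanh(w2 * tanh(w1)) with w2 < 0
  y <- propagate(net, p, c(A = 1))
  expect_equal(y[["B"]], tanh(0.9))
  expect_equal(y[["C"]], tanh(-0.8 * tanh(0.9)))
  expect_lt(sign(y[["C"]]), 0)

  expect_error(propagate(net, p, c(Q = 1)), "unknown stimulus")
})

test_that("propagation keeps activities bounded, clamps exact, and is odd in the clamps", {
  for (s in 1:5) {
    net <- random_net(12, p = 0.3, seed = s)
    params <- random_params(net, seed = 100 + s, n_steps = 4)
    clamp <- c(N01 = 1, N05 = -1)
    y <- propagate(net, params, clamp)
    expect_true(all(y >= -1 & y <= 1))
    expect_identical(y[names(clamp)], clamp)
    y_neg <- propagate(net, params, -clamp)
    expect_equal(y_neg, -y)
  }
})

test_that("zero-weight model maps every stimulus to zero off the clamps", {
  net <- random_net(8, p = 0.4, seed = 3)
  p0 <- model_params(net, rep(0, nrow(net$edges)), n_steps = 3)
  y <- propagate(net, p0, c(N02 = 1))
  expect_identical(unname(y[setdiff(names(y), "N02")]),
                   rep(0, length(y) - 1))
})

test_that("propagation matches the loop-based brute-force oracle", {
  for (s in 1:6) {
    net <- random_net(9, p = 0.3, seed = 20 + s)
    params <- random_params(net, seed = 200 + s, n_steps = 3)
    clamp <- c(N01 = -1, N03 = 1)
    expect_equal(propagate(net, params, clamp),
                 bf_propagate(net, params, clamp), tolerance = 1e-12)
  }
})

test_that("model accuracy counts sign-and-threshold compliant constraints", {
  # a constraint set recorded from the model itself is fully compliant
  net <- random_net(10, p = 0.3, seed = 7)
  params <- random_params(net, seed = 77, n_steps = 3)
  y <- propagate(net, params, c(N03 = 1))
  resp <- head(names(y)[abs(y) >= 0.1 & names(y) != "N03"], 3)
  expect_gte(length(resp), 1)
  tt <- truth_table(lapply(resp, function(r)
    list(stimulus = c(N03 = 1), response = r, sign = sign(y[[r]]))))
  expect_equal(model_accuracy(net, params, tt), 1)

  # all-zero weights never reach the activity threshold
  p0 <- model_params(net, rep(0, nrow(net$edges)), n_steps = 3)
  expect_equal(model_accuracy(net, p0, tt), 0)

  # hand-checkable star: A activates B and C, inhibits D; with unit weights
  # and one deliberately wrong required sign exactly 3 of 4 constraints hold
  star <- interactome(data.frame(from = "A", to = c("B", "C", "D"),
                                 sign = c(1, 1, -1)),
                      proteins = c("A", "B", "C", "D", "E"))
  ps <- model_params(star, c(1, 1, -1), n_steps = 1)
  t4 <- truth_table(list(
    list(stimulus = c(A = 1), response = "B", sign = 1),
    list(stimulus = c(A = 1), response = "C", sign = 1),
    list(stimulus = c(A = 1), response = "D", sign = -1),
    list(stimulus = c(A = 1), response = "E", sign = 1)))  # E is isolated
  expect_equal(model_accuracy(star, ps, t4), 0.75)

  expect_error(model_accuracy(net, params, truth_table(list(
    list(stimulus = c(N01 = 1), response = "Q", sign = 1)))), "not in network")
})

test_that("training is deterministic and solves a single satisfiable constraint", {
  net <- interactome(data.frame(from = "A", to = "B", sign = 1))
  tt <- truth_table(list(list(stimulus = c(A = 1), response = "B", sign = 1)))
  ctl <- sa_control(n_proposals = 50)
  s1 <- train_solution(net, tt, seed = 9, control = ctl)
  s2 <- train_solution(net, tt, seed = 9, control = ctl)
  expect_equal(s1$accuracy, 1)
  expect_identical(s1$params$weights, s2$params$weights)
  s3 <- train_solution(net, tt, seed = 10, control = ctl)
  expect_false(identical(s1$params$weights, s3$params$weights))
})

test_that("training a planted-solvable benchmark reaches high compliance", {
  b <- small_bench()
  # the planted parameterization proves a perfect solution exists
  expect_equal(model_accuracy(b$network, b$planted$params, b$truth), 1)
  sol <- train_solution(b$network, b$truth, seed = 1)
  expect_gte(sol$accuracy, 0.93)
  # sign constraint: trained weights keep the curated edge signs
  nz <- sol$params$weights != 0
  expect_identical(sign(sol$params$weights[nz]), as.numeric(b$network$edges$sign[nz]))
})

test_that("ensemble sampling applies the acceptance threshold", {
  b <- small_bench()
  ctl <- sa_control(n_proposals = 400)
  ens <- sample_ensemble(b$network, b$truth, n_solutions = 4,
                         acceptance_threshold = 0, base_seed = 3,
                         control = ctl)
  expect_length(ens$solutions, 4)
  expect_length(ens$all_accuracies, 4)
  expect_error(
    sample_ensemble(b$network, b$truth, n_solutions = 2,
                    acceptance_threshold = 1.01, base_seed = 3,
                    control = ctl),
    "ensemble empty")
})

test_that("a planted-solvable truth table retains most solutions at threshold 0.9", {
  b <- small_bench()
  ens <- sample_ensemble(b$network, b$truth, n_solutions = 10,
                         acceptance_threshold = 0.9, base_seed = 21)
  expect_gte(length(ens$solutions), 8)
})

test_that("ensemble serialization round-trips bit-exactly", {
  b <- small_bench()
  ctl <- sa_control(n_proposals = 300)
  ens <- sample_ensemble(b$network, b$truth, n_solutions = 2,
                         acceptance_threshold = 0, base_seed = 5,
                         control = ctl)
  dir <- withr::local_tempdir()
  write_ensemble(ens, b$network, dir)
  back <- read_ensemble(dir, b$network)
  expect_equal(length(back$solutions), 2)
  for (i in 1:2) {
    expect_identical(back$solutions[[i]]$params$weights,
                     ens$solutions[[i]]$params$weights)
  }
  expect_equal(back$all_accuracies, ens$all_accuracies)
})
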