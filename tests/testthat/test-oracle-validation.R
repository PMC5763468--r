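test_that("the enumeration oracle solves the hand-checkable toys", {
  net <- toy_edge_net()
  prof <- toy_profile(matrix(c(1L, 1L), 2, 1, dimnames = list(c("A", "B"), NULL)))
  o <- brute_force_solve(net, prof)
  expect_equal(o$status, "optimal")
  expect_equal(o$objective, 0)
  expect_equal(o$min_fit, 0)
  expect_equal(unname(o$states[c("A", "B"), "c1"]), c(1L, 1L))

  # all-zero observations: perfect fit, every candidate edge removed
  zero <- toy_profile(matrix(c(0L, 0L), 2, 1, dimnames = list(c("A", "B"), NULL)))
  oz <- brute_force_solve(net, zero, gamma = -0.4)
  expect_equal(oz$objective, -0.4)
  expect_equal(oz$n_removed, 1)

  # a prior pinned where no parent can deliver support is infeasible
  prior <- data.frame(condition = "c1", node = c("A", "B"),
                      direction = c(-1L, 1L))
  oi <- brute_force_solve(net, zero, prior, exempt_prior_targets = FALSE)
  expect_equal(oi$status, "infeasible")

  expect_error(
    brute_force_solve(net, zero, node_limit = 1),
    "enumeration bounds")
})

test_that("the MILP reports infeasibility on an unsupportable prior", {
  net <- toy_edge_net()
  prof <- toy_profile(matrix(c(0L, 0L), 2, 1, dimnames = list(c("A", "B"), NULL)))
  prior <- data.frame(condition = "c1", node = c("A", "B"),
                      direction = c(-1L, 1L))
  prob <- suppressMessages(
    build_training_problem(net, prof, prior, exempt_prior_targets = FALSE))
  sol <- solve_problem(prob)
  expect_equal(sol$status, "infeasible")
  expect_error(decode_solution(prob, sol), "non-optimal")
})

test_that("MILP optimum matches the oracle on random small instances", {
  seeds <- 101:130
  insts <- lapply(seeds, random_instance)
  oracles <- lapply(insts, function(i) {
    brute_force_solve(i$net, i$profile, i$prior)
  })
  feasible <- which(vapply(oracles, function(o) o$status == "optimal", logical(1)))
  problems <- lapply(insts[feasible], function(i) {
    suppressMessages(build_training_problem(i$net, i$profile, i$prior))
  })
  solutions <- solve_problem(problems)
  expect_gt(length(feasible), 20)
  for (q in seq_along(feasible)) {
    o <- oracles[[feasible[q]]]
    s <- solutions[[q]]
    expect_equal(s$status, "optimal")
    expect_equal(s$objective, o$objective, tolerance = 1e-9)
    # simplicity never trades away a unit of fit
    expect_equal(s$fit_term, o$min_fit)
  }
  # infeasible oracle instances only arise from priors
  for (i in which(vapply(oracles, function(o) o$status != "optimal", logical(1)))) {
    expect_false(is.null(insts[[i]]$prior))
  }
})

test_that("per-condition fit terms are separable across conditions", {
  # joint optimum over two conditions equals the sum of the per-condition
  # optima, so adding a condition never degrades the shared fit
  for (seed in c(201, 202, 203)) {
    inst <- random_instance(seed)
    if (ncol(inst$profile) < 2) {
      prof2 <- cbind(inst$profile, inst$profile[, 1])
      colnames(prof2) <- c("c1", "c2")
      inst$profile <- as_ternary_profile(prof2)
    }
    sub <- function(k) {
      p <- inst$profile[, k, drop = FALSE]
      as_ternary_profile(p)
    }
    o_joint <- brute_force_solve(inst$net, inst$profile, inst$prior)
    pr1 <- inst$prior
    o1 <- brute_force_solve(inst$net, sub(1), pr1)
    o2 <- brute_force_solve(inst$net, sub(2), NULL)
    if (o_joint$status == "optimal") {
      expect_equal(o_joint$min_fit, o1$min_fit + o2$min_fit)
    }
  }
})

test_that("leave-one-out folds cover every condition", {
  truth <- generate_network(small_synth(seed = 21, n_conditions = 3))
  sim <- simulate_profiles(truth)
  cv <- loo_crossval(truth$network, sim$profile, sim$prior)
  expect_equal(nrow(cv), ncol(sim$profile))
  expect_setequal(cv$condition, colnames(sim$profile))
  expect_true(all(cv$status == "optimal"))
  expect_true(all(cv$fitting_precision >= 0 & cv$fitting_precision <= 1))
  expect_true(all(cv$network_similarity >= 0 & cv$network_similarity <= 1))
  gl <- glance(cv)
  expect_equal(gl$n_folds, nrow(cv))
})

test_that("duplicated conditions make each fold match joint training", {
  toy <- identifiable_toy()
  prof2 <- cbind(toy$profile, toy$profile[, 1])
  colnames(prof2) <- c("c1", "c2")
  prof2 <- as_ternary_profile(prof2)
  prior2 <- rbind(toy$prior,
                  data.frame(condition = "c2", node = "A", direction = 1L))
  joint <- infer_cell_specific_network(toy$net, prof2, prior2)
  cv <- loo_crossval(toy$net, prof2, prior2)
  expect_equal(cv$fitting_precision, rep(joint$fitting_precision, 2))
  expect_equal(cv$network_similarity, rep(1.0, 2))
})

test_that("noise-free recovery fits exactly; noisy profiles do not", {
  params <- small_synth()
  clean <- recovery_experiment(params, noise_rates = 0, replicates = 3,
                               seed = 7)
  expect_true(all(clean$status == "optimal"))
  expect_true(all(clean$fit_term == 0))
  expect_true(all(clean$recall >= 0 & clean$recall <= 1))

  noisy <- recovery_experiment(params, noise_rates = 0.5, replicates = 3,
                               seed = 7)
  expect_gt(sum(noisy$fit_term), 0)

  p <- autoplot(clean)
  expect_s3_class(p, "ggplot")
})
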