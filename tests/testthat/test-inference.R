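test_that("noise-free synthetic profiles are fitted exactly", {
  truth <- generate_network(small_synth(seed = 5))
  sim <- simulate_profiles(truth)
  fit <- infer_cell_specific_network(truth$network, sim$profile, sim$prior)
  expect_equal(fit$fit_term, 0)
  expect_equal(fit$fitting_precision, 1.0)
  # kept + removed partition the candidate set
  cand <- truth$network$edges$id[truth$network$edges$removable]
  kept <- intersect(fit$cell_specific_network$edges$id, cand)
  expect_setequal(c(kept, fit$removed_edges), cand)
  expect_length(intersect(kept, fit$removed_edges), 0)
})

test_that("an all-zero profile prunes every candidate edge", {
  net <- identifiable_toy()$net
  prof <- as_ternary_profile(
    matrix(0L, 3, 2, dimnames = list(c("A", "B", "C"), c("c1", "c2"))))
  fit <- infer_cell_specific_network(net, prof)
  expect_equal(fit$fit_term, 0)
  expect_setequal(fit$removed_edges, net$edges$id)
  expect_equal(fit$objective, fit$gamma * 3)
})

test_that("a contradicted absent edge is removed while the real path stays", {
  toy <- identifiable_toy()
  fit <- infer_cell_specific_network(toy$net, toy$profile, toy$prior)
  expect_equal(fit$fit_term, 0)
  expect_equal(fit$removed_edges, toy$true_removed)
  expect_setequal(fit$cell_specific_network$edges$id, c("A->B", "B-|C"))
})

test_that("inference is deterministic across repeated runs", {
  truth <- generate_network(small_synth(seed = 9))
  sim <- simulate_profiles(truth)
  f1 <- infer_cell_specific_network(truth$network, sim$profile, sim$prior, seed = 1)
  f2 <- infer_cell_specific_network(truth$network, sim$profile, sim$prior, seed = 1)
  expect_identical(f1$removed_edges, f2$removed_edges)
  expect_identical(f1$states, f2$states)
  expect_identical(f1$objective, f2$objective)
})

test_that("prediction keeps topology fixed and refits the states", {
  toy <- identifiable_toy()
  fit <- infer_cell_specific_network(toy$net, toy$profile, toy$prior)

  # a test condition equal to a training optimum is reproduced exactly
  states <- fit$states[c("A", "B", "C"), 1]
  test_prof <- as_ternary_profile(
    matrix(states, ncol = 1, dimnames = list(names(states), "test")))
  resp <- predict_compound_response(fit, test_prof,
                                    prior = data.frame(condition = "test",
                                                       node = "A",
                                                       direction = 1L))
  expect_equal(resp$fitting_precision, 1.0)
  expect_setequal(resp$labels$edge, fit$cell_specific_network$edges$id)

  # an all-zero test profile leaves the network silent
  zero <- as_ternary_profile(
    matrix(0L, 3, 1, dimnames = list(c("A", "B", "C"), "null")))
  silent <- predict_compound_response(fit, zero)
  expect_true(all(silent$states == 0))
  expect_true(all(silent$labels$label == "no-change"))
  expect_error(predict_compound_response(fit, zero, condition = "nope"),
               "not in profile")
})

test_that("edge labels follow the four-way alteration semantics", {
  truth <- generate_network(small_synth(seed = 5))
  sim <- simulate_profiles(truth)
  fit <- infer_cell_specific_network(truth$network, sim$profile, sim$prior)
  k <- colnames(sim$profile)[1]
  prof_k <- sim$profile[, k, drop = FALSE]
  class(prof_k) <- c("ternary_profile", "matrix", "array")
  resp <- predict_compound_response(fit, prof_k,
                                    prior = sim$prior[sim$prior$condition == k, ])
  expect_true(all(resp$labels$label %in%
                    c("up", "down", "no-change", "not-occurring")))
  # an occurring edge label matches the sign it delivers
  e <- fit$cell_specific_network$edges
  for (i in seq_len(nrow(e))) {
    lab <- resp$labels$label[resp$labels$edge == e$id[i]]
    delivered <- e$sign[i] * resp$states[[e$source[i]]]
    if (lab == "up") expect_gte(delivered, 0)
    if (lab == "down") expect_lt(delivered, 0)
    if (lab == "no-change" && e$removable[i]) {
      expect_equal(resp$states[[e$source[i]]], 0)
      expect_equal(resp$states[[e$target[i]]], 0)
    }
  }
  # the outcome vector recomputes from the decoded factor states
  defs <- output_definitions(fit$cell_specific_network)
  expect_equal(resp$outcome, compute_output_vector(resp$states, defs))
})

test_that("tidy and glance expose the fitted objects as tables", {
  toy <- identifiable_toy()
  fit <- infer_cell_specific_network(toy$net, toy$profile, toy$prior)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_setequal(td$status[td$edge == "A->C"], "removed")
  gl <- glance(fit)
  expect_equal(gl$n_edges_removed, 1)
  expect_equal(gl$fit_term, 0)
})
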