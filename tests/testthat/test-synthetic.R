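test_that("generator parameters are validated", {
  expect_error(synth_params(flip_noise_rate = 1.5), "\\[0, 1\\]")
  expect_error(synth_params(n_outputs = 3, n_tf = 2), "per output")
  expect_error(synth_params(n_nodes = 4, n_edges = 50, n_outputs = 0),
               "acyclic bound")
  p <- synth_params(n_edges = 0, n_outputs = 0, n_tf = 0)
  expect_equal(nrow(generate_network(p)$network$edges), 0)
})

test_that("generated networks are valid, acyclic and reproducible", {
  for (seed in c(1, 2, 3)) {
    t1 <- generate_network(small_synth(seed = seed))
    t2 <- generate_network(small_synth(seed = seed))
    expect_identical(t1$network$edges, t2$network$edges)
    expect_identical(t1$true_removed, t2$true_removed)
    expect_equal(nrow(validate_network(t1$network)), 0)
    g <- igraph::graph_from_data_frame(
      t1$network$edges[, c("source", "target")], directed = TRUE)
    expect_true(igraph::is_dag(g))
    expect_true(all(t1$true_removed %in%
                      t1$network$edges$id[t1$network$edges$removable]))
  }
  preset <- generate_network(synth_params(n_nodes = 35, n_edges = 39,
                                          n_outputs = 4, n_tf = 11))
  s <- network_stats(preset$network)
  expect_equal(s$n_nodes, 35)
  expect_equal(s$n_edges, 50)  # 39 candidates + 11 factor-output links
})

test_that("propagation follows the signed-sum tie rule", {
  # chain propagation through activation and inhibition
  chain <- signaling_network(
    nodes = data.frame(id = c("A", "B", "C"), role = "protein", observed = TRUE),
    edges = data.frame(source = c("A", "B"), target = c("B", "C"),
                       sign = c(1L, -1L)))
  params <- synth_params(n_nodes = 3, n_edges = 2, n_outputs = 0, n_tf = 0,
                         n_conditions = 4, perturbations_per_condition = 1,
                         removed_edge_fraction = 0, observation_coverage = 1,
                         seed = 13)
  sim <- simulate_profiles(chain, params = params)
  for (ci in seq_len(nrow(sim$perturbations))) {
    k <- sim$perturbations$condition[ci]
    d <- sim$perturbations$direction[ci]
    expect_equal(unname(sim$truth_states[c("A", "B", "C"), k]),
                 c(d, d, -d))
  }

  # two parents delivering opposite signals cancel at the child
  vee <- signaling_network(
    nodes = data.frame(id = c("A", "B", "C"), role = "protein", observed = TRUE),
    edges = data.frame(source = c("A", "B"), target = c("C", "C"),
                       sign = c(1L, 1L)))
  pv <- synth_params(n_nodes = 3, n_edges = 2, n_outputs = 0, n_tf = 0,
                     n_conditions = 8, perturbations_per_condition = 2,
                     removed_edge_fraction = 0, observation_coverage = 1,
                     seed = 17)
  simv <- simulate_profiles(vee, params = pv)
  pert <- simv$perturbations
  for (k in unique(pert$condition)) {
    pk <- pert[pert$condition == k, ]
    expected <- sign(sum(pk$direction[match(c("A", "B"), pk$node)]))
    expect_equal(unname(simv$truth_states["C", k]), as.integer(expected))
  }
})

test_that("simulated profiles stay ternary; flips respect the noise rate", {
  truth <- generate_network(small_synth(seed = 4))
  clean <- simulate_profiles(truth)
  expect_true(all(clean$profile %in% c(-1L, 0L, 1L)))
  expect_identical(rownames(clean$profile),
                   truth$network$nodes$id[truth$network$nodes$observed])

  noisy_params <- small_synth(seed = 4, noise = 1)
  noisy <- simulate_profiles(generate_network(noisy_params))
  expect_true(all(noisy$profile %in% c(-1L, 0L, 1L)))
  # rate 1 flips every entry away from the clean value
  expect_true(all(noisy$profile != clean$profile))
})

test_that("simulation refuses cyclic networks", {
  cyc <- signaling_network(
    nodes = data.frame(id = c("A", "B"), role = "protein", observed = TRUE),
    edges = data.frame(source = c("A", "B"), target = c("B", "A"), sign = 1L))
  expect_error(simulate_profiles(cyc, params = small_synth()), "acyclic")
})

test_that("the MCF7-scale preset has the training-set shape", {
  preset <- preset_mcf7_like(seed = 2)
  expect_equal(ncol(preset$profile), 10)
  expect_true(all(preset$profile %in% c(-1L, 0L, 1L)))
  expect_true(all(preset$prior$direction %in% c(-1L, 1L)))
  expect_lte(max(table(preset$prior$condition)), 1)
  expect_identical(preset$profile, preset_mcf7_like(seed = 2)$profile)
})
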