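# Shared builders for small test instances.

# signed two/three-node toys ------------------------------------------------

toy_edge_net <- function(sign = 1L, observed = c(A = TRUE, B = TRUE)) {
  signaling_network(
    nodes = data.frame(id = c("A", "B"), role = "protein",
                       observed = unname(observed[c("A", "B")])),
    edges = data.frame(source = "A", target = "B", sign = sign)
  )
}

toy_profile <- function(values, conditions = paste0("c", seq_len(ncol(values)))) {
  colnames(values) <- conditions
  as_ternary_profile(values)
}

# identifiable removal toy: A->B->C real, A->C truly absent ------------------

identifiable_toy <- function() {
  net <- signaling_network(
    nodes = data.frame(id = c("A", "B", "C"), role = "protein", observed = TRUE),
    edges = data.frame(source = c("A", "B", "A"),
                       target = c("B", "C", "C"),
                       sign = c(1L, -1L, 1L))
  )
  profile <- as_ternary_profile(matrix(c(1L, 1L, -1L), nrow = 3,
                                       dimnames = list(c("A", "B", "C"), "c1")))
  prior <- data.frame(condition = "c1", node = "A", direction = 1L)
  list(net = net, profile = profile, prior = prior,
       true_removed = "A->C")
}

# random small instances within the enumeration bounds -----------------------

random_instance <- function(seed) {
  set.seed(seed)
  n <- sample(3:6, 1)
  ids <- paste0("n", seq_len(n))
  pairs <- expand.grid(s = seq_len(n), t = seq_len(n))
  pairs <- pairs[pairs$s < pairs$t, , drop = FALSE]
  density <- runif(1, 0.3, 0.6)
  e <- pairs[runif(nrow(pairs)) < density, , drop = FALSE]
  if (nrow(e) > 7) e <- e[sample(nrow(e), 7), , drop = FALSE]
  edges <- data.frame(source = ids[e$s], target = ids[e$t],
                      sign = ifelse(runif(nrow(e)) < 0.3, -1L, 1L))
  coverage <- runif(1, 0.6, 1)
  nodes <- data.frame(id = ids, role = "protein",
                      observed = runif(n) < coverage)
  net <- signaling_network(nodes, edges)
  n_cond <- sample(1:2, 1)
  obs <- nodes$id[nodes$observed]
  profile <- matrix(
    sample(c(-1L, 0L, 1L, NA), length(obs) * n_cond, replace = TRUE,
           prob = c(0.3, 0.3, 0.3, 0.1)),
    nrow = length(obs), dimnames = list(obs, paste0("c", seq_len(n_cond))))
  prior <- NULL
  if (runif(1) < 0.3) {
    prior <- data.frame(condition = "c1", node = sample(ids, 1),
                        direction = sample(c(-1L, 1L), 1))
  }
  list(net = net, profile = as_ternary_profile(profile), prior = prior)
}

# small fast generator preset for solver-backed tests ------------------------

small_synth <- function(seed = 3, noise = 0, n_conditions = 4) {
  synth_params(n_nodes = 12, n_edges = 14, inhibition_fraction = 0.3,
               n_outputs = 2, n_tf = 3, n_conditions = n_conditions,
               perturbations_per_condition = 2,
               removed_edge_fraction = 0.25, observation_coverage = 0.8,
               flip_noise_rate = noise, seed = seed)
}
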