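# Synthetic ground-truth generator: layered signed acyclic networks and
# ternary perturbation-response profiles with a controllable
# state-flip noise rate.

#' Parameters for the synthetic generator
#'
#' @param n_nodes Total nodes including outputs.
#' @param n_edges Candidate signaling edges (excluding the fixed
#'   TF-to-output links).
#' @param inhibition_fraction Fraction of inhibitory edges.
#' @param n_outputs Cell-function output nodes.
#' @param n_tf Terminal transcription-factor nodes (each wired to one
#'   output with a random +/- coefficient; must be >= `n_outputs` when
#'   outputs are requested).
#' @param n_conditions Perturbation conditions.
#' @param perturbations_per_condition Root nodes perturbed to +/-1 per
#'   condition.
#' @param removed_edge_fraction Fraction of candidate edges marked truly
#'   absent from the cell-specific ground truth.
#' @param observation_coverage Fraction of non-output nodes observed.
#' @param flip_noise_rate Probability that an observed entry is flipped
#'   to one of the two other ternary values.
#' @param seed RNG seed.
#' @return A `generator_params` list.
#' @export
synth_params <- function(n_nodes = 20, n_edges = 28,
                         inhibition_fraction = 0.3, n_outputs = 2,
                         n_tf = 4, n_conditions = 6,
                         perturbations_per_condition = 2,
                         removed_edge_fraction = 0.25,
                         observation_coverage = 0.8,
                         flip_noise_rate = 0, seed = 1) {
  p <- list(n_nodes = n_nodes, n_edges = n_edges,
            inhibition_fraction = inhibition_fraction,
            n_outputs = n_outputs, n_tf = n_tf,
            n_conditions = n_conditions,
            perturbations_per_condition = perturbations_per_condition,
            removed_edge_fraction = removed_edge_fraction,
            observation_coverage = observation_coverage,
            flip_noise_rate = flip_noise_rate, seed = seed)
  fracs <- c("inhibition_fraction", "removed_edge_fraction",
             "observation_coverage", "flip_noise_rate")
  for (f in fracs) {
    if (p[[f]] < 0 || p[[f]] > 1) abort(paste0("`", f, "` must lie in [0, 1]"))
  }
  if (p$n_outputs > 0 && p$n_tf < p$n_outputs) {
    abort("need at least one transcription factor per output")
  }
  inner <- p$n_nodes - p$n_outputs
  if (inner < 2 && p$n_edges > 0) abort("too few non-output nodes for edges")
  max_edges <- inner * (inner - 1) / 2
  if (p$n_edges > max_edges) {
    abort(sprintf("n_edges=%d exceeds the acyclic bound %d", p$n_edges, max_edges))
  }
  structure(p, class = "generator_params")
}

#' Generate a random layered signed network with ground truth
#'
#' Nodes are ordered; edges run strictly forward, giving an acyclic
#' signed digraph in which downstream transcription factors feed the
#' output readouts with fixed coefficients.  A random fraction of the
#' candidate edges is designated truly absent: the profiles simulated by
#' [simulate_profiles()] propagate over the remaining edges only, so
#' inference can be scored against a known removal set.
#'
#' @param params A [synth_params()] list.
#' @return List with `network` (all candidate edges, removable),
#'   `true_removed` (edge ids absent from the ground truth) and the
#'   `params`.
#' @export
generate_network <- function(params) {
  stopifnot(inherits(params, "generator_params"))
  p <- params
  set.seed(p$seed)
  inner_n <- p$n_nodes - p$n_outputs
  ids <- sprintf("N%02d", seq_len(inner_n))
  tf_ids <- if (p$n_tf > 0) utils::tail(ids, p$n_tf) else character()
  out_ids <- if (p$n_outputs > 0) sprintf("OUT%d", seq_len(p$n_outputs)) else character()
  roles <- ifelse(ids %in% tf_ids, "transcription_factor", "protein")

  # candidate forward pairs among non-output nodes; TFs are terminal
  src_ok <- which(!ids %in% tf_ids)
  pairs <- expand.grid(s = seq_len(inner_n), t = seq_len(inner_n))
  pairs <- pairs[pairs$s < pairs$t & pairs$s %in% src_ok, , drop = FALSE]
  if (nrow(pairs) < p$n_edges) {
    abort("not enough forward node pairs for the requested edge count")
  }
  # first give every non-root node a chance at one incoming edge, then
  # fill the rest uniformly
  chosen <- integer()
  targets <- sort(unique(pairs$t))
  for (tt in targets) {
    cand <- which(pairs$t == tt)
    if (length(chosen) < p$n_edges && length(cand) > 0) {
      chosen <- c(chosen, cand[sample.int(length(cand), 1)])
    }
  }
  chosen <- utils::head(unique(chosen), p$n_edges)
  remaining <- setdiff(seq_len(nrow(pairs)), chosen)
  need <- p$n_edges - length(chosen)
  if (need > 0) chosen <- c(chosen, sample(remaining, need))
  ep <- pairs[chosen, , drop = FALSE]
  sign <- ifelse(runif(nrow(ep)) < p$inhibition_fraction, -1L, 1L)
  edges <- tibble::tibble(source = ids[ep$s], target = ids[ep$t], sign = sign)

  nodes <- tibble::tibble(id = c(ids, out_ids),
                          role = c(roles, rep("output", p$n_outputs)),
                          observed = FALSE)
  if (p$n_outputs > 0) {
    # each TF feeds one output; every output gets at least one TF
    assign_out <- c(seq_len(p$n_outputs),
                    sample(p$n_outputs, max(0, p$n_tf - p$n_outputs),
                           replace = TRUE))
    assign_out <- assign_out[sample.int(length(assign_out))]
    coef <- sample(c(-1L, 1L), p$n_tf, replace = TRUE)
    edges <- dplyr::bind_rows(edges, tibble::tibble(
      source = tf_ids, target = out_ids[assign_out], sign = coef))
  }

  # observation coverage over non-output nodes
  n_obs <- round(p$observation_coverage * inner_n)
  obs <- sample(ids, n_obs)
  nodes$observed <- nodes$id %in% obs

  net <- signaling_network(nodes, edges)
  cand <- net$edges$id[net$edges$removable]
  n_rm <- round(p$removed_edge_fraction * length(cand))
  true_removed <- if (n_rm > 0) sample(cand, n_rm) else character()
  list(network = net, true_removed = true_removed, params = p)
}

#' Simulate ternary perturbation-response profiles
#'
#' Per condition, a set of root nodes is perturbed to +/-1 and states
#' propagate in topological order over the non-removed edges: a node's
#' state is the sign of the sum of delivered parent signals
#' (edge sign x parent state), 0 on a tie or with no active parent.
#' Observed entries are then flipped to one of the two other ternary
#' values with probability `flip_noise_rate`.
#'
#' @param truth Output of [generate_network()], or a
#'   `signaling_network` (then `true_removed` may be given separately).
#' @param params A [synth_params()] list (defaults to `truth$params`).
#' @param true_removed Edge ids absent from the ground truth.
#' @return List with `profile` (observed nodes x conditions, class
#'   `ternary_profile`), `truth_states` (all non-output nodes x
#'   conditions, noise-free), `perturbations` (tibble condition, node,
#'   direction) and `prior` (the perturbation records, usable as prior
#'   knowledge).
#' @export
simulate_profiles <- function(truth, params = NULL, true_removed = NULL) {
  if (inherits(truth, "signaling_network")) {
    net <- truth
    true_removed <- true_removed %||% character()
  } else {
    net <- truth$network
    true_removed <- true_removed %||% truth$true_removed
    params <- params %||% truth$params
  }
  stopifnot(inherits(params, "generator_params"))
  p <- params
  set.seed(p$seed + 1L)

  nodes <- net$nodes
  inner <- nodes$id[nodes$role != "output"]
  e <- net$edges[net$edges$removable & !net$edges$id %in% true_removed, ,
                 drop = FALSE]
  g <- igraph::graph_from_data_frame(
    net$edges[net$edges$removable, c("source", "target")],
    directed = TRUE, vertices = inner)
  if (!igraph::is_dag(g)) abort("propagation needs an acyclic network")
  topo <- igraph::as_ids(igraph::topo_sort(g, mode = "out"))

  roots <- setdiff(inner, net$edges$target)
  if (length(roots) == 0) abort("network has no root nodes to perturb")
  conds <- sprintf("cond%02d", seq_len(p$n_conditions))
  states <- matrix(0L, length(inner), p$n_conditions,
                   dimnames = list(inner, conds))
  perturb <- list()
  for (ci in seq_len(p$n_conditions)) {
    n_pert <- min(p$perturbations_per_condition, length(roots))
    tgt <- sample(roots, n_pert)
    dirn <- sample(c(-1L, 1L), n_pert, replace = TRUE)
    perturb[[ci]] <- tibble::tibble(condition = conds[ci], node = tgt,
                                    direction = dirn)
    s <- stats::setNames(rep(0L, length(inner)), inner)
    s[tgt] <- dirn
    for (v in topo) {
      if (v %in% tgt) next
      inc <- e[e$target == v, , drop = FALSE]
      if (nrow(inc) == 0) next
      s[v] <- as.integer(sign(sum(inc$sign * s[inc$source])))
    }
    states[, ci] <- s[inner]
  }

  obs <- nodes$id[nodes$observed]
  profile <- states[obs, , drop = FALSE]
  if (p$flip_noise_rate > 0 && length(profile) > 0) {
    flip <- runif(length(profile)) < p$flip_noise_rate
    other <- function(v) sample(setdiff(c(-1L, 0L, 1L), v), 1)
    profile[flip] <- vapply(profile[flip], other, integer(1))
  }
  class(profile) <- c("ternary_profile", "matrix", "array")
  list(profile = profile, truth_states = states,
       perturbations = dplyr::bind_rows(perturb),
       prior = dplyr::bind_rows(perturb))
}

#' Deterministic MCF7-scale synthetic preset
#'
#' A size-matched analog of the packaged breast-cancer map (35 nodes, 50
#' candidate-plus-output edges) with ten perturbation conditions and at
#' most one prior target per condition, for integration tests and
#' examples that need known ground truth.
#'
#' @param seed RNG seed (default 42).
#' @param flip_noise_rate Observation noise (default 0).
#' @return List with `network`, `true_removed`, `profile`,
#'   `truth_states`, `prior` (single target per condition) and `params`.
#' @export
preset_mcf7_like <- function(seed = 42, flip_noise_rate = 0) {
  params <- synth_params(
    n_nodes = 35, n_edges = 39, inhibition_fraction = 0.3,
    n_outputs = 4, n_tf = 11, n_conditions = 10,
    perturbations_per_condition = 1, removed_edge_fraction = 0.25,
    observation_coverage = 15 / 31, flip_noise_rate = flip_noise_rate,
    seed = seed)
  truth <- generate_network(params)
  sim <- simulate_profiles(truth)
  prior <- sim$perturbations |>
    dplyr::group_by(.data$condition) |>
    dplyr::slice_head(n = 1) |>
    dplyr::ungroup()
  c(truth[c("network", "true_removed", "params")],
    sim[c("profile", "truth_states")], list(prior = prior))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
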