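# Orchestration: training (network inference) and per-compound
# prediction, decoding solver output into domain results.

#' Infer a cell-specific network from perturbation profiles
#'
#' Fits the generic map to the discretized training profiles (plus
#' prior-knowledge constraints) by mixed-integer optimization, keeps
#' the candidate edges whose reaction occurs under some condition, and
#' removes those that occur under none.
#'
#' @inheritParams build_training_problem
#' @param time_limit,seed Passed to [solve_problem()].
#' @return A `network_inference` object: the pruned
#'   `cell_specific_network`, `removed_edges`, per-condition `states`
#'   and `occurrences`, the objective decomposition, and
#'   `fitting_precision` over observed non-missing entries.
#' @export
infer_cell_specific_network <- function(network, profile, prior = NULL,
                                        gamma = NULL, time_limit = NULL,
                                        seed = NULL,
                                        exempt_prior_targets = TRUE) {
  problem <- build_training_problem(network, profile, prior, gamma,
                                    exempt_prior_targets)
  solution <- solve_problem(problem, time_limit = time_limit, seed = seed)
  if (solution$status != "optimal") {
    abort(c(paste0("training optimization did not reach an optimum: ",
                   solution$status),
            i = solution$message))
  }
  dec <- decode_solution(problem, solution)
  kept_edges <- network$edges[!network$edges$id %in% dec$removed, , drop = FALSE]
  cell_net <- signaling_network(network$nodes, kept_edges)
  prof <- problem$profile
  fp <- if (length(problem$observed_nodes) > 0 && any(!is.na(prof))) {
    fitting_precision(dec$states, prof)
  } else NA_real_
  structure(list(
    cell_specific_network = cell_net,
    removed_edges = dec$removed,
    states = dec$states,
    occurrences = dec$occurrences,
    objective = solution$objective,
    fit_term = solution$fit_term,
    simplicity_term = solution$simplicity_term,
    fitting_precision = fp,
    gamma = problem$gamma,
    conditions = problem$conditions,
    generic_network = network,
    prior = problem$prior
  ), class = "network_inference")
}

#' @export
print.network_inference <- function(x, ...) {
  cat(sprintf(
    "<network_inference> %d/%d candidate edges removed | fit term %g | fitting precision %s\n",
    length(x$removed_edges), sum(x$generic_network$edges$removable),
    x$fit_term,
    ifelse(is.na(x$fitting_precision), "NA",
           sprintf("%.2f%%", 100 * x$fitting_precision))))
  invisible(x)
}

#' @export
tidy.network_inference <- function(x, ...) {
  e <- x$generic_network$edges
  tibble::tibble(
    edge = e$id, source = e$source, target = e$target, sign = e$sign,
    removable = e$removable,
    status = dplyr::if_else(e$id %in% x$removed_edges, "removed", "kept")
  )
}

#' @export
glance.network_inference <- function(x, ...) {
  tibble::tibble(
    n_conditions = length(x$conditions),
    n_edges_kept = nrow(x$cell_specific_network$edges),
    n_edges_removed = length(x$removed_edges),
    objective = x$objective,
    fit_term = x$fit_term,
    simplicity_term = x$simplicity_term,
    fitting_precision = x$fitting_precision,
    gamma = x$gamma
  )
}

#' Predict a compound's treatment effects on an inferred network
#'
#' Re-optimizes the cell-specific network (topology fixed; no edge
#' removal) against one test condition's ternary profile, then decodes
#' the qualitative pathway alteration per edge and the quantitative
#' cell-function outcome vector.
#'
#' Edge labels follow the four-way coloring semantics: an occurring
#' reaction delivering a positive signal is `"up"`, a negative one
#' `"down"`; a non-occurring reaction between two unchanged nodes is
#' `"no-change"`, any other non-occurring reaction `"not-occurring"`.
#'
#' @param network A `network_inference` result or a cell-specific
#'   `signaling_network`.
#' @param profile Ternary profile holding the test condition.
#' @param prior Optional prior records for the test compound.
#' @param condition Condition (column) to predict; defaults to the
#'   profile's single column.
#' @param time_limit,seed Passed to [solve_problem()].
#' @return A `response_network` object with node `states`, per-edge
#'   `labels`, the `outcome` vector, and `fitting_precision`.
#' @export
predict_compound_response <- function(network, profile, prior = NULL,
                                      condition = NULL, time_limit = NULL,
                                      seed = NULL) {
  net <- if (inherits(network, "network_inference")) {
    network$cell_specific_network
  } else network
  stopifnot(inherits(net, "signaling_network"))
  profile <- as_ternary_profile(profile)
  if (is.null(condition)) {
    if (ncol(profile) != 1) {
      abort("supply `condition` when the profile has several columns")
    }
    condition <- colnames(profile)
  }
  if (!condition %in% colnames(profile)) {
    abort(paste0("condition `", condition, "` not in profile"))
  }
  profile <- profile[, condition, drop = FALSE]
  class(profile) <- c("ternary_profile", "matrix", "array")
  if (!is.null(prior)) {
    prior <- as_prior(prior)
    prior <- prior[prior$condition == condition, , drop = FALSE]
  }
  problem <- build_prediction_problem(net, profile, prior)
  solution <- solve_problem(problem, time_limit = time_limit, seed = seed)
  if (solution$status != "optimal") {
    abort(c(paste0("prediction optimization failed: ", solution$status),
            i = solution$message))
  }
  dec <- decode_solution(problem, solution)
  states <- dec$states[, 1]
  labels <- label_edges(net, states, dec$occurrences[, 1])
  defs <- output_definitions(net)
  outcome <- if (nrow(defs) > 0) compute_output_vector(states, defs) else integer()
  fp <- if (any(!is.na(profile))) fitting_precision(dec$states, profile) else NA_real_
  structure(list(
    condition = condition,
    network = net,
    states = states,
    labels = labels,
    outcome = outcome,
    fitting_precision = fp,
    fit_term = solution$fit_term,
    objective = solution$objective
  ), class = "response_network")
}

label_edges <- function(net, states, occurrence) {
  e <- net$edges
  out_ids <- net$nodes$id[net$nodes$role == "output"]
  lab <- character(nrow(e))
  for (i in seq_len(nrow(e))) {
    delivered <- e$sign[i] * states[[e$source[i]]]
    if (e$target[i] %in% out_ids) {
      # definitional TF->output links: labeled by the delivered signal
      lab[i] <- if (delivered > 0) "up" else if (delivered < 0) "down" else "no-change"
    } else if (occurrence[[e$id[i]]]) {
      lab[i] <- if (delivered >= 0) "up" else "down"
    } else if (states[[e$source[i]]] == 0 && states[[e$target[i]]] == 0) {
      lab[i] <- "no-change"
    } else {
      lab[i] <- "not-occurring"
    }
  }
  tibble::tibble(edge = e$id, source = e$source, target = e$target,
                 sign = e$sign, label = lab)
}

#' @export
print.response_network <- function(x, ...) {
  cat(sprintf("<response_network> condition=%s | outcome [%s] | fitting precision %s\n",
              x$condition, paste(x$outcome, collapse = ", "),
              ifelse(is.na(x$fitting_precision), "NA",
                     sprintf("%.2f%%", 100 * x$fitting_precision))))
  invisible(x)
}

#' @export
tidy.response_network <- function(x, ...) {
  x$labels
}

#' @export
glance.response_network <- function(x, ...) {
  tibble::tibble(
    condition = x$condition,
    fit_term = x$fit_term,
    fitting_precision = x$fitting_precision,
    n_up = sum(x$labels$label == "up"),
    n_down = sum(x$labels$label == "down"),
    n_no_change = sum(x$labels$label == "no-change"),
    n_not_occurring = sum(x$labels$label == "not-occurring")
  )
}

#' Per-condition state table of an inference result
#'
#' @param result A `network_inference`.
#' @return Long tibble with columns `node`, `condition`, `state`.
#' @export
inferred_states <- function(result) {
  stopifnot(inherits(result, "network_inference"))
  as.data.frame.table(result$states, stringsAsFactors = FALSE) |>
    stats::setNames(c("node", "condition", "state")) |>
    tibble::as_tibble()
}
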