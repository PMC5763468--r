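# Leave-one-out cross-validation and synthetic recovery experiments.

#' Leave-one-out cross-validation of network inference
#'
#' For each condition: train on the remaining conditions, predict the
#' held-out condition on the fold's inferred network, and record the
#' held-out fitting precision plus the fold network's topological
#' similarity to the network inferred from all conditions.  All fold
#' training problems are solved in one backend call, then all fold
#' predictions in a second.
#'
#' @inheritParams build_training_problem
#' @param time_limit Per-solve limit in seconds.
#' @return A `crossval_report`: tibble with one row per fold
#'   (`condition`, `status`, `fitting_precision`, `network_similarity`,
#'   `n_edges_kept`, `fit_term`) plus attributes `mean_precision`,
#'   `mean_similarity` and the `reference` all-data inference.
#' @export
loo_crossval <- function(network, profile, prior = NULL, gamma = NULL,
                         time_limit = NULL) {
  profile <- as_ternary_profile(profile)
  prior <- as_prior(prior)
  conds <- colnames(profile)
  if (length(conds) < 2) abort("cross-validation needs at least 2 conditions")

  reference <- infer_cell_specific_network(network, profile, prior, gamma,
                                           time_limit = time_limit)
  subprofile <- function(keep) {
    p <- profile[, keep, drop = FALSE]
    class(p) <- c("ternary_profile", "matrix", "array")
    p
  }
  train_problems <- lapply(conds, function(k) {
    build_training_problem(network, subprofile(setdiff(conds, k)),
                           prior[prior$condition != k, , drop = FALSE], gamma)
  })
  train_solutions <- solve_problem(train_problems, time_limit = time_limit)

  folds <- vector("list", length(conds))
  pred_problems <- list(); pred_nets <- list(); pred_at <- integer()
  for (fi in seq_along(conds)) {
    k <- conds[fi]
    sol <- train_solutions[[fi]]
    if (sol$status != "optimal") {
      folds[[fi]] <- tibble::tibble(condition = k, status = sol$status,
                                    fitting_precision = NA_real_,
                                    network_similarity = NA_real_,
                                    n_edges_kept = NA_integer_,
                                    fit_term = NA_real_)
      next
    }
    dec <- decode_solution(train_problems[[fi]], sol)
    kept <- network$edges[!network$edges$id %in% dec$removed, , drop = FALSE]
    fold_net <- signaling_network(network$nodes, kept)
    pred_nets[[length(pred_nets) + 1L]] <- fold_net
    pred_problems[[length(pred_problems) + 1L]] <- build_prediction_problem(
      fold_net, subprofile(k), prior[prior$condition == k, , drop = FALSE])
    pred_at <- c(pred_at, fi)
    folds[[fi]] <- tibble::tibble(
      condition = k, status = "optimal", fitting_precision = NA_real_,
      network_similarity = topology_similarity(
        fold_net, reference$cell_specific_network),
      n_edges_kept = nrow(kept), fit_term = sol$fit_term)
  }
  if (length(pred_problems) > 0) {
    pred_solutions <- solve_problem(pred_problems, time_limit = time_limit)
    for (q in seq_along(pred_problems)) {
      fi <- pred_at[q]
      sol <- pred_solutions[[q]]
      if (sol$status != "optimal") {
        folds[[fi]]$status <- paste0("prediction-", sol$status)
        next
      }
      dec <- decode_solution(pred_problems[[q]], sol)
      folds[[fi]]$fitting_precision <- fitting_precision(
        dec$states, subprofile(conds[fi]))
    }
  }
  report <- dplyr::bind_rows(folds)
  structure(report,
            mean_precision = mean(report$fitting_precision, na.rm = TRUE),
            mean_similarity = mean(report$network_similarity, na.rm = TRUE),
            reference = reference,
            class = c("crossval_report", class(report)))
}

#' @export
glance.crossval_report <- function(x, ...) {
  tibble::tibble(
    n_folds = nrow(x),
    n_failed = sum(x$status != "optimal"),
    mean_precision = attr(x, "mean_precision"),
    mean_similarity = attr(x, "mean_similarity")
  )
}

#' Edge-recovery experiment on synthetic ground truth
#'
#' Generates networks with a known truly-absent edge subset, simulates
#' perturbation profiles at each requested noise rate, runs inference,
#' and scores the removed-edge set against the truth.
#'
#' @param params Base [synth_params()]; its seed and noise rate are
#'   overridden per replicate.
#' @param noise_rates Vector of state-flip probabilities.
#' @param replicates Replicates per noise rate.
#' @param seed Base seed; replicate r at noise index q uses
#'   `seed + 1000 * q + r`.
#' @param gamma,time_limit Passed to inference.
#' @return A `recovery_experiment` tibble: one row per run with
#'   `noise_rate`, `replicate`, `fit_term`, `n_removed`, `n_true_removed`,
#'   `precision` and `recall` of the removed-edge set.
#' @export
recovery_experiment <- function(params = synth_params(),
                                noise_rates = c(0, 0.1, 0.3),
                                replicates = 3, seed = 1, gamma = NULL,
                                time_limit = NULL) {
  grid <- expand.grid(replicate = seq_len(replicates),
                      noise_rate = noise_rates)
  runs <- vector("list", nrow(grid))
  problems <- vector("list", nrow(grid))
  for (r in seq_len(nrow(grid))) {
    p <- params
    p$seed <- seed + 1000L * match(grid$noise_rate[r], noise_rates) +
      grid$replicate[r]
    p$flip_noise_rate <- grid$noise_rate[r]
    truth <- generate_network(p)
    sim <- simulate_profiles(truth)
    runs[[r]] <- list(truth = truth, sim = sim)
    problems[[r]] <- build_training_problem(
      truth$network, sim$profile, sim$prior, gamma)
  }
  solutions <- solve_problem(problems, time_limit = time_limit)
  rows <- purrr::pmap(list(runs, problems, solutions, seq_len(nrow(grid))),
                      function(run, prob, sol, r) {
    truth <- run$truth
    if (sol$status != "optimal") {
      return(tibble::tibble(noise_rate = grid$noise_rate[r],
                            replicate = grid$replicate[r],
                            status = sol$status, fit_term = NA_real_,
                            n_removed = NA_integer_,
                            n_true_removed = length(truth$true_removed),
                            precision = NA_real_, recall = NA_real_))
    }
    dec <- decode_solution(prob, sol)
    inter <- length(intersect(dec$removed, truth$true_removed))
    tibble::tibble(
      noise_rate = grid$noise_rate[r], replicate = grid$replicate[r],
      status = "optimal", fit_term = sol$fit_term,
      n_removed = length(dec$removed),
      n_true_removed = length(truth$true_removed),
      precision = if (length(dec$removed) > 0) inter / length(dec$removed) else NA_real_,
      recall = if (length(truth$true_removed) > 0) inter / length(truth$true_removed) else NA_real_)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("recovery_experiment", class(out))
  out
}

#' Recovery precision/recall against the noise rate
#'
#' @param object A [recovery_experiment()] table.
#' @param ... Unused.
#' @return ggplot object: mean precision, recall and fit term per noise
#'   rate with per-replicate points.
#' @export
autoplot.recovery_experiment <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object),
                            cols = c("precision", "recall"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$noise_rate, y = .data$value,
                                   color = .data$metric)) +
    ggplot2::geom_point(alpha = 0.5, position = ggplot2::position_jitter(width = 0.005, height = 0)) +
    ggplot2::stat_summary(fun = mean, geom = "line") +
    ggplot2::labs(x = "state-flip noise rate", y = "removed-edge recovery",
                  color = NULL) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
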