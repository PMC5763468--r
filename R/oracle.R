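# Brute-force enumeration oracle for small instances.
#
# States are enumerated exhaustively per condition; occurrence and
# removal variables are derived analytically: a reaction is forced to
# occur where its endpoint product demands it, every other occurrence
# is chosen only to cover a support need, and an edge is removed
# exactly when it occurs under no condition.  The reported optimum is
# the exact global minimum of fit + gamma * removals, found by scanning
# all 2^n_edges "occurs-somewhere" sets.

#' Exhaustive reference solution of a small inference instance
#'
#' Independent of the MILP encoding: enumerates all ternary state
#' assignments and all occurs-somewhere edge sets under the same
#' constraint semantics and returns the exact optimum.  Intended as a
#' test oracle; refuses instances beyond the enumeration bounds.
#'
#' @inheritParams build_training_problem
#' @param node_limit,edge_limit,cond_limit Enumeration bounds (defaults
#'   8 non-output nodes, 8 reaction edges, 2 conditions).
#' @return List with `status` (`"optimal"`/`"infeasible"`),
#'   `objective`, `fit_term`, `min_fit` (best achievable mismatch count
#'   regardless of simplicity), `n_removed`, `removed`, one optimal
#'   `states` matrix, and `n_optimal` (state assignments attaining the
#'   optimum for the reported edge set).
#' @export
brute_force_solve <- function(network, profile, prior = NULL, gamma = NULL,
                              exempt_prior_targets = TRUE,
                              node_limit = 8, edge_limit = 8,
                              cond_limit = 2) {
  stopifnot(inherits(network, "signaling_network"))
  profile <- as_ternary_profile(profile)
  prior <- as_prior(prior)
  nodes <- network$nodes
  inner <- nodes$id[nodes$role != "output"]
  out_ids <- nodes$id[nodes$role == "output"]
  redges <- network$edges[!network$edges$target %in% out_ids, , drop = FALSE]
  conds <- colnames(profile)
  n <- length(inner); E <- nrow(redges); L <- length(conds)
  if (n > node_limit || E > edge_limit || L > cond_limit) {
    abort(sprintf("instance exceeds enumeration bounds (%d nodes, %d edges, %d conditions)",
                  n, E, L))
  }
  rem_idx <- which(redges$removable)
  n_rem <- length(rem_idx)
  gamma <- if (n_rem > 0) {
    check_gamma(if (is.null(gamma)) default_gamma(n_rem) else gamma, n_rem)
  } else 0

  # all ternary assignments over the inner nodes, one row each
  X <- as.matrix(expand.grid(rep(list(c(-1L, 0L, 1L)), n),
                             KEEP.OUT.ATTRS = FALSE))
  colnames(X) <- inner
  ui <- match(redges$source, inner)
  di <- match(redges$target, inner)
  obs <- intersect(rownames(profile), nodes$id[nodes$observed])
  obs_i <- match(obs, inner)

  per_cond <- lapply(conds, function(k) {
    keep <- rep(TRUE, nrow(X))
    pk <- prior[prior$condition == k, , drop = FALSE]
    for (r in seq_len(nrow(pk))) {
      keep <- keep & X[, pk$node[r]] == pk$direction[r]
    }
    Xk <- X[keep, , drop = FALSE]
    fit <- rep(0L, nrow(Xk))
    for (jj in seq_along(obs)) {
      mv <- profile[obs[jj], k]
      if (!is.na(mv)) fit <- fit + (Xk[, obs_i[jj]] != mv)
    }
    forced <- rep(0L, nrow(Xk))
    elig_pos <- vector("list", E)  # per edge: rows where it delivers x_d's sign
    for (i in seq_len(E)) {
      pvec <- Xk[, ui[i]] * Xk[, di[i]]
      f <- if (redges$sign[i] == 1L) pvec == 1L else pvec == -1L
      forced <- forced + bitwShiftL(1L, i - 1L) * f
    }
    # support needs per target node
    exempt <- if (exempt_prior_targets) pk$node else character()
    need_assign <- integer(); need_mask <- integer()
    feasible <- rep(TRUE, nrow(Xk))
    for (d in unique(redges$target)) {
      if (d %in% exempt) next
      rows <- which(Xk[, d] != 0L)
      if (length(rows) == 0) next
      ids_in <- which(redges$target == d)
      elig <- rep(0L, length(rows))
      for (i in ids_in) {
        hit <- redges$sign[i] * Xk[rows, ui[i]] == Xk[rows, d]
        elig <- elig + bitwShiftL(1L, i - 1L) * hit
      }
      feasible[rows[elig == 0L]] <- FALSE
      keep2 <- elig != 0L
      need_assign <- c(need_assign, rows[keep2])
      need_mask <- c(need_mask, elig[keep2])
    }
    list(fit = fit, forced = forced, feasible = feasible,
         need_assign = need_assign, need_mask = need_mask, Xk = Xk)
  })
  names(per_cond) <- conds

  full <- bitwShiftL(1L, E) - 1L
  g_of <- function(pc, M) {
    ok <- pc$feasible & bitwAnd(pc$forced, bitwAnd(full, bitwNot(M))) == 0L
    if (length(pc$need_assign) > 0) {
      bad <- pc$need_assign[bitwAnd(pc$need_mask, M) == 0L]
      if (length(bad) > 0) ok[bad] <- FALSE
    }
    if (!any(ok)) return(Inf)
    min(pc$fit[ok])
  }

  masks <- if (E > 0) 0:full else 0L
  rem_bits <- if (n_rem > 0) bitwShiftL(1L, rem_idx - 1L) else integer()
  best <- list(obj = Inf, M = NA_integer_)
  min_fit_total <- sum(vapply(per_cond, g_of, numeric(1), M = full))
  if (!is.finite(min_fit_total)) {
    return(list(status = "infeasible", objective = NA_real_,
                fit_term = NA_real_, min_fit = NA_real_,
                n_removed = NA_integer_, removed = character(),
                states = NULL, n_optimal = 0L))
  }
  for (M in masks) {
    g <- vapply(per_cond, g_of, numeric(1), M = M)
    if (any(!is.finite(g))) next
    n_removed <- sum(bitwAnd(rem_bits, bitwNot(M)) != 0L)
    obj <- sum(g) + gamma * n_removed
    if (obj < best$obj - 1e-12) best <- list(obj = obj, M = M, g = g)
  }
  M <- best$M
  g <- best$g
  removed <- redges$id[rem_idx[bitwAnd(rem_bits, bitwNot(M)) != 0L]]

  states <- matrix(0L, length(nodes$id), L, dimnames = list(nodes$id, conds))
  n_opt <- 1L
  for (k in conds) {
    pc <- per_cond[[k]]
    ok <- pc$feasible & bitwAnd(pc$forced, bitwAnd(full, bitwNot(M))) == 0L
    if (length(pc$need_assign) > 0) {
      bad <- pc$need_assign[bitwAnd(pc$need_mask, M) == 0L]
      if (length(bad) > 0) ok[bad] <- FALSE
    }
    hits <- which(ok & pc$fit == g[[k]])
    n_opt <- n_opt * length(hits)
    states[inner, k] <- pc$Xk[hits[1], ]
  }
  defs <- output_definitions(network)
  for (k in conds) {
    for (o in out_ids) {
      d <- defs[defs$output == o, , drop = FALSE]
      states[o, k] <- sum(d$coef * states[d$tf, k])
    }
  }
  list(status = "optimal", objective = best$obj,
       fit_term = sum(g), min_fit = min_fit_total,
       n_removed = length(removed), removed = removed,
       states = states, n_optimal = n_opt)
}
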