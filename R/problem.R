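# Encoding of the ternary-state network inference problem as a MILP.
#
# Per condition k and node j, an integer x[j,k] in {-1,0,1} holds the
# ternary state (output nodes carry the signed TF sum, with wider
# bounds).  Binaries: sign split x = xp - xm; per-edge removal y
# (1 = dropped from the map); per-edge-and-condition occurrence z
# (0 = the reaction takes place, as in the source convention);
# mismatch indicators a for observed entries; product binaries w and
# support indicators pos/neg.  Objective: sum(a) + gamma * sum(y).

vkey <- function(...) paste(..., sep = "|")

default_gamma <- function(n_removable) {
  if (n_removable == 0) 0 else -0.5 / n_removable
}

check_gamma <- function(gamma, n_removable) {
  if (n_removable == 0) return(0)
  if (!is.numeric(gamma) || length(gamma) != 1 ||
      gamma >= 0 || gamma <= -1 / n_removable) {
    abort(sprintf(
      "`gamma` must lie in the open interval (-1/%d, 0); got %s",
      n_removable, format(gamma)))
  }
  gamma
}

#' Build the training problem for cell-specific network inference
#'
#' Encodes the generic map, the discretized perturbation profile, and
#' the prior-knowledge constraints as a mixed-integer linear program
#' whose optimum minimizes the number of observation mismatches and,
#' within that, maximizes the number of removed candidate edges
#' (`gamma` is negative with `|gamma| < 1/n_removable`, so a unit of
#' data fit is never traded for simplicity).
#'
#' The constraint system comprises: ternary sign-split domains; mismatch
#' indicators (`m - x <= 2a`, `x - m <= 2a`); removal/occurrence
#' coupling (`z >= y` per condition and `1 - y <= sum(1 - z)`);
#' product-linearized consistency bounds that force an activation edge
#' to occur when its endpoints are co-directed (and an inhibition edge
#' when anti-directed); an occurrence guard (a reaction cannot take
#' place from an unchanged parent); linking-pattern support (a node can
#' only change if some occurring incoming edge delivers a matching
#' signal); fixed output-node equalities; and prior targets pinned to
#' their literature direction.
#'
#' @param network A [signaling_network()].
#' @param profile Ternary profile (matrix or data frame; see
#'   [as_ternary_profile()]); rows must be network nodes, columns are
#'   the training conditions.  Missing entries contribute no mismatch
#'   term.
#' @param prior Optional prior-knowledge table (see [as_prior()]).
#' @param gamma Simplicity weight; default `-0.5 / n_removable`.
#' @param exempt_prior_targets Exempt a prior-pinned node from the
#'   support constraint in that condition (the compound acts on it
#'   directly).  Default `TRUE`.
#' @return A `ternet_problem` object.
#' @seealso [solve_problem()], [variable_accounting()],
#'   [build_prediction_problem()]
#' @export
build_training_problem <- function(network, profile, prior = NULL,
                                   gamma = NULL,
                                   exempt_prior_targets = TRUE) {
  build_problem(network, profile, prior, gamma, mode = "training",
                exempt_prior_targets = exempt_prior_targets)
}

#' Build the prediction (fixed-topology) problem
#'
#' Same constraint system as [build_training_problem()] minus the
#' edge-removal machinery: no removal variables, occurrence free per
#' condition, objective is the mismatch count only.  Used to re-optimize
#' an inferred cell-specific network against a new compound's profile.
#'
#' @inheritParams build_training_problem
#' @export
build_prediction_problem <- function(network, profile, prior = NULL,
                                     exempt_prior_targets = TRUE) {
  build_problem(network, profile, prior, gamma = 0, mode = "prediction",
                exempt_prior_targets = exempt_prior_targets)
}

build_problem <- function(network, profile, prior, gamma, mode,
                          exempt_prior_targets = TRUE) {
  stopifnot(inherits(network, "signaling_network"))
  profile <- as_ternary_profile(profile)
  prior <- as_prior(prior)
  nodes <- network$nodes
  edges <- network$edges
  conds <- colnames(profile)
  if (length(conds) == 0) abort("profile has no conditions")

  unknown <- setdiff(rownames(profile), nodes$id)
  if (length(unknown) > 0) {
    abort(paste0("profile row(s) not in network: ",
                 paste(unknown, collapse = ", ")))
  }
  if (nrow(prior) > 0) {
    if (length(setdiff(prior$node, nodes$id)) > 0) {
      abort(paste0("prior node(s) not in network: ",
                   paste(setdiff(prior$node, nodes$id), collapse = ", ")))
    }
    if (length(setdiff(prior$condition, conds)) > 0) {
      abort(paste0("prior condition(s) not in profile: ",
                   paste(setdiff(prior$condition, conds), collapse = ", ")))
    }
    out_ids <- nodes$id[nodes$role == "output"]
    if (any(prior$node %in% out_ids)) {
      abort("prior knowledge cannot target an output node")
    }
  }

  out_ids <- nodes$id[nodes$role == "output"]
  inner <- nodes$id[nodes$role != "output"]
  redges <- edges[!edges$target %in% out_ids, , drop = FALSE]  # reaction edges
  oedges <- edges[edges$target %in% out_ids, , drop = FALSE]
  rem <- redges$id[redges$removable]
  n_rem <- length(rem)
  gamma <- if (mode == "training") {
    check_gamma(if (is.null(gamma)) default_gamma(n_rem) else gamma, n_rem)
  } else 0

  L <- length(conds)
  m <- milp_new()

  # x for every node (integer domain); outputs bounded by their signed sum
  defs <- output_definitions(network)
  out_span <- vapply(out_ids, function(o) sum(abs(defs$coef[defs$output == o])),
                     numeric(1))
  for (k in conds) {
    milp_add_vars(m, vkey("x", inner, k), "x", "integer", -1, 1)
    if (length(out_ids) > 0) {
      milp_add_vars(m, vkey("x", out_ids, k), "x", "integer",
                    -out_span, out_span)
    }
    milp_add_vars(m, vkey("xp", inner, k), "xp", "binary", 0, 1)
    milp_add_vars(m, vkey("xm", inner, k), "xm", "binary", 0, 1)
  }
  if (mode == "training" && n_rem > 0) {
    milp_add_vars(m, vkey("y", rem), "y", "binary", 0, 1, obj = gamma)
  }
  for (k in conds) {
    if (nrow(redges) > 0) {
      milp_add_vars(m, vkey("z", redges$id, k), "z", "binary", 0, 1)
      for (fam in c("wpp", "wmm", "wpm", "wmp")) {
        milp_add_vars(m, vkey(fam, redges$id, k), fam, "binary", 0, 1)
      }
      milp_add_vars(m, vkey("pos", redges$id, k), "pos", "binary", 0, 1)
      milp_add_vars(m, vkey("neg", redges$id, k), "neg", "binary", 0, 1)
    }
  }

  # mismatch indicators for observed, non-missing entries
  obs_nodes <- intersect(rownames(profile), nodes$id[nodes$observed])
  mism <- list()
  for (k in conds) {
    for (j in obs_nodes) {
      if (!is.na(profile[j, k])) {
        milp_add_vars(m, vkey("a", j, k), "a", "binary", 0, 1, obj = 1)
        mism[[length(mism) + 1L]] <- c(j, k)
      }
    }
  }

  # sign split: x = xp - xm, xp + xm <= 1
  for (k in conds) {
    for (j in inner) {
      ix <- milp_idx(m, c(vkey("x", j, k), vkey("xp", j, k), vkey("xm", j, k)))
      milp_add_con(m, ix, c(1, -1, 1), 0, 0)
      milp_add_con(m, ix[2:3], c(1, 1), -Inf, 1)
    }
  }

  # output equalities: x_out = sum(coef * x_tf)
  for (k in conds) {
    for (o in out_ids) {
      d <- defs[defs$output == o, , drop = FALSE]
      ix <- milp_idx(m, c(vkey("x", o, k), vkey("x", d$tf, k)))
      milp_add_con(m, ix, c(1, -d$coef), 0, 0)
    }
  }

  # mismatch: m - x <= 2a  and  x - m <= 2a
  for (p in mism) {
    j <- p[1]; k <- p[2]
    mv <- profile[j, k]
    ix <- milp_idx(m, c(vkey("x", j, k), vkey("a", j, k)))
    milp_add_con(m, ix, c(1, 2), mv, Inf)    # x + 2a >= m
    milp_add_con(m, ix, c(1, -2), -Inf, mv)  # x - 2a <= m
  }

  # prior targets pinned to their literature direction
  exempt <- character()
  if (nrow(prior) > 0) {
    for (r in seq_len(nrow(prior))) {
      j <- prior$node[r]; k <- prior$condition[r]; dirn <- prior$direction[r]
      milp_set_bounds(m, vkey("x", j, k), dirn, dirn)
      if (exempt_prior_targets) exempt <- c(exempt, vkey(j, k))
      if (j %in% rownames(profile) && !is.na(profile[j, k]) &&
          profile[j, k] == -dirn) {
        message(sprintf(
          "prior direction for %s under %s contradicts the observation; prior wins",
          j, k))
      }
    }
  }

  # per-edge machinery
  for (i in seq_len(nrow(redges))) {
    e <- redges[i, ]
    act <- e$sign == 1L
    for (k in conds) {
      zi <- milp_idx(m, vkey("z", e$id, k))
      up <- milp_idx(m, vkey("xp", e$source, k))
      um <- milp_idx(m, vkey("xm", e$source, k))
      dp <- milp_idx(m, vkey("xp", e$target, k))
      dm <- milp_idx(m, vkey("xm", e$target, k))
      ws <- milp_idx(m, vkey(c("wpp", "wmm", "wpm", "wmp"), e$id, k))
      # AND linearization of the four endpoint sign products
      pairs <- list(c(up, dp), c(um, dm), c(up, dm), c(um, dp))
      for (q in 1:4) {
        b <- pairs[[q]]
        milp_add_con(m, c(ws[q], b[1]), c(1, -1), -Inf, 0)
        milp_add_con(m, c(ws[q], b[2]), c(1, -1), -Inf, 0)
        milp_add_con(m, c(ws[q], b[1], b[2]), c(-1, 1, 1), -Inf, 1)
      }
      # consistency bounds: p + z (activation) / p - z (inhibition) in [-1, 1]
      zc <- if (act) 1 else -1
      milp_add_con(m, c(ws, zi), c(1, 1, -1, -1, zc), -1, 1)
      # occurrence guard: 1 - z <= |x_u|
      milp_add_con(m, c(up, um, zi), c(1, 1, 1), 1, Inf)
      # support indicators: pos/neg only from a matching, occurring parent
      pi_ <- milp_idx(m, vkey("pos", e$id, k))
      ni_ <- milp_idx(m, vkey("neg", e$id, k))
      del_pos <- if (act) up else um
      del_neg <- if (act) um else up
      milp_add_con(m, c(pi_, del_pos), c(1, -1), -Inf, 0)
      milp_add_con(m, c(pi_, zi), c(1, 1), -Inf, 1)
      milp_add_con(m, c(ni_, del_neg), c(1, -1), -Inf, 0)
      milp_add_con(m, c(ni_, zi), c(1, 1), -Inf, 1)
    }
    if (mode == "training" && e$removable) {
      yi <- milp_idx(m, vkey("y", e$id))
      zs <- milp_idx(m, vkey("z", e$id, conds))
      for (zi in zs) milp_add_con(m, c(zi, yi), c(1, -1), 0, Inf)  # z >= y
      milp_add_con(m, c(zs, yi), c(rep(1, L), -1), -Inf, L - 1)    # 1-y <= sum(1-z)
    }
  }

  # linking-pattern support: a changed node needs an occurring incoming
  # edge delivering the matching sign (roots and prior targets exempt)
  in_edges <- split(redges$id, redges$target)
  for (k in conds) {
    for (d in names(in_edges)) {
      if (vkey(d, k) %in% exempt) next
      ids <- in_edges[[d]]
      dp <- milp_idx(m, vkey("xp", d, k))
      dm <- milp_idx(m, vkey("xm", d, k))
      ps <- milp_idx(m, vkey("pos", ids, k))
      ns <- milp_idx(m, vkey("neg", ids, k))
      milp_add_con(m, c(dp, ps), c(1, rep(-1, length(ps))), -Inf, 0)
      milp_add_con(m, c(dm, ns), c(1, rep(-1, length(ns))), -Inf, 0)
    }
  }

  structure(list(milp = m, network = network, profile = profile,
                 prior = prior, gamma = gamma, mode = mode,
                 conditions = conds, reaction_edges = redges,
                 removable = rem, observed_nodes = obs_nodes),
            class = "ternet_problem")
}

#' @export
print.ternet_problem <- function(x, ...) {
  acc <- variable_accounting(x)
  cat(sprintf("<ternet_problem> mode=%s | %d variables (%d integer, %d binary), %d constraints, gamma=%g\n",
              x$mode, sum(acc$n), sum(acc$n[acc$domain == "integer"]),
              sum(acc$n[acc$domain == "binary"]), x$milp$n_con, x$gamma))
  invisible(x)
}

#' Variable accounting of a built problem
#'
#' Counts decision variables by family (node state `x`, sign splits,
#' removal `y`, occurrence `z`, mismatch `a`, product and support
#' auxiliaries) and by domain.  The integer-domain count equals
#' nodes x conditions; everything else is binary.
#'
#' @param problem A `ternet_problem`.
#' @return Tibble with columns `family`, `domain`, `n`.
#' @export
variable_accounting <- function(problem) {
  m <- problem$milp
  tibble::tibble(family = m$family, domain = m$domain) |>
    dplyr::count(.data$family, .data$domain, name = "n") |>
    dplyr::arrange(dplyr::desc(.data$n))
}

#' Export a built problem in LP format
#'
#' Writes the mixed-integer program in CPLEX LP format for inspection
#' with any external solver.
#'
#' @param problem A `ternet_problem`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lp <- function(problem, path) {
  milp_write_lp(problem$milp, path)
}

#' Solve a built problem to proven optimality
#'
#' Runs the HiGHS mixed-integer solver (through the bundled scipy
#' bridge) with a zero relative MIP gap, so a returned optimum is exact.
#' Solutions are integral within 1e-6 and are rounded on extraction.
#'
#' @param problem A `ternet_problem`, or a list of them (solved in one
#'   backend call).
#' @param time_limit Optional wall-clock limit in seconds; hitting it
#'   yields status `"error"` with the best bound in the message.
#' @param seed Unused by the deterministic backend; accepted so run
#'   manifests can record one interface-wide.
#' @return A `ternet_solution` (or list of them): solver `status`
#'   (`"optimal"`, `"infeasible"`, `"error"`), `objective`, `fit_term`
#'   (mismatch count), `simplicity_term` (removed-edge count), and the
#'   decoded variable values.
#' @export
solve_problem <- function(problem, time_limit = NULL, seed = NULL) {
  single <- inherits(problem, "ternet_problem")
  problems <- if (single) list(problem) else problem
  raw <- solve_milp(lapply(problems, `[[`, "milp"), time_limit = time_limit)
  out <- purrr::map2(raw, problems, decode_raw_solution)
  if (single) out[[1]] else out
}

decode_raw_solution <- function(r, problem) {
  if (r$status != "optimal" || is.null(r$x)) {
    return(structure(list(status = r$status, message = r$message,
                          objective = NA_real_, fit_term = NA_real_,
                          simplicity_term = NA_real_, values = NULL),
                     class = "ternet_solution"))
  }
  v <- r$x
  if (max(abs(v - round(v))) > 1e-6) {
    abort("solver returned non-integral values beyond tolerance 1e-6")
  }
  v <- round(v)
  fam <- problem$milp$family
  structure(list(status = "optimal", message = r$message,
                 objective = r$objective,
                 fit_term = sum(v[fam == "a"]),
                 simplicity_term = sum(v[fam == "y"]),
                 values = v),
            class = "ternet_solution")
}

#' @export
print.ternet_solution <- function(x, ...) {
  cat(sprintf("<ternet_solution> status=%s objective=%s fit=%s removed=%s\n",
              x$status, format(x$objective), format(x$fit_term),
              format(x$simplicity_term)))
  invisible(x)
}

#' Decode a solved problem into domain quantities
#'
#' Extracts per-condition node states, per-condition reaction
#' occurrences, and the removed-edge set, re-asserting the
#' removal/occurrence coupling (a removed edge occurs nowhere; a kept
#' removable edge occurs somewhere in training mode).
#'
#' @param problem The `ternet_problem` that was solved.
#' @param solution The matching optimal `ternet_solution`.
#' @return List with `states` (nodes x conditions integer matrix),
#'   `occurrences` (edges x conditions logical matrix, `TRUE` = the
#'   reaction takes place) and `removed` (edge ids).
#' @export
decode_solution <- function(problem, solution) {
  if (solution$status != "optimal") {
    abort(paste0("cannot decode a non-optimal solution (status ",
                 solution$status, ")"))
  }
  v <- solution$values
  conds <- problem$conditions
  node_ids <- problem$network$nodes$id
  states <- vapply(conds, function(k) v[vkey("x", node_ids, k)],
                   numeric(length(node_ids)))
  if (!is.matrix(states)) states <- matrix(states, nrow = length(node_ids))
  dimnames(states) <- list(node_ids, conds)
  eids <- problem$reaction_edges$id
  occ <- NULL
  if (length(eids) > 0) {
    occ <- vapply(conds, function(k) v[vkey("z", eids, k)] == 0,
                  logical(length(eids)))
    if (!is.matrix(occ)) occ <- matrix(occ, nrow = length(eids))
    dimnames(occ) <- list(eids, conds)
  }
  removed <- character()
  if (problem$mode == "training" && length(problem$removable) > 0) {
    yv <- v[vkey("y", problem$removable)]
    removed <- problem$removable[yv == 1]
    # coupling re-asserted: y=1 => never occurs; y=0 => occurs somewhere
    for (i in problem$removable) {
      zrow <- !occ[i, , drop = TRUE]
      if (i %in% removed && !all(zrow)) {
        abort(sprintf("internal decode error: removed edge `%s` occurs", i))
      }
      if (!(i %in% removed) && all(zrow)) {
        abort(sprintf("internal decode error: kept edge `%s` never occurs", i))
      }
    }
  }
  list(states = states, occurrences = occ, removed = removed)
}

#' Linearize the product of two ternary states
#'
#' The consistency bounds use the product of the two endpoint states of
#' an edge.  With each state split into sign indicators
#' (`u = u_plus - u_minus`, at most one of them 1), the product equals
#' `w(u+,d+) + w(u-,d-) - w(u+,d-) - w(u-,d+)` where each `w` is the
#' AND of its two indicator bits, enforced in the program by
#' `w <= b1`, `w <= b2`, `w >= b1 + b2 - 1`.  This helper evaluates the
#' construction for given indicator bits.
#'
#' @param u_plus,u_minus,d_plus,d_minus Sign-indicator bits (0/1) of the
#'   parent and child states.
#' @return List with the four `w` bits and the decoded product `p`.
#' @export
#' @examples
#' linearize_product(1, 0, 0, 1)$p  # (+1) * (-1) = -1
linearize_product <- function(u_plus, u_minus, d_plus, d_minus) {
  stopifnot(u_plus + u_minus <= 1, d_plus + d_minus <= 1,
            all(c(u_plus, u_minus, d_plus, d_minus) %in% 0:1))
  and2 <- function(b1, b2) {
    w <- max(0, b1 + b2 - 1)  # lower bound of the linearization
    stopifnot(w <= b1, w <= b2)  # its upper bounds pin w to the AND
    w
  }
  w <- c(pp = and2(u_plus, d_plus), mm = and2(u_minus, d_minus),
         pm = and2(u_plus, d_minus), mp = and2(u_minus, d_plus))
  list(w = w, p = unname(w["pp"] + w["mm"] - w["pm"] - w["mp"]))
}
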