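# Internal mixed-integer linear program container and solver bridge.
#
# Variables and constraints are accumulated into flat vectors/triplets;
# the model is solved by scipy's HiGHS backend through the bundled
# python script (JSON in, JSON out).  All problems in one solve_milp()
# call share a single python process.

milp_new <- function() {
  env <- new.env(parent = emptyenv())
  env$n_var <- 0L
  env$name <- character()
  env$family <- character()
  env$domain <- character()   # "integer" or "binary" (binaries solve as integer 0/1)
  env$lb <- numeric()
  env$ub <- numeric()
  env$obj <- numeric()
  env$idx <- new.env(parent = emptyenv(), size = 4096L)
  env$con_i <- vector("list", 256L)
  env$con_lb <- numeric()
  env$con_ub <- numeric()
  env$n_con <- 0L
  class(env) <- "ternet_milp"
  env
}

milp_add_vars <- function(m, names, family, domain, lb, ub, obj = 0) {
  n <- length(names)
  if (n == 0L) return(invisible(m))
  k <- m$n_var
  m$name <- c(m$name, names)
  m$family <- c(m$family, rep_len(family, n))
  m$domain <- c(m$domain, rep_len(domain, n))
  m$lb <- c(m$lb, rep_len(lb, n))
  m$ub <- c(m$ub, rep_len(ub, n))
  m$obj <- c(m$obj, rep_len(obj, n))
  for (j in seq_len(n)) assign(names[j], k + j, envir = m$idx)
  m$n_var <- k + n
  invisible(m)
}

milp_idx <- function(m, names) {
  vapply(names, function(nm) get(nm, envir = m$idx), integer(1),
         USE.NAMES = FALSE)
}

# coefs: named numeric vector (names = variable names) or an integer
# index vector with a parallel `val` argument
milp_add_con <- function(m, idx, val, lb, ub) {
  m$n_con <- m$n_con + 1L
  if (m$n_con > length(m$con_i)) {
    length(m$con_i) <- 2L * length(m$con_i)
  }
  m$con_i[[m$n_con]] <- list(idx = idx, val = val)
  m$con_lb[m$n_con] <- lb
  m$con_ub[m$n_con] <- ub
  invisible(m)
}

milp_set_bounds <- function(m, name, lb, ub) {
  j <- milp_idx(m, name)
  m$lb[j] <- pmax(m$lb[j], lb)
  m$ub[j] <- pmin(m$ub[j], ub)
  invisible(m)
}

milp_as_list <- function(m) {
  cons <- m$con_i[seq_len(m$n_con)]
  nnz <- vapply(cons, function(cc) length(cc$idx), integer(1))
  list(
    obj = m$obj,
    integrality = rep(1L, m$n_var),
    lb = m$lb,
    ub = m$ub,
    a_row = rep(seq_len(m$n_con), nnz),
    a_col = unlist(lapply(cons, `[[`, "idx"), use.names = FALSE),
    a_val = unlist(lapply(cons, `[[`, "val"), use.names = FALSE),
    n_con = m$n_con,
    c_lb = m$con_lb[seq_len(m$n_con)],
    c_ub = m$con_ub[seq_len(m$n_con)]
  )
}

milp_python <- function() {
  py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py)) abort("no `python` found on PATH; the MILP backend needs python + scipy")
  py
}

#' @keywords internal
solve_milp <- function(problems, time_limit = NULL, mip_rel_gap = 0) {
  single <- inherits(problems, "ternet_milp")
  if (single) problems <- list(problems)
  payload <- lapply(problems, function(m) {
    p <- milp_as_list(m)
    p$time_limit <- time_limit
    p$mip_rel_gap <- mip_rel_gap
    p
  })
  inp <- tempfile(fileext = ".json")
  outp <- tempfile(fileext = ".json")
  on.exit(unlink(c(inp, outp)), add = TRUE)
  jsonlite::write_json(payload, inp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  script <- system.file("python", "milp_solve.py", package = "ternet")
  status <- system2(milp_python(), c(shQuote(script), shQuote(inp), shQuote(outp)),
                    stdout = FALSE, stderr = "")
  if (status != 0L || !file.exists(outp)) {
    abort(sprintf("MILP backend failed (exit status %d)", status))
  }
  res <- jsonlite::read_json(outp, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  out <- purrr::map2(res, problems, function(r, m) {
    status <- switch(as.character(r$status),
                     "0" = "optimal", "2" = "infeasible", "error")
    x <- if (is.null(r$x) || length(r$x) == 0) NULL else {
      stats::setNames(as.numeric(r$x), m$name)
    }
    list(status = status, message = r$message, x = x,
         objective = if (is.null(r$fun)) NA_real_ else as.numeric(r$fun),
         mip_gap = if (is.null(r$mip_gap)) NA_real_ else as.numeric(r$mip_gap))
  })
  if (single) out[[1]] else out
}

# CPLEX-LP-format export for solver-independent inspection
milp_write_lp <- function(m, path) {
  vn <- gsub("[^A-Za-z0-9_]", "_", m$name)
  term <- function(idx, val) {
    paste(sprintf("%+g %s", val, vn[idx]), collapse = " ")
  }
  lines <- c("Minimize", paste(" obj:", term(which(m$obj != 0), m$obj[m$obj != 0])),
             "Subject To")
  for (r in seq_len(m$n_con)) {
    cc <- m$con_i[[r]]
    lhs <- term(cc$idx, cc$val)
    lb <- m$con_lb[r]; ub <- m$con_ub[r]
    if (is.finite(lb) && is.finite(ub) && lb == ub) {
      lines <- c(lines, sprintf(" c%d: %s = %g", r, lhs, lb))
    } else {
      if (is.finite(ub)) lines <- c(lines, sprintf(" c%d_u: %s <= %g", r, lhs, ub))
      if (is.finite(lb)) lines <- c(lines, sprintf(" c%d_l: %s >= %g", r, lhs, lb))
    }
  }
  lines <- c(lines, "Bounds",
             sprintf(" %g <= %s <= %g", m$lb, vn, m$ub),
             "General", paste("", paste(vn, collapse = " ")), "End")
  writeLines(lines, path)
  invisible(path)
}
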