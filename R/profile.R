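#' Read a protein-by-condition log-ratio matrix
#'
#' Values are log2(treatment/control) ratios, rows proteins, columns
#' treatment conditions.  TSV/CSV files carry the protein id in the
#' first column and condition ids in the header; GCT 1.3 files are read
#' per the format (the dimension line and row/column metadata blocks are
#' skipped).
#'
#' @param path Input file.
#' @param format `"tsv"`, `"csv"` or `"gct"`; guessed from the file
#'   extension by default.
#' @return Numeric matrix with unique protein rownames and condition
#'   colnames; missing values stay `NA`.
#' @export
read_matrix <- function(path, format = c("auto", "tsv", "csv", "gct")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("tsv", "csv", "gct")) ext else "tsv"
  }
  if (format == "gct") {
    return(read_gct(path))
  }
  reader <- if (format == "csv") readr::read_csv else readr::read_tsv
  df <- reader(path, show_col_types = FALSE, progress = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate protein id(s): ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  if (anyDuplicated(names(df)[-1])) {
    abort("duplicate condition id(s) in header")
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) abort("non-numeric values in matrix body")
  rownames(m) <- ids
  m
}

# GCT 1.3: line 1 "#1.3", line 2 "nrow ncol nrowmeta ncolmeta",
# then a header row, nrowmeta metadata columns after the id column and
# ncolmeta metadata rows before the data block.
read_gct <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3 || !startsWith(lines[1], "#1.")) {
    abort("not a GCT file (missing #1.x version line)")
  }
  dims <- as.integer(strsplit(trimws(lines[2]), "\t")[[1]])
  if (length(dims) < 2 || anyNA(dims[1:2])) abort("malformed GCT dimension line")
  n_row <- dims[1]; n_col <- dims[2]
  n_rmeta <- if (length(dims) >= 3 && !is.na(dims[3])) dims[3] else 0L
  n_cmeta <- if (length(dims) >= 4 && !is.na(dims[4])) dims[4] else 0L
  header <- strsplit(lines[3], "\t")[[1]]
  cond_ids <- header[(2L + n_rmeta):(1L + n_rmeta + n_col)]
  body <- lines[(4L + n_cmeta):(3L + n_cmeta + n_row)]
  parts <- strsplit(body, "\t")
  ids <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(ids)) abort("duplicate protein id(s) in GCT")
  vals <- t(vapply(parts, function(p) {
    suppressWarnings(as.numeric(p[(2L + n_rmeta):(1L + n_rmeta + n_col)]))
  }, numeric(n_col)))
  if (n_col == 1L) vals <- matrix(vals, ncol = 1L)
  dimnames(vals) <- list(ids, cond_ids)
  vals
}

#' Discretize log2 ratios to ternary states
#'
#' A protein is called up-regulated (+1) when its log2 ratio reaches
#' `log2(threshold)`, down-regulated (-1) when it falls to
#' `-log2(threshold)`, and unchanged (0) in between; both boundaries are
#' inclusive.  The default fold-change threshold is 1.2.  Replicate
#' columns sharing a condition id are averaged on the log2 scale before
#' thresholding.
#'
#' @param x Numeric matrix (proteins x conditions) of log2 ratios, or a
#'   data frame whose first column holds protein ids.
#' @param threshold Fold-change threshold, must exceed 1.
#' @return Integer matrix over \{-1, 0, +1\} (class `ternary_profile`);
#'   `NA` entries stay missing.
#' @export
#' @examples
#' m <- matrix(c(0.5, 0, -1), nrow = 3,
#'             dimnames = list(c("A", "B", "C"), "drug1"))
#' ternarize(m, threshold = 1.2)
ternarize <- function(x, threshold = 1.2) {
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold <= 1) {
    abort("`threshold` must be a single fold-change value > 1")
  }
  m <- as_ratio_matrix(x)
  # average replicate columns sharing a condition id on the log2 scale
  if (anyDuplicated(colnames(m))) {
    conds <- unique(colnames(m))
    m <- vapply(conds, function(k) {
      rowMeans(m[, colnames(m) == k, drop = FALSE], na.rm = FALSE)
    }, numeric(nrow(m)))
    if (!is.matrix(m)) m <- matrix(m, nrow = 1, dimnames = list(rownames(x), conds))
  }
  cut <- log2(threshold)
  t3 <- matrix(0L, nrow(m), ncol(m), dimnames = dimnames(m))
  t3[m >= cut] <- 1L
  t3[m <= -cut] <- -1L
  t3[is.na(m)] <- NA_integer_
  structure(t3, class = c("ternary_profile", class(t3)))
}

as_ratio_matrix <- function(x) {
  if (is.data.frame(x)) {
    ids <- as.character(x[[1]])
    m <- as.matrix(x[, -1, drop = FALSE])
    rownames(m) <- ids
    x <- m
  }
  if (!is.matrix(x) || !is.numeric(x)) {
    abort("expected a numeric matrix or a data frame with an id column")
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    abort("matrix needs protein rownames and condition colnames")
  }
  x
}

#' Coerce a ternary profile to a matrix of states
#'
#' Accepts a `ternary_profile`, a plain matrix over \{-1, 0, 1, NA\}, or
#' a data frame with an id column; validates the domain.
#' @param x Profile input.
#' @return Integer matrix over \{-1, 0, 1\} with `NA` for missing.
#' @export
as_ternary_profile <- function(x) {
  if (is.data.frame(x)) {
    ids <- as.character(x[[1]])
    x <- as.matrix(x[, -1, drop = FALSE])
    rownames(x) <- ids
  }
  m <- x
  if (!is.matrix(m)) abort("expected a matrix or data frame profile")
  storage.mode(m) <- "integer"
  ok <- is.na(m) | m %in% c(-1L, 0L, 1L)
  if (!all(ok)) abort("profile entries must lie in {-1, 0, 1} or be missing")
  class(m) <- c("ternary_profile", "matrix", "array")
  m
}

#' Differentially expressed proteins of a ternary profile
#'
#' @param profile Ternary profile (see [as_ternary_profile()]).
#' @return Character vector of proteins with at least one non-zero
#'   (non-missing) state in any condition.
#' @export
select_deps <- function(profile) {
  m <- as_ternary_profile(profile)
  hit <- apply(m, 1, function(r) any(r != 0L, na.rm = TRUE))
  rownames(m)[hit]
}

#' Read a prior-knowledge table
#'
#' Literature-confirmed direct targets per compound: a tab-separated
#' table with columns `condition`, `node`, `direction`, the direction
#' one of `up`/`+1`/`1` or `down`/`-1`.
#'
#' @param path TSV path.
#' @return Tibble with columns `condition`, `node` and integer
#'   `direction` in \{-1, +1\}.
#' @export
read_prior <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = "c"))
  if (!all(c("condition", "node", "direction") %in% names(df))) {
    abort("prior table needs columns `condition`, `node`, `direction`")
  }
  as_prior(df)
}

#' Normalize a prior-knowledge table
#'
#' @param prior Data frame with columns `condition`, `node`,
#'   `direction`; `NULL` yields an empty prior.
#' @return Tibble with `direction` coerced to -1/+1; duplicate
#'   (condition, node) pairs are rejected.
#' @export
as_prior <- function(prior) {
  if (is.null(prior)) {
    return(tibble::tibble(condition = character(), node = character(),
                          direction = integer()))
  }
  df <- tibble::as_tibble(prior)
  dir_chr <- tolower(as.character(df$direction))
  dir <- dplyr::case_match(dir_chr, c("up", "+1", "1") ~ 1L,
                           c("down", "-1") ~ -1L)
  if (anyNA(dir) && nrow(df) > 0) {
    abort(paste0("unknown direction token(s): ",
                 paste(unique(dir_chr[is.na(dir)]), collapse = ", ")))
  }
  key <- paste(df$condition, df$node)
  if (anyDuplicated(key)) {
    abort(paste0("duplicate prior record(s): ",
                 paste(unique(key[duplicated(key)]), collapse = "; ")))
  }
  tibble::tibble(condition = as.character(df$condition),
                 node = as.character(df$node), direction = dir)
}

#' @export
tidy.ternary_profile <- function(x, ...) {
  m <- unclass(x)
  tibble::as_tibble(as.data.frame.table(m, stringsAsFactors = FALSE),
                    .name_repair = "minimal") |>
    stats::setNames(c("protein", "condition", "state")) |>
    tibble::as_tibble()
}

#' Heatmap of a ternary profile
#'
#' @param object A `ternary_profile`.
#' @param ... Unused.
#' @return A ggplot object: conditions x proteins tile map colored by
#'   ternary state.
#' @export
autoplot.ternary_profile <- function(object, ...) {
  df <- tidy(object)
  df$state <- factor(df$state, levels = c(-1, 0, 1),
                     labels = c("down", "no-change", "up"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$condition, y = .data$protein,
                                   fill = .data$state)) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::scale_fill_manual(
      values = c(down = "#2c7bb6", `no-change` = "grey95", up = "#d7191c"),
      na.value = "grey60", drop = FALSE) +
    ggplot2::labs(x = NULL, y = NULL, fill = "state") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
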