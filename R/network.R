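#' Construct a signed signaling network
#'
#' A signaling network couples a node table (proteins, transcription
#' factors, and cell-function output nodes) with a signed directed edge
#' table.  Output nodes are fixed arithmetic readouts of their upstream
#' transcription factors; edges into them are definitional and are never
#' candidates for data-driven removal.
#'
#' @param nodes Data frame with columns `id` (unique character), `role`
#'   (one of `"protein"`, `"transcription_factor"`, `"output"`),
#'   `observed` (logical), and optionally `display_name`.
#' @param edges Data frame with columns `source`, `target`, `sign`
#'   (+1 activation / -1 inhibition) and optionally `id` and `removable`.
#'   `removable` defaults to `TRUE` except for edges into output nodes,
#'   which are always fixed.
#' @param validate Stop on invariant violations (default `TRUE`).
#'
#' @return An object of class `signaling_network`: a list with tibbles
#'   `nodes` and `edges`.
#' @seealso [read_sif()], [validate_network()], [network_stats()]
#' @export
#' @examples
#' net <- signaling_network(
#'   nodes = data.frame(id = c("A", "B"), role = "protein", observed = TRUE),
#'   edges = data.frame(source = "A", target = "B", sign = 1)
#' )
#' network_stats(net)
signaling_network <- function(nodes, edges, validate = TRUE) {
  nodes <- tibble::as_tibble(nodes)
  if (!all(c("id", "role") %in% names(nodes))) {
    abort("`nodes` needs columns `id` and `role`")
  }
  if (is.null(nodes[["observed"]])) nodes$observed <- FALSE
  if (is.null(nodes[["display_name"]])) nodes$display_name <- NA_character_
  nodes <- dplyr::select(nodes, "id", "role", "observed", "display_name")
  nodes$id <- as.character(nodes$id)
  nodes$observed <- as.logical(nodes$observed)

  edges <- tibble::as_tibble(edges)
  if (nrow(edges) == 0 && !all(c("source", "target", "sign") %in% names(edges))) {
    edges <- tibble::tibble(source = character(), target = character(),
                            sign = integer())
  }
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  edges$sign <- as.integer(edges$sign)
  out_ids <- nodes$id[nodes$role == "output"]
  if (is.null(edges[["removable"]])) {
    edges$removable <- !(edges$target %in% out_ids)
  }
  edges$removable <- as.logical(edges$removable) & !(edges$target %in% out_ids)
  if (is.null(edges[["id"]])) {
    edges$id <- paste0(edges$source, ifelse(edges$sign >= 0, "->", "-|"),
                       edges$target)
  }
  edges <- dplyr::select(edges, "id", "source", "target", "sign", "removable")

  net <- structure(list(nodes = nodes, edges = edges),
                   class = "signaling_network")
  if (validate) {
    v <- validate_network(net)
    if (nrow(v) > 0) {
      abort(c("invalid signaling network",
              stats::setNames(v$message, rep("x", nrow(v)))))
    }
  }
  net
}

#' @export
print.signaling_network <- function(x, ...) {
  s <- network_stats(x)
  cat(sprintf(
    "<signaling_network> %d nodes (%d observed), %d edges (%d removable, %d inhibitory)\n",
    s$n_nodes, s$n_observed, s$n_edges, s$n_removable, s$n_inhibition))
  invisible(x)
}

#' Validate signaling-network invariants
#'
#' Checks the structural rules a network must satisfy before it can be
#' encoded as an integer program: unique ids, resolvable endpoints, no
#' self-loops, no duplicate signed edges, output nodes unobserved with no
#' outgoing edges and only fixed (non-removable) incoming edges, and each
#' transcription factor wired to at most one output readout.
#'
#' @param network A `signaling_network` (possibly built with
#'   `validate = FALSE`).
#' @return A tibble of violations with columns `element`, `rule` and
#'   `message`; zero rows if the network is valid.  Violations are data,
#'   not errors.
#' @export
validate_network <- function(network) {
  nodes <- network$nodes
  edges <- network$edges
  v <- list()
  bad <- function(element, rule, message) {
    v[[length(v) + 1L]] <<- tibble::tibble(element = element, rule = rule,
                                           message = message)
  }

  dup <- nodes$id[duplicated(nodes$id)]
  for (id in unique(dup)) bad(id, "unique-node-id", paste0("duplicate node id `", id, "`"))
  bad_role <- !nodes$role %in% c("protein", "transcription_factor", "output")
  for (id in nodes$id[bad_role]) bad(id, "known-role", paste0("node `", id, "` has unknown role"))

  out_ids <- nodes$id[nodes$role == "output"]
  for (id in intersect(nodes$id[nodes$observed], out_ids)) {
    bad(id, "output-unobserved", paste0("output node `", id, "` cannot be observed"))
  }

  missing_src <- setdiff(edges$source, nodes$id)
  missing_tgt <- setdiff(edges$target, nodes$id)
  for (id in missing_src) bad(id, "endpoint-exists", paste0("edge source `", id, "` not in node table"))
  for (id in missing_tgt) bad(id, "endpoint-exists", paste0("edge target `", id, "` not in node table"))

  self <- edges$id[edges$source == edges$target]
  for (id in self) bad(id, "no-self-loop", paste0("edge `", id, "` is a self-loop"))

  key <- paste(edges$source, edges$target, edges$sign)
  for (id in edges$id[duplicated(key)]) {
    bad(id, "no-duplicate-edge", paste0("duplicate signed edge `", id, "`"))
  }
  if (!all(edges$sign %in% c(-1L, 1L))) {
    for (id in edges$id[!edges$sign %in% c(-1L, 1L)]) {
      bad(id, "sign-domain", paste0("edge `", id, "` has sign outside {-1, +1}"))
    }
  }

  for (id in edges$id[edges$source %in% out_ids]) {
    bad(id, "output-terminal", paste0("edge `", id, "` leaves an output node"))
  }
  for (id in edges$id[edges$target %in% out_ids & edges$removable]) {
    bad(id, "output-edge-fixed", paste0("edge `", id, "` into an output node must be non-removable"))
  }
  # a TF may feed at most one output readout, with one fixed coefficient
  tf_out <- edges[edges$target %in% out_ids, , drop = FALSE]
  multi <- names(which(table(tf_out$source) > 1))
  for (id in multi) bad(id, "tf-single-output", paste0("node `", id, "` feeds more than one output"))

  if (length(v) == 0) {
    return(tibble::tibble(element = character(), rule = character(),
                          message = character()))
  }
  dplyr::bind_rows(v)
}

#' Read a signed network from a SIF file
#'
#' Parses the simple interaction format (one tab-separated
#' `source relation target` triple per line) together with an optional
#' node-annotation table.  Relation tokens `1`/`activates` encode
#' activation and `-1`/`inhibits` encode inhibition.
#'
#' @param path Path to the SIF file.
#' @param annotations_path Optional path to a tab-separated node table
#'   with header `id`, `role`, `observed` (and optionally
#'   `display_name`).  Nodes appearing only in the SIF default to
#'   role `"protein"`, unobserved.
#' @return A validated [signaling_network()].
#' @export
read_sif <- function(path, annotations_path = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  n_fields <- lengths(parts)
  if (any(n_fields != 3L)) {
    bad <- which(n_fields != 3L)[1]
    abort(sprintf("malformed SIF line %d: expected 3 tab-separated fields, got %d",
                  bad, n_fields[bad]))
  }
  rel <- vapply(parts, `[[`, "", 2L)
  sign <- dplyr::case_match(rel, c("1", "activates") ~ 1L,
                            c("-1", "inhibits") ~ -1L)
  if (anyNA(sign)) {
    bad <- which(is.na(sign))[1]
    abort(sprintf("unknown relation token `%s` on SIF line %d", rel[bad], bad))
  }
  edges <- tibble::tibble(source = vapply(parts, `[[`, "", 1L),
                          target = vapply(parts, `[[`, "", 3L),
                          sign = sign)

  sif_ids <- unique(c(edges$source, edges$target))
  nodes <- tibble::tibble(id = sif_ids, role = "protein", observed = FALSE,
                          display_name = NA_character_)
  if (!is.null(annotations_path)) {
    ann <- readr::read_tsv(annotations_path, show_col_types = FALSE,
                           progress = FALSE)
    if (!all(c("id", "role", "observed") %in% names(ann))) {
      abort("annotation table needs columns `id`, `role`, `observed`")
    }
    orphan <- setdiff(ann$id, sif_ids)
    if (length(orphan) > 0 && is.null(ann[["isolated"]])) {
      abort(paste0("annotated node(s) absent from SIF: ",
                   paste(orphan, collapse = ", "),
                   " (declare an `isolated` column to keep them)"))
    }
    if (is.null(ann[["display_name"]])) ann$display_name <- NA_character_
    nodes <- dplyr::bind_rows(
      dplyr::select(ann, "id", "role", "observed", "display_name"),
      nodes[!nodes$id %in% ann$id, ]
    )
  }
  signaling_network(nodes, edges)
}

#' Write a network to SIF (and optionally its node annotations)
#'
#' @param network A `signaling_network`.
#' @param path Output SIF path.
#' @param annotations_path Optional path for the node-annotation TSV.
#' @return `path`, invisibly.  `read_sif(write_sif(net))` restores the
#'   network up to edge ordering.
#' @export
write_sif <- function(network, path, annotations_path = NULL) {
  e <- network$edges
  lines <- sprintf("%s\t%d\t%s", e$source, e$sign, e$target)
  writeLines(lines, path)
  if (!is.null(annotations_path)) {
    ann <- network$nodes
    iso <- !ann$id %in% c(e$source, e$target)
    if (any(iso)) ann$isolated <- iso  # keeps edge-less nodes readable back
    readr::write_tsv(ann, annotations_path, progress = FALSE)
  }
  invisible(path)
}

#' Summary statistics of a signaling network
#'
#' @param network A `signaling_network`.
#' @return One-row tibble: node/edge counts, observed and removable
#'   counts, activation/inhibition counts, and the number of root nodes
#'   (no incoming edges).
#' @export
network_stats <- function(network) {
  nodes <- network$nodes
  edges <- network$edges
  roots <- setdiff(nodes$id[nodes$role != "output"], edges$target)
  tibble::tibble(
    n_nodes = nrow(nodes),
    n_edges = nrow(edges),
    n_observed = sum(nodes$observed),
    n_removable = sum(edges$removable),
    n_activation = sum(edges$sign == 1L),
    n_inhibition = sum(edges$sign == -1L),
    n_outputs = sum(nodes$role == "output"),
    n_roots = length(roots)
  )
}

#' Output-node definitions of a network
#'
#' Each cell-function output node is the signed sum of its upstream
#' transcription-factor states; the edge sign is the coefficient
#' (+1 for a factor that promotes the function, -1 for one that
#' suppresses it).
#'
#' @param network A `signaling_network`.
#' @return Tibble with columns `output`, `tf`, `coef`.
#' @export
output_definitions <- function(network) {
  out_ids <- network$nodes$id[network$nodes$role == "output"]
  e <- network$edges[network$edges$target %in% out_ids, , drop = FALSE]
  tibble::tibble(output = e$target, tf = e$source, coef = e$sign)
}

#' Packaged MCF7-style generic pathway map
#'
#' A literature-style transcription of a breast-cancer signaling map
#' covering ER/SHC, EGFR, HER2, INSR, MAPK (MEK/ERK and JNK), PI3K/AKT,
#' HSP90/HIF, AMPK, HDAC and ATM/BRCA1/p53 signaling: 35 nodes
#' (including four cell-function outputs) and 50 signed edges, 15 of the
#' protein nodes flagged as observed in the phosphoproteomic assay.
#' Edge-level topology within the named pathways is a best-effort
#' reconstruction; analyses should rely on its aggregate shape, not on
#' any individual link.
#'
#' @return A `signaling_network`.
#' @export
mcf7_generic_map <- function() {
  read_sif(system.file("extdata", "mcf7_map.sif", package = "ternet"),
           system.file("extdata", "mcf7_nodes.tsv", package = "ternet"))
}

#' Packaged literature prior for the MCF7 training compounds
#'
#' Known direct-target directions for the ten training compounds
#' (e.g. fulvestrant down-regulates ER; HDAC inhibitors down-regulate
#' HDAC1), encoded as hard prior-knowledge constraints.
#'
#' @return Tibble with columns `condition`, `node`, `direction`.
#' @export
mcf7_prior <- function() {
  read_prior(system.file("extdata", "mcf7_prior.tsv", package = "ternet"))
}

#' @export
tidy.signaling_network <- function(x, ...) {
  x$edges
}

#' @export
glance.signaling_network <- function(x, ...) {
  network_stats(x)
}
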