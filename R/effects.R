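# Quantitative treatment-effect readouts.

#' Cell-function outcome vector from transcription-factor states
#'
#' Each cell-function readout is the signed sum of its upstream
#' transcription-factor states: factors that promote the function enter
#' with +1, factors that suppress it with -1.  For the packaged map the
#' four components are cell cycle regulation, DNA repair, cell survival
#' and cell growth.
#'
#' @param tf_states Named vector (or single-condition matrix column) of
#'   ternary states covering every factor named in the definitions.
#' @param definitions Output definitions, a data frame with columns
#'   `output`, `tf`, `coef` (see [output_definitions()]).
#' @return Named integer vector, one component per output.
#' @export
#' @examples
#' defs <- data.frame(output = "CELL_SURVIVAL", tf = c("NFKB", "BAD", "BCL2"),
#'                    coef = c(1, -1, 1))
#' compute_output_vector(c(NFKB = -1, BAD = 1, BCL2 = -1), defs)
compute_output_vector <- function(tf_states, definitions) {
  definitions <- tibble::as_tibble(definitions)
  missing <- setdiff(definitions$tf, names(tf_states))
  if (length(missing) > 0) {
    abort(paste0("missing state(s) for factor(s): ",
                 paste(missing, collapse = ", ")))
  }
  vapply(split(definitions, factor(definitions$output,
                                   levels = unique(definitions$output))),
         function(d) as.integer(sum(d$coef * tf_states[d$tf])),
         integer(1))
}

#' Similarity score between two outcome vectors
#'
#' The Pearson correlation coefficient of the two cell-function outcome
#' vectors, in \[-1, 1\].  A zero-variance vector has no defined
#' correlation and raises an error rather than returning a convention
#' value.
#'
#' @param t_a,t_c Numeric outcome vectors of equal length (>= 2).
#' @return A single correlation value.
#' @export
#' @examples
#' similarity_score(c(0, 0, -3, -1), c(0, 0, -2, -2))
similarity_score <- function(t_a, t_c) {
  if (length(t_a) != length(t_c) || length(t_a) < 2) {
    abort("outcome vectors must have equal length >= 2")
  }
  if (stats::var(t_a) == 0 || stats::var(t_c) == 0) {
    abort("similarity undefined for a zero-variance outcome vector")
  }
  stats::cor(t_a, t_c)
}

#' Topological similarity of a network to a reference
#'
#' The fraction of the reference network's edges (matched as signed
#' source/target pairs) present in the query network.
#'
#' @param network Query `signaling_network`.
#' @param reference Reference `signaling_network` (must have edges).
#' @return Fraction in \[0, 1\].
#' @export
topology_similarity <- function(network, reference) {
  ekey <- function(n) paste(n$edges$source, n$edges$target, n$edges$sign)
  ref <- ekey(reference)
  if (length(ref) == 0) abort("reference network has no edges")
  length(intersect(ekey(network), ref)) / length(ref)
}

#' Fitting precision of predicted states against observations
#'
#' The fraction of observed, non-missing (protein, condition) pairs
#' whose predicted ternary state equals the discretized observation.
#'
#' @param states Matrix of predicted states (nodes x conditions) or a
#'   named single-condition vector.
#' @param profile Observed ternary profile; its rows/columns select the
#'   pairs that are scored.
#' @return Fraction in \[0, 1\].
#' @export
fitting_precision <- function(states, profile) {
  profile <- as_ternary_profile(profile)
  if (is.null(dim(states))) {
    states <- matrix(states, ncol = 1,
                     dimnames = list(names(states), colnames(profile)[1]))
  }
  rows <- intersect(rownames(profile), rownames(states))
  cols <- intersect(colnames(profile), colnames(states))
  obs <- profile[rows, cols, drop = FALSE]
  prd <- states[rows, cols, drop = FALSE]
  keep <- !is.na(obs)
  if (!any(keep)) abort("no observed, non-missing pairs to score")
  mean(prd[keep] == obs[keep])
}
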