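# StateDistribution: probability mass over full Boolean network states,
# keyed by bit strings in model node order, plus a total-mass scalar used for
# population bookkeeping (relative population size carried by the mass).

#' Construct a state distribution
#'
#' A probability mass over network states.  States are encoded as bit strings
#' (`"0"`/`"1"` characters) aligned with `nodes`; the population
#' interpretation is `cells in state S = total cells x P(S)`, with
#' `total_mass` carrying the relative population size.
#'
#' @param p Named numeric vector: `names(p)` are bit-string states, values
#'   are nonnegative masses.
#' @param nodes Character vector of node names defining bit order.
#' @param total_mass Relative population size carried by the distribution.
#' @param normalize If `TRUE`, rescale `p` to sum to 1.
#' @return An object of class `bp_dist`.
#' @examples
#' d <- state_distribution(c("10" = 0.3, "01" = 0.7), nodes = c("A", "B"))
#' joint_probability(d, "A", 1)
#' @export
state_distribution <- function(p, nodes, total_mass = 1, normalize = FALSE) {
  if (length(p) == 0L) bp_validation_error("empty state distribution")
  if (is.null(names(p)) || any(!nzchar(names(p))))
    bp_validation_error("state distribution masses must be named by bit strings")
  if (any(p < 0)) bp_validation_error("negative mass in state distribution")
  if (any(nchar(names(p)) != length(nodes)))
    bp_validation_error("state keys must have one bit per node")
  if (any(grepl("[^01]", names(p))))
    bp_validation_error("state keys may contain only '0' and '1'")
  if (anyDuplicated(names(p))) {
    p <- tapply(p, names(p), sum)
    p <- stats::setNames(as.numeric(p), names(p))
  }
  if (normalize) {
    s <- sum(p)
    if (s <= 0) bp_validation_error("cannot normalize a zero-mass distribution")
    p <- p / s
  }
  structure(list(p = p, nodes = nodes, total_mass = total_mass),
            class = "bp_dist")
}

is_normalized <- function(dist, tol = 1e-9) abs(sum(dist$p) - 1) <= tol

# decode keys into an integer 0/1 matrix (states x nodes)
key_bits <- function(keys, n_nodes) {
  if (length(keys) == 0L) return(matrix(integer(), 0L, n_nodes))
  ch <- do.call(rbind, strsplit(keys, "", fixed = TRUE))
  matrix(as.integer(ch), nrow = length(keys), ncol = n_nodes)
}

bits_key <- function(bits) paste(bits, collapse = "")

#' Joint probability of a Boolean assignment
#'
#' Sums the mass of all states matching the assignment
#' `(nodes) = (values)`, marginalizing over the remaining nodes.  This is the
#' quantity the `p[(A,B) = (1,0)]` terms of population-update formulas
#' evaluate to.
#'
#' @param dist A [state_distribution()].
#' @param nodes Node names queried.
#' @param values 0/1 values, same length as `nodes`.
#' @return Numeric in `[0, total mass]`.
#' @export
joint_probability <- function(dist, nodes, values) {
  stopifnot(inherits(dist, "bp_dist"))
  if (length(nodes) != length(values) || length(nodes) < 1L)
    bp_validation_error("joint_probability needs matching non-empty node/value vectors")
  idx <- match(nodes, dist$nodes)
  if (anyNA(idx))
    bp_validation_error(sprintf("unknown node name(s): %s",
                                paste(nodes[is.na(idx)], collapse = ", ")))
  bm <- key_bits(names(dist$p), length(dist$nodes))
  sel <- rep(TRUE, nrow(bm))
  for (k in seq_along(idx)) sel <- sel & (bm[, idx[k]] == as.integer(values[k]))
  sum(dist$p[sel])
}

#' Marginal probability that a node is active
#'
#' @param dist A [state_distribution()].
#' @param node Node name.
#' @return `P(node = 1)` under `dist`.
#' @export
node_marginal <- function(dist, node) joint_probability(dist, node, 1L)

# force a node to a fixed value in every state (merging colliding states);
# used by perturbations and treatment-phase istate edits
force_node_state <- function(dist, node, value) {
  idx <- match(node, dist$nodes)
  if (is.na(idx)) bp_validation_error(sprintf("unknown node '%s'", node))
  keys <- names(dist$p)
  substr(keys, idx, idx) <- as.character(as.integer(value))
  state_distribution(stats::setNames(dist$p, keys), dist$nodes,
                     total_mass = dist$total_mass)
}

#' @export
print.bp_dist <- function(x, ...) {
  cat(sprintf("State distribution over %d node(s): %s\n",
              length(x$nodes), paste(x$nodes, collapse = " ")))
  cat(sprintf("  %d state(s), total probability %.6g, total mass %.6g\n",
              length(x$p), sum(x$p), x$total_mass))
  ord <- order(x$p, decreasing = TRUE)
  show <- utils::head(ord, 8L)
  for (i in show) cat(sprintf("  %s  %.6g\n", names(x$p)[i], x$p[[i]]))
  if (length(ord) > 8L) cat(sprintf("  ... %d more\n", length(ord) - 8L))
  invisible(x)
}
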