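# NetworkModel: ordered Boolean nodes, each carrying a logic rule and
# rate_up/rate_down transition-rate expressions, plus declared external
# variables ($name) with default values.

new_network_model <- function(nodes, variables = numeric(), forced = integer()) {
  m <- structure(list(nodes = nodes,
                      node_names = names(nodes),
                      variables = variables,
                      forced = forced),
                 class = "bp_model")
  validate_model(m)
  m
}

validate_model <- function(model) {
  nn <- model$node_names
  if (length(nn) == 0L) bp_validation_error("model has no nodes")
  if (anyDuplicated(nn))
    bp_validation_error(sprintf("duplicate node name(s): %s",
                                paste(unique(nn[duplicated(nn)]), collapse = ", ")))
  if (any(!nzchar(nn)) || any(grepl("^\\$", nn)))
    bp_validation_error("node names must be nonempty and must not start with '$'")
  for (nd in model$nodes) {
    for (slot in c("logic", "rate_up", "rate_down")) {
      if (is.null(nd[[slot]]))
        bp_validation_error(sprintf("node '%s' is missing its %s expression", nd$name, slot))
    }
  }
  invisible(model)
}

# Build a node entry, synthesizing the documented defaults:
#   rate_up   = @logic ? 1.0 : 0.0
#   rate_down = @logic ? 0.0 : 1.0
# and, when only rates are given, logic = the node itself.
make_node <- function(name, logic = NULL, rate_up = NULL, rate_down = NULL,
                      nodes, variables = NULL) {
  parse_slot <- function(text, dialect) {
    if (is.null(text)) return(NULL)
    if (inherits(text, "bp_expr") || is.list(text)) return(text)
    parse_expression(text, nodes = nodes, variables = variables, dialect = dialect)
  }
  logic <- parse_slot(logic, "logic")
  rate_up <- parse_slot(rate_up, "rate")
  rate_down <- parse_slot(rate_down, "rate")
  if (is.null(logic)) logic <- structure(list(type = "node", name = name),
                                         class = "bp_expr")
  default_rate <- function(on_true, on_false) {
    structure(list(type = "ifelse",
                   cond = list(type = "logic"),
                   yes = list(type = "num", value = on_true),
                   no = list(type = "num", value = on_false)),
              class = "bp_expr")
  }
  if (is.null(rate_up)) rate_up <- default_rate(1, 0)
  if (is.null(rate_down)) rate_down <- default_rate(0, 1)
  list(name = name, logic = logic, rate_up = rate_up, rate_down = rate_down)
}

# collect variable names referenced anywhere in an AST
expr_variables <- function(e) {
  out <- character()
  walk <- function(x) {
    if (!is.list(x)) return()
    if (!is.null(x$type) && x$type == "var") out <<- c(out, x$name)
    for (f in x) if (is.list(f)) walk(f)
  }
  walk(e)
  unique(out)
}

model_variables_used <- function(model) {
  unique(unlist(lapply(model$nodes, function(nd)
    c(expr_variables(nd$logic), expr_variables(nd$rate_up),
      expr_variables(nd$rate_down)))))
}

#' @export
print.bp_model <- function(x, ...) {
  cat(sprintf("Boolean network model: %d node(s)\n", length(x$nodes)))
  cat("  nodes:", paste(x$node_names, collapse = ", "), "\n")
  if (length(x$variables))
    cat("  external variables:",
        paste(sprintf("$%s=%g", names(x$variables), x$variables), collapse = ", "),
        "\n")
  if (length(x$forced))
    cat("  forced nodes:",
        paste(sprintf("%s=%d", names(x$forced), x$forced), collapse = ", "), "\n")
  invisible(x)
}

# SimulationConfig ------------------------------------------------------------

new_simulation_config <- function(variables = numeric(), istate = list(),
                                  max_time = 1, time_tick = 0.1,
                                  sample_count = 10000, seed = NULL) {
  if (!(max_time > 0)) bp_validation_error("max_time must be > 0")
  if (!(time_tick > 0 && time_tick <= max_time))
    bp_validation_error("time_tick must satisfy 0 < time_tick <= max_time")
  if (sample_count < 1) bp_validation_error("sample_count must be >= 1")
  structure(list(variables = variables, istate = istate,
                 max_time = max_time, time_tick = time_tick,
                 sample_count = as.integer(sample_count), seed = seed),
            class = "bp_config")
}

#' Default simulation configuration for a model
#'
#' All nodes start inactive with probability 1; `max_time = 1`,
#' `time_tick = 0.1`, `sample_count = 10000`.
#'
#' @param model A network model.
#' @param ... Overrides passed to the config constructor
#'   (`max_time`, `time_tick`, `sample_count`, `seed`, `variables`, `istate`).
#' @return A `bp_config`.
#' @export
default_config <- function(model, ...) {
  args <- list(...)
  defaults <- list(variables = numeric(), istate = list(),
                   max_time = 1, time_tick = 0.1, sample_count = 10000,
                   seed = NULL)
  defaults[names(args)] <- args
  do.call(new_simulation_config, defaults)
}

validate_istate <- function(istate, node_names, tol = 1e-9) {
  seen <- character()
  for (ent in istate) {
    if (anyNA(match(ent$nodes, node_names)))
      bp_validation_error(sprintf("istate references unknown node(s): %s",
                                  paste(setdiff(ent$nodes, node_names), collapse = ", ")))
    if (any(ent$nodes %in% seen))
      bp_validation_error(sprintf("node '%s' appears in more than one istate entry",
                                  intersect(ent$nodes, seen)[1]))
    seen <- c(seen, ent$nodes)
    if (any(ent$probs < 0))
      bp_validation_error("negative istate probability")
    if (abs(sum(ent$probs) - 1) > tol)
      bp_validation_error(sprintf(
        "istate probabilities for [%s] sum to %.10g, expected 1",
        paste(ent$nodes, collapse = ","), sum(ent$probs)))
    for (v in ent$values)
      if (length(v) != length(ent$nodes) || any(!(v %in% c(0L, 1L))))
        bp_validation_error("istate value tuples must be 0/1 and match the node tuple length")
  }
  invisible(istate)
}

#' Initial state distribution implied by a configuration
#'
#' Expands the (independent) istate entries of a configuration into a joint
#' distribution over full network states.  Nodes without an istate entry start
#' at 0 with probability 1.  Nodes forced by a perturbation override their
#' configured initial state.
#'
#' @param model A network model.
#' @param config A simulation configuration.
#' @return A [state_distribution()].
#' @export
initial_distribution <- function(model, config) {
  nn <- model$node_names
  validate_istate(config$istate, nn)
  keys <- bits_key(rep(0L, length(nn)))
  probs <- 1
  for (ent in config$istate) {
    idx <- match(ent$nodes, nn)
    nk <- character(); np <- numeric()
    for (j in seq_along(ent$values)) {
      if (ent$probs[j] == 0) next
      k2 <- keys
      for (q in seq_along(idx))
        substr(k2, idx[q], idx[q]) <- as.character(ent$values[[j]][q])
      nk <- c(nk, k2)
      np <- c(np, probs * ent$probs[j])
    }
    keys <- nk
    probs <- np
  }
  d <- state_distribution(stats::setNames(probs, keys), nn)
  for (nm in names(model$forced))
    d <- force_node_state(d, nm, model$forced[[nm]])
  d
}

# PopulationUpdateSpec ---------------------------------------------------------

new_population_spec <- function(death_node = NULL, division_node = NULL,
                                steps, updates = list(), model = NULL) {
  if (!(is.numeric(steps) && steps >= 1))
    bp_validation_error("steps must be a positive integer")
  if (!is.null(death_node) && !is.null(division_node) &&
      identical(death_node, division_node))
    bp_validation_error("death and division must be distinct nodes")
  if (!is.null(model)) {
    for (nm in c(death_node, division_node))
      if (!(nm %in% model$node_names))
        bp_validation_error(sprintf("unknown death/division node '%s'", nm))
  }
  structure(list(death_node = death_node, division_node = division_node,
                 steps = as.integer(steps), updates = updates),
            class = "bp_popspec")
}
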