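# Programmatic model builders.  Every builder returns a triple
# list(model, config, spec) that runs end-to-end through run_population and
# round-trips through the file writers/readers, so the whole package is
# testable without any external model files.

fixture_triple <- function(model, config, spec) {
  list(model = model, config = config, spec = spec)
}

#' Toy differentiation model with a paracrine switch
#'
#' Six nodes I, A, L, R, T1, T2 implementing a differentiation decision
#' between two irreversible, mutually exclusive cell types.  The trigger I
#' activates A; A drives both the T1 fate and the ligand L; L activates the
#' receptor R, which drives the T2 fate only while A is still inactive.  The
#' receptor rule is `R = $innerOn ? L : $outerL`: with `innerOn = 1` the
#' receptor sees only the cell's own ligand (independent cells -- T2 is then
#' unreachable, since R requires L requires A); with `innerOn = 0` its
#' activation rate is the external variable `$outerL`, refreshed after every
#' window as `5 * p[(L) = (1)]`, so receptors respond to the ligand level of
#' the whole population and a fraction of cells differentiates into T2.
#'
#' All rates are 1.0 except the receptor drive; T2 has no degradation rate
#' (irreversible fate); I starts active in every cell.  Defaults: 20 windows
#' of 1 h (enough to reach the plateau), 10000 trajectories.
#'
#' @param inner_on 0 (interacting population) or 1 (independent cells).
#' @return `list(model, config, spec)`.
#' @export
build_toy_model <- function(inner_on = 0) {
  nn <- c("I", "A", "L", "R", "T1", "T2")
  nodes <- list(
    I = make_node("I", logic = "I", nodes = nn),
    A = make_node("A", logic = "I", nodes = nn),
    L = make_node("L", logic = "A", nodes = nn),
    R = make_node("R", logic = "$innerOn ? L : $outerL",
                  rate_up = "@logic",
                  rate_down = "@logic ? 0.0 : 1.0", nodes = nn),
    T1 = make_node("T1", logic = "A & !T2", nodes = nn),
    T2 = make_node("T2", logic = "R & !A",
                   rate_up = "@logic ? 1.0 : 0.0",
                   rate_down = "0.0", nodes = nn)
  )
  model <- new_network_model(nodes,
                             variables = c(innerOn = inner_on, outerL = 0))
  config <- default_config(model,
                           istate = list(list(nodes = "I",
                                              values = list(1L),
                                              probs = 1)))
  upd <- parse_expression("5 * p[(L) = (1)]", nodes = nn,
                          variables = c("innerOn", "outerL"),
                          dialect = "update")
  spec <- new_population_spec(steps = 20,
                              updates = list(list(var = "outerL", expr = upd)),
                              model = model)
  fixture_triple(model, config, spec)
}

#' Single-node telegraph process
#'
#' One node with constant rates `u` (0 to 1) and `d` (1 to 0).  Starting from
#' 0, the closed form is `P(t) = u/(u+d) (1 - exp(-(u+d) t))` (pure-birth
#' `1 - exp(-u t)` when `d = 0`), giving tests an analytic oracle.
#'
#' @param u Activation rate (> 0 or 0).
#' @param d Deactivation rate.
#' @param max_time Window length (default 2 h).
#' @return `list(model, config, spec)`.
#' @export
build_telegraph <- function(u = 1, d = 1, max_time = 2) {
  nodes <- list(N = make_node("N", rate_up = format(u, digits = 15),
                              rate_down = format(d, digits = 15),
                              nodes = "N"))
  model <- new_network_model(nodes)
  config <- default_config(model, max_time = max_time)
  spec <- new_population_spec(steps = 10, model = model)
  fixture_triple(model, config, spec)
}

# closed-form occupancy of the telegraph node starting from 0
telegraph_prob <- function(u, d, t) {
  if (u + d == 0) return(rep(0, length(t)))
  u / (u + d) * (1 - exp(-(u + d) * t))
}

#' Incoherent feed-forward loop motif
#'
#' Four nodes: stimulus S (latched on), fast activator F (logic `S`, rate_up
#' 3), slow repressor P (logic `S`, rate_up 0.3) and readout X
#' (`F & !P`).  The readout probability rises quickly and is later shut off
#' by the repressor, so its trace has an interior extremum -- the transient
#' non-monotone response typical of incoherent feed-forward loops.  With
#' `repression = FALSE` the repressor edge is removed (`X = F`) and the trace
#' is monotone.
#'
#' @param repression Keep the repressing edge (default `TRUE`).
#' @return `list(model, config, spec)`.
#' @export
build_iffl <- function(repression = TRUE) {
  nn <- c("S", "F", "P", "X")
  nodes <- list(
    S = make_node("S", logic = "S", nodes = nn),
    F = make_node("F", logic = "S", rate_up = "@logic ? 3.0 : 0.0",
                  rate_down = "@logic ? 0.0 : 3.0", nodes = nn),
    P = make_node("P", logic = "S", rate_up = "@logic ? 0.3 : 0.0",
                  rate_down = "@logic ? 0.0 : 0.3", nodes = nn),
    X = make_node("X", logic = if (repression) "F & !P" else "F", nodes = nn)
  )
  model <- new_network_model(nodes)
  config <- default_config(model, max_time = 10, time_tick = 0.25,
                           istate = list(list(nodes = "S", values = list(1L),
                                              probs = 1)))
  spec <- new_population_spec(steps = 1, model = model)
  fixture_triple(model, config, spec)
}

#' Random small logic network
#'
#' Each node gets two regulators and a random two-input Boolean function;
#' rates are the defaults (1.0 for every permitted flip).  Initial states are
#' independent coin flips with random biases.  Deterministic given `seed`
#' (the builder saves and restores the caller's RNG state), so the same seed
#' always yields the same model -- the corpus for matrix-exponential
#' cross-checks.
#'
#' @param n Number of nodes (<= 8).
#' @param seed Integer seed.
#' @return `list(model, config, spec)`.
#' @export
build_random_network <- function(n, seed) {
  stopifnot(n >= 1, n <= 8)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  nn <- paste0("N", seq_len(n))
  templates <- c("%s & %s", "%s | %s", "%s & !%s", "%s | !%s", "%s ^ %s",
                 "!%s & %s", "!%s | !%s", "!%s")
  nodes <- list()
  for (i in seq_len(n)) {
    regs <- sample(nn, 2L, replace = n == 1L)
    tpl <- sample(templates, 1L)
    logic <- if (tpl == "!%s") sprintf(tpl, regs[1]) else sprintf(tpl, regs[1], regs[2])
    nodes[[nn[i]]] <- make_node(nn[i], logic = logic, nodes = nn)
  }
  model <- new_network_model(nodes)
  bias <- round(stats::runif(n), 3)
  istate <- lapply(seq_len(n), function(i)
    list(nodes = nn[i], values = list(0L, 1L), probs = c(1 - bias[i], bias[i])))
  config <- default_config(model, istate = istate, max_time = 2,
                           time_tick = 0.5)
  spec <- new_population_spec(steps = 5, model = model)
  fixture_triple(model, config, spec)
}

#' Small death/division motif
#'
#' A toggle X (constant rates 1 up / 1 down) wired to two phenotype nodes:
#' Death follows X, Division follows !X.  The population spec exercises both
#' update weights (death removes mass, division doubles it and resets the
#' flag in daughters).  Variants drop one of the two phenotypes:
#' `"death"` yields a non-increasing population, `"division"` a
#' non-decreasing one.
#'
#' @param variant `"both"`, `"death"` or `"division"`.
#' @return `list(model, config, spec)`.
#' @export
build_population_motif <- function(variant = c("both", "death", "division")) {
  variant <- match.arg(variant)
  nn <- c("X", "Death", "Division")
  nodes <- list(
    X = make_node("X", rate_up = "1.0", rate_down = "1.0", nodes = nn),
    Death = make_node("Death", logic = "X", nodes = nn),
    Division = make_node("Division", logic = "!X", nodes = nn)
  )
  model <- new_network_model(nodes)
  config <- default_config(model, max_time = 1, time_tick = 0.25,
                           sample_count = 5000)
  spec <- new_population_spec(
    death_node = if (variant != "division") "Death" else NULL,
    division_node = if (variant != "death") "Division" else NULL,
    steps = 5, model = model)
  fixture_triple(model, config, spec)
}
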