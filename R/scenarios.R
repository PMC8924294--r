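# Genetic perturbations and sequential/transient treatment schedules over the
# population loop, plus the single-mutant screen.

#' Apply a genetic perturbation to a model
#'
#' A knockdown forces the node permanently inactive (`rate_up := 0`, initial
#' state forced to 0); a knockin forces it permanently active
#' (`rate_down := 0`, initial state forced to 1).  Forcing the initial state
#' makes the mutant effective from t = 0 regardless of the configured
#' istate.  The input model is not modified.
#'
#' @param model A network model.
#' @param node Node name.
#' @param mode `"knockdown"` or `"knockin"`.
#' @return A new network model.
#' @export
apply_perturbation <- function(model, node, mode = c("knockdown", "knockin")) {
  mode <- match.arg(mode)
  if (!(node %in% model$node_names))
    bp_validation_error(sprintf("unknown node '%s'", node))
  m <- model
  if (mode == "knockdown") {
    m$nodes[[node]]$rate_up <- bp_num_expr(0)
    m$forced[node] <- 0L
  } else {
    m$nodes[[node]]$rate_down <- bp_num_expr(0)
    m$forced[node] <- 1L
  }
  m
}

#' Define one phase of a treatment schedule
#'
#' Phases span contiguous, non-overlapping step ranges covering the whole
#' run.  Edits are applied before the first window of the phase: `istate`
#' forces node values in the carried distribution (e.g. a ligand pulse sets
#' the ligand to 1 and lets its degradation rate clear it), `knockin` /
#' `knockdown` apply [apply_perturbation()] (a constitutive treatment is a
#' ligand knockin), `variables` overrides external variables and `rates`
#' overrides rate expressions.  Edits never alter the accumulated population
#' size -- treatments change dynamics, not census.
#'
#' @param from,to First and last step of the phase (1-based, inclusive).
#' @param label Phase label used in outputs.
#' @param istate Named 0/1 vector of node values forced at phase start.
#' @param knockin,knockdown Character vectors of node names.
#' @param variables Named numeric vector of variable overrides.
#' @param rates Named list `node -> list(rate_up=, rate_down=)` of expression
#'   strings.
#' @return A `bp_phase` list.
#' @export
schedule_phase <- function(from, to, label = sprintf("steps %d-%d", from, to),
                           istate = NULL, knockin = NULL, knockdown = NULL,
                           variables = NULL, rates = NULL) {
  if (!(from >= 1 && to >= from))
    bp_validation_error("phase span must satisfy 1 <= from <= to")
  structure(list(from = as.integer(from), to = as.integer(to), label = label,
                 istate = istate, knockin = knockin, knockdown = knockdown,
                 variables = variables, rates = rates),
            class = "bp_phase")
}

validate_schedule <- function(phases, steps) {
  if (!length(phases)) bp_validation_error("empty treatment schedule")
  froms <- vapply(phases, `[[`, 1L, "from")
  tos <- vapply(phases, `[[`, 1L, "to")
  if (froms[1] != 1L || tos[length(tos)] != steps ||
      (length(phases) > 1L && any(froms[-1] != tos[-length(tos)] + 1L)))
    bp_validation_error(sprintf(
      "phase spans must be contiguous, non-overlapping and cover steps 1..%d", steps))
  invisible(phases)
}

apply_phase_edits <- function(model, vars, phase) {
  for (nd in phase$knockdown) model <- apply_perturbation(model, nd, "knockdown")
  for (nd in phase$knockin) model <- apply_perturbation(model, nd, "knockin")
  if (!is.null(phase$rates)) {
    for (nm in names(phase$rates)) {
      if (!(nm %in% model$node_names))
        bp_validation_error(sprintf("rate override for unknown node '%s'", nm))
      ov <- phase$rates[[nm]]
      for (slot in intersect(names(ov), c("rate_up", "rate_down"))) {
        model$nodes[[nm]][[slot]] <- parse_expression(
          as.character(ov[[slot]]), nodes = model$node_names,
          variables = NULL, dialect = "rate")
      }
    }
  }
  if (!is.null(phase$variables)) vars[names(phase$variables)] <- phase$variables
  list(model = model, vars = vars)
}

#' Run the population loop under a treatment schedule
#'
#' Runs phase by phase, carrying the post-update distribution and cumulative
#' population size across phase boundaries; each phase's model/variable
#' edits are applied before its first window.
#'
#' @param model A network model.
#' @param config A `bp_config`.
#' @param spec A `bp_popspec` (its `steps` defines the schedule span).
#' @param schedule List of [schedule_phase()] objects.
#' @param seed Integer seed (default `config$seed`).
#' @return A `bp_poptraj` with a `phases` attribute recording each phase's
#'   label and span.
#' @export
run_schedule <- function(model, config, spec, schedule, seed = NULL) {
  validate_schedule(schedule, spec$steps)
  if (is.null(seed)) seed <- config$seed
  if (!is.null(seed)) set.seed(seed)
  vars <- merge_variables(model, config)
  wmodel <- model
  ph1 <- apply_phase_edits(wmodel, vars, schedule[[1]])
  dist0 <- initial_distribution(ph1$model, config)
  for (nm in names(schedule[[1]]$istate))
    dist0 <- force_node_state(dist0, nm, schedule[[1]]$istate[[nm]])
  dist <- dist0
  acc <- NULL
  N <- 1
  for (pi in seq_along(schedule)) {
    phase <- schedule[[pi]]
    ed <- apply_phase_edits(model, vars, phase)
    pm <- ed$model
    vars <- ed$vars
    if (pi > 1L) {
      for (nm in names(phase$istate))
        dist <- force_node_state(dist, nm, phase$istate[[nm]])
      for (nm in names(pm$forced))
        dist <- force_node_state(dist, nm, pm$forced[[nm]])
    }
    res <- population_loop(pm, config, spec, dist, vars,
                           steps = phase$to - phase$from + 1L,
                           start_step = phase$from - 1L, start_size = N)
    acc <- if (is.null(acc)) res else merge_loop_results(acc, res)
    if (res$truncated) {
      # pad any later phases with extinct rows so outputs keep steps+1 rows
      last <- max(acc$population$step)
      if (last < spec$steps) {
        acc$population <- rbind(acc$population,
                                data.frame(step = (last + 1L):spec$steps,
                                           ratio = 0, size = 0))
      }
      break
    }
    dist <- res$final_dist
    vars <- res$final_vars
    N <- res$final_size
  }
  out <- finish_poptraj(acc, model, config, spec, seed, initial_dist = dist0)
  attr(out, "phases") <- lapply(schedule, function(p)
    list(label = p$label, from = p$from, to = p$to))
  out
}

merge_loop_results <- function(a, b) {
  list(population = rbind(a$population, b$population),
       node_probs = rbind(a$node_probs, b$node_probs),
       pre_dists = c(a$pre_dists, b$pre_dists),
       post_dists = c(a$post_dists, b$post_dists),
       variables = c(a$variables, b$variables),
       ensembles = c(a$ensembles, b$ensembles),
       final_dist = b$final_dist, final_vars = b$final_vars,
       final_size = b$final_size,
       truncated = b$truncated)
}

#' Single-mutant screen over treatment schedules
#'
#' Runs the wild type and every single perturbation of the listed nodes
#' under each schedule and reports the final relative population size.  Rows
#' are ordered wild type first, then node order within mode; every run uses
#' the same seed so mutants are compared on a common stream and the table is
#' reproducible.
#'
#' @param model A network model.
#' @param config A `bp_config`.
#' @param spec A `bp_popspec`.
#' @param schedules Named list of schedules (lists of [schedule_phase()]);
#'   `NULL` runs the plain population loop as a single `"default"` schedule.
#' @param nodes Nodes to perturb (default all).
#' @param modes Perturbation modes to sweep (default knockdown only).
#' @param seed Integer seed shared by all runs.
#' @param normalize_at_step If set, divide each run's final size by its size
#'   at this step (e.g. the boundary between two treatment phases), so the
#'   table reads as growth after that point.  Off by default.
#' @return A data.frame `mutant`, `mode`, `schedule`, `final_size`.
#' @export
mutant_sweep <- function(model, config, spec, schedules = NULL,
                         nodes = model$node_names,
                         modes = "knockdown", seed = NULL,
                         normalize_at_step = NULL) {
  if (is.null(schedules))
    schedules <- list(default = list(schedule_phase(1L, spec$steps)))
  if (is.null(names(schedules)))
    names(schedules) <- paste0("schedule", seq_along(schedules))
  runs <- data.frame(mutant = "WT", mode = "none", stringsAsFactors = FALSE)
  if (length(nodes)) {
    for (md in modes)
      runs <- rbind(runs, data.frame(mutant = nodes, mode = md,
                                     stringsAsFactors = FALSE))
  }
  out <- NULL
  for (i in seq_len(nrow(runs))) {
    m <- if (runs$mode[i] == "none") model else
      apply_perturbation(model, runs$mutant[i], runs$mode[i])
    for (sn in names(schedules)) {
      traj <- run_schedule(m, config, spec, schedules[[sn]], seed = seed)
      pop <- traj$population
      fs <- pop$size[nrow(pop)]
      if (!is.null(normalize_at_step)) {
        base <- pop$size[pop$step == normalize_at_step]
        if (!length(base))
          bp_validation_error(sprintf("no step %d in run to normalize by",
                                      normalize_at_step))
        fs <- if (base > 0) fs / base else NA_real_
      }
      out <- rbind(out, data.frame(mutant = runs$mutant[i], mode = runs$mode[i],
                                   schedule = sn, final_size = fs,
                                   stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}
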