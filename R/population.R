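# The population loop: alternate continuous-time simulation windows with
# synchronous population updates.
#
# At each update, every state S of the end-of-window distribution gets a
# weight w(S): 0 if the death node is active (death takes precedence), 2 if
# the division node is active (two identical daughters, division flag reset
# to 0), 1 otherwise.  The step ratio is sum q(S) w(S) -- equivalently
# 1 - P(death) + P(division & !death) -- and the relative population size is
# the running product of ratios, N_0 = 1.  The reweighted distribution is
# renormalized and becomes the next window's initial condition; update
# formulas are then evaluated on this post-update distribution so that
# ligands from removed (dead) cells do not signal into the next window.

#' Synchronous population update of an end-of-window distribution
#'
#' @param end_dist Normalized [state_distribution()] at the end of a
#'   simulation window.
#' @param spec A `bp_popspec` naming the death/division nodes (either may be
#'   absent).
#' @param model The network model (defines node order).
#' @return A list: `dist` (post-update normalized distribution, `NULL` when
#'   extinct), `ratio` (step population ratio >= 0), `extinct` (logical).
#' @export
apply_population_update <- function(end_dist, spec, model) {
  if (!is_normalized(end_dist, tol = 1e-6))
    bp_validation_error("end-of-window distribution is not normalized")
  keys <- names(end_dist$p)
  q <- end_dist$p
  nn <- end_dist$nodes
  bm <- key_bits(keys, length(nn))
  death_on <- rep(FALSE, length(keys))
  div_on <- rep(FALSE, length(keys))
  if (!is.null(spec$death_node))
    death_on <- bm[, match(spec$death_node, nn)] == 1L
  if (!is.null(spec$division_node))
    div_on <- bm[, match(spec$division_node, nn)] == 1L
  w <- rep(1, length(keys))
  w[div_on] <- 2
  w[death_on] <- 0           # a dying cell cannot divide
  ratio <- sum(q * w)
  if (ratio < 1e-12)
    return(list(dist = NULL, ratio = 0, extinct = TRUE))
  mass <- q * w
  keep <- mass > 0
  new_keys <- keys[keep]
  if (!is.null(spec$division_node)) {
    j <- match(spec$division_node, nn)
    substr(new_keys, j, j) <- "0"   # daughters do not inherit the division flag
  }
  agg <- rowsum(mass[keep], new_keys)
  newp <- stats::setNames(agg[, 1L] / ratio, rownames(agg))
  list(dist = state_distribution(newp, nn,
                                 total_mass = end_dist$total_mass * ratio),
       ratio = ratio, extinct = FALSE)
}

#' Refresh external variables from population state probabilities
#'
#' Evaluates the update formulas of a population spec in order against the
#' post-update distribution; later formulas see the assignments made by
#' earlier ones.
#'
#' @param spec A `bp_popspec`.
#' @param dist The post-update normalized [state_distribution()].
#' @param variables Named list/vector of current variable values.
#' @return The updated variables as a named list.
#' @export
refresh_variables <- function(spec, dist, variables) {
  vars <- as.list(variables)
  for (u in spec$updates) {
    vars[[u$var]] <- eval_expression(u$expr, state = NULL, variables = vars,
                                     dist = dist)
  }
  vars
}

# shared stepped loop; `start_step`/`start_size` let treatment schedules
# splice phases together
population_loop <- function(model, config, spec, dist, vars, steps,
                            start_step = 0L, start_size = 1) {
  step_no <- integer(); ratio <- numeric(); size <- numeric()
  np_step <- integer(); np_time <- numeric(); np_node <- character()
  np_prob <- numeric()
  pre_dists <- list(); post_dists <- list(); var_log <- list()
  ensembles <- list()
  N <- start_size
  truncated <- FALSE
  for (k in seq_len(steps)) {
    ens <- run_ensemble(model, config, initial = dist, variables = vars,
                        seed = NULL)
    gk <- start_step + k
    tt <- (gk - 1L) * config$max_time + ens$time
    nw <- length(tt)
    for (nm in colnames(ens$node_probs)) {
      np_step <- c(np_step, rep(gk, nw))
      np_time <- c(np_time, tt)
      np_node <- c(np_node, rep(nm, nw))
      np_prob <- c(np_prob, ens$node_probs[, nm])
    }
    upd <- apply_population_update(ens$end_dist, spec, model)
    N <- N * upd$ratio
    step_no <- c(step_no, gk)
    ratio <- c(ratio, upd$ratio)
    size <- c(size, N)
    pre_dists[[k]] <- ens$end_dist
    ensembles[[k]] <- ens
    if (upd$extinct) {
      truncated <- TRUE
      post_dists[k] <- list(NULL)
      var_log[[k]] <- as.list(vars)
      # population is extinct: later steps record N = 0
      rem <- seq_len(steps - k)
      step_no <- c(step_no, start_step + k + rem)
      ratio <- c(ratio, rep(0, length(rem)))
      size <- c(size, rep(0, length(rem)))
      break
    }
    vars <- refresh_variables(spec, upd$dist, vars)
    dist <- upd$dist
    post_dists[[k]] <- dist
    var_log[[k]] <- as.list(vars)
  }
  list(population = data.frame(step = step_no, ratio = ratio, size = size),
       node_probs = data.frame(step = np_step, time = np_time, node = np_node,
                               probability = np_prob, stringsAsFactors = FALSE),
       pre_dists = pre_dists, post_dists = post_dists,
       variables = var_log, ensembles = ensembles,
       final_dist = dist, final_vars = vars, final_size = N,
       truncated = truncated)
}

#' Run the full population loop
#'
#' Alternates `spec$steps` simulation windows of length `config$max_time`
#' with synchronous population updates (death, division, update formulas),
#' so the total simulated time is `steps x max_time`.  Step 0 reports the
#' baseline relative population size 1.
#'
#' @param model A network model.
#' @param config A `bp_config`.
#' @param spec A `bp_popspec`.
#' @param seed Integer seed for the whole run (default `config$seed`).  All
#'   windows draw from this single stream, so a run is reproducible
#'   end-to-end.
#' @param steps Override for `spec$steps`.
#' @return A `bp_poptraj`: `population` (data.frame `step`, `ratio`, `size`,
#'   including the step-0 baseline), `node_probs` (long data.frame on the
#'   global time grid), per-step pre/post-update distributions, per-step
#'   variable values, per-step ensembles, and a `truncated` flag set when
#'   the population went extinct.
#' @examples
#' fx <- build_telegraph(1, 1)
#' traj <- run_population(fx$model, fx$config, fx$spec, seed = 1)
#' traj$population
#' @export
run_population <- function(model, config, spec, seed = NULL, steps = NULL) {
  if (is.null(seed)) seed <- config$seed
  if (!is.null(seed)) set.seed(seed)
  if (is.null(steps)) steps <- spec$steps
  vars <- merge_variables(model, config)
  dist <- initial_distribution(model, config)
  res <- population_loop(model, config, spec, dist, vars, steps)
  finish_poptraj(res, model, config, spec, seed)
}

finish_poptraj <- function(res, model, config, spec, seed,
                           initial_dist = NULL) {
  if (is.null(initial_dist)) initial_dist <- initial_distribution(model, config)
  res$population <- rbind(data.frame(step = 0L, ratio = 1, size = 1),
                          res$population)
  res$initial_dist <- initial_dist
  res$nodes <- model$node_names
  res$seed <- seed
  res$max_time <- config$max_time
  res$time_tick <- config$time_tick
  res$sample_count <- config$sample_count
  res$death_node <- spec$death_node
  res$division_node <- spec$division_node
  class(res) <- "bp_poptraj"
  res
}

#' Final node marginals of a population run
#'
#' Convenience accessor: `P(node = 1)` under the distribution carried into
#' the step after the last one simulated.
#'
#' @param traj A `bp_poptraj`.
#' @return Named numeric vector over model nodes.
#' @export
final_marginals <- function(traj) {
  d <- traj$final_dist
  if (is.null(d)) return(stats::setNames(rep(NA_real_, length(traj$nodes)), traj$nodes))
  stats::setNames(vapply(traj$nodes, function(nm) joint_probability(d, nm, 1L), 0),
                  traj$nodes)
}

#' @export
print.bp_poptraj <- function(x, ...) {
  K <- nrow(x$population) - 1L
  cat(sprintf("Population trajectory: %d step(s) x max_time %g (%d trajectories/window)\n",
              K, x$max_time, x$sample_count))
  cat(sprintf("  final relative population size: %.6g%s\n",
              x$population$size[nrow(x$population)],
              if (isTRUE(x$truncated)) " (extinct, truncated)" else ""))
  fm <- final_marginals(x)
  if (!anyNA(fm)) {
    cat("  final node marginals:\n")
    for (nm in names(fm)) cat(sprintf("    %-12s %.4f\n", nm, fm[[nm]]))
  }
  invisible(x)
}
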