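# Continuous-time Markov simulation on Boolean states.
#
# Dynamics: in state S, each node with value 0 whose rate_up evaluates > 0
# may flip up at that rate; each node with value 1 whose rate_down evaluates
# > 0 may flip down.  The total rate rho is the sum of enabled rates; the
# waiting time is Exponential(rho) and the flip is chosen with probability
# rate/rho (exact-jump stochastic simulation).  rho = 0 marks an absorbing
# state.
#
# The ensemble engine advances all trajectories in lock-step with vectorised
# draws, memoising the per-state transition table lazily (external variables
# are constant within a run, so rates depend on the state only).  Reported
# probabilities are occupancy-weighted window averages on the time_tick grid;
# the end-of-run distribution is the point sample at exactly t = max_time,
# which is what the next population step starts from.

#' Enabled transitions of a state
#'
#' Lists every permitted single-node flip out of `state` with its rate: nodes
#' at 0 whose `rate_up` evaluates positive, and nodes at 1 whose `rate_down`
#' evaluates positive.  Rates must evaluate nonnegative.
#'
#' @param model A network model.
#' @param state Named 0/1 vector over all model nodes (or unnamed in node
#'   order).
#' @param variables Named external-variable values (merged over the model
#'   defaults).
#' @return A data.frame with columns `node`, `direction` (`"up"`/`"down"`),
#'   `rate`.
#' @export
enabled_transitions <- function(model, state, variables = NULL) {
  vars <- merge_variables(model, NULL, variables)
  if (is.null(names(state))) names(state) <- model$node_names
  state <- state[model$node_names]
  node <- character(); direction <- character(); rate <- numeric()
  for (nd in model$nodes) {
    v <- as.numeric(state[[nd$name]])
    slot <- if (v == 0) "rate_up" else "rate_down"
    r <- eval_expression(nd[[slot]], state = state, variables = vars,
                         logic = nd$logic)
    if (r < 0)
      bp_eval_error(sprintf("negative rate: %s of node '%s' evaluates to %g",
                            slot, nd$name, r))
    if (r > 0) {
      node <- c(node, nd$name)
      direction <- c(direction, if (v == 0) "up" else "down")
      rate <- c(rate, r)
    }
  }
  data.frame(node = node, direction = direction, rate = rate,
             stringsAsFactors = FALSE)
}

merge_variables <- function(model, config = NULL, variables = NULL) {
  vars <- as.list(model$variables)
  if (!is.null(config)) vars[names(config$variables)] <- config$variables
  if (!is.null(variables)) vars[names(variables)] <- variables
  vars
}

#' Simulate one stochastic trajectory
#'
#' Exact-jump simulation of a single cell: exponential waiting times drawn
#' from the total enabled rate, one node flipped per jump, absorbing states
#' persisting to `max_time`.
#'
#' @param model A network model.
#' @param initial Named 0/1 vector (or unnamed in node order).
#' @param variables Named external-variable values.
#' @param max_time Run length (hours).
#' @return A data.frame of path segments: `time` (entry time) and `state`
#'   (bit string); the first row is `time = 0`.
#' @export
simulate_trajectory <- function(model, initial, variables = NULL, max_time = 1) {
  if (!(max_time > 0)) bp_validation_error("max_time must be > 0")
  if (is.null(names(initial))) names(initial) <- model$node_names
  state <- as.numeric(initial[model$node_names])
  names(state) <- model$node_names
  times <- 0
  keys <- bits_key(as.integer(state))
  t <- 0
  repeat {
    tr <- enabled_transitions(model, state, variables)
    rho <- sum(tr$rate)
    if (rho == 0) break
    t <- t + stats::rexp(1L, rho)
    if (t >= max_time) break
    pick <- sample.int(nrow(tr), 1L, prob = tr$rate)
    nm <- tr$node[pick]
    state[[nm]] <- 1 - state[[nm]]
    times <- c(times, t)
    keys <- c(keys, bits_key(as.integer(state)))
  }
  data.frame(time = times, state = keys, stringsAsFactors = FALSE)
}

# --- lazily memoised per-state transition table ------------------------------

new_state_table <- function(model, variables) {
  tbl <- new.env(parent = emptyenv())
  n <- length(model$node_names)
  tbl$model <- model
  tbl$vars <- variables
  tbl$n_nodes <- n
  tbl$index <- new.env(parent = emptyenv(), hash = TRUE)
  cap <- 64L
  tbl$keys <- character(cap)
  tbl$bits <- matrix(NA_integer_, cap, n)
  tbl$computed <- logical(cap)
  tbl$tot <- numeric(cap)
  tbl$cum <- matrix(1, cap, n)     # cumulative flip probabilities, padded 1
  tbl$tgt <- matrix(NA_integer_, cap, n)
  tbl$size <- 0L
  tbl
}

st_grow <- function(tbl) {
  cap <- length(tbl$keys)
  newcap <- cap * 2L
  tbl$keys <- c(tbl$keys, character(cap))
  tbl$computed <- c(tbl$computed, logical(cap))
  tbl$tot <- c(tbl$tot, numeric(cap))
  tbl$bits <- rbind(tbl$bits, matrix(NA_integer_, cap, tbl$n_nodes))
  tbl$cum <- rbind(tbl$cum, matrix(1, cap, tbl$n_nodes))
  tbl$tgt <- rbind(tbl$tgt, matrix(NA_integer_, cap, tbl$n_nodes))
  invisible(newcap)
}

st_id <- function(tbl, key) {
  id <- tbl$index[[key]]
  if (!is.null(id)) return(id)
  if (tbl$size == length(tbl$keys)) st_grow(tbl)
  id <- tbl$size + 1L
  tbl$size <- id
  tbl$keys[id] <- key
  tbl$bits[id, ] <- key_bits(key, tbl$n_nodes)[1L, ]
  tbl$index[[key]] <- id
  id
}

st_compute <- function(tbl, ids) {
  model <- tbl$model
  for (id in ids) {
    if (tbl$computed[id]) next
    bits <- tbl$bits[id, ]
    state <- stats::setNames(as.numeric(bits), model$node_names)
    rates <- numeric(); tgts <- integer()
    for (j in seq_along(model$nodes)) {
      nd <- model$nodes[[j]]
      slot <- if (bits[j] == 0L) nd$rate_up else nd$rate_down
      r <- eval_expression(slot, state = state, variables = tbl$vars,
                           logic = nd$logic)
      if (r < 0)
        bp_eval_error(sprintf("negative rate for node '%s' in state %s: %g",
                              nd$name, tbl$keys[id], r))
      if (r > 0) {
        fb <- bits
        fb[j] <- 1L - fb[j]
        rates <- c(rates, r)
        tgts <- c(tgts, st_id(tbl, bits_key(fb)))
      }
    }
    tot <- sum(rates)
    tbl$tot[id] <- tot
    if (tot > 0) {
      k <- length(rates)
      tbl$cum[id, seq_len(k)] <- cumsum(rates) / tot
      if (k < tbl$n_nodes) tbl$cum[id, (k + 1L):tbl$n_nodes] <- 1
      tbl$tgt[id, seq_len(k)] <- tgts
    }
    tbl$computed[id] <- TRUE
  }
  invisible(tbl)
}

# Residual (stratified) draw of initial states: each state gets
# floor(n * p) trajectories outright and the fractional remainders are
# sampled multinomially.  Unbiased, but avoids the compounding resampling
# noise a plain multinomial draw would inject at every population step
# (the population loop is a sequential Monte Carlo scheme; residual
# resampling is the standard way to keep its variance in check).  The
# result is shuffled so trajectory index carries no information.
draw_initial_ids <- function(ids, probs, n) {
  if (length(ids) == 1L) return(rep(ids, n))
  base <- floor(n * probs)
  rem <- n - sum(base)
  id <- rep(ids, base)
  if (rem > 0) {
    resid <- n * probs - base
    id <- c(id, sample(ids, rem, replace = TRUE, prob = resid))
  }
  sample(id)
}

# --- ensemble ----------------------------------------------------------------

#' Run an ensemble of stochastic trajectories
#'
#' Simulates `config$sample_count` trajectories from initial states drawn
#' from `initial`, reporting occupancy-weighted state and node probabilities
#' on the `time_tick` grid and the empirical state distribution at exactly
#' `t = max_time`.
#'
#' @param model A network model.
#' @param config A `bp_config` (see [default_config()]); supplies
#'   `max_time`, `time_tick`, `sample_count` and (unless `seed` is given)
#'   the RNG seed.
#' @param initial A [state_distribution()], or `NULL` to use
#'   [initial_distribution()] of the config.
#' @param variables Named external-variable overrides for this run.
#' @param seed Integer seed; `NULL` uses `config$seed` if set, otherwise the
#'   current RNG stream (so the population loop can draw consecutive windows
#'   from one seeded stream).
#' @return A `bp_ensemble`: `time` (window start times), `node_probs`
#'   (windows x nodes), `state_probs` (windows x visited states),
#'   `end_dist`.
#' @export
run_ensemble <- function(model, config, initial = NULL, variables = NULL,
                         seed = NULL) {
  if (is.null(seed)) seed <- config$seed
  if (!is.null(seed)) set.seed(seed)
  vars <- merge_variables(model, config, variables)
  if (is.null(initial)) initial <- initial_distribution(model, config)
  if (length(initial$p) == 0L || sum(initial$p) <= 0)
    bp_validation_error("empty initial distribution")
  if (!is_normalized(initial))
    bp_validation_error("initial distribution is not normalized")

  n_samp <- config$sample_count
  max_time <- config$max_time
  breaks <- seq(0, max_time, by = config$time_tick)
  if (breaks[length(breaks)] < max_time) breaks <- c(breaks, max_time)
  W <- length(breaks) - 1L
  widths <- diff(breaks)

  tbl <- new_state_table(model, vars)
  init_ids <- vapply(names(initial$p), function(k) st_id(tbl, k), 1L)
  id <- draw_initial_ids(init_ids, initial$p, n_samp)

  occ <- matrix(0, W, 256L)
  occ_grow <- function(need) {
    if (need > ncol(occ)) {
      add <- matrix(0, W, max(need - ncol(occ), ncol(occ)))
      occ <<- cbind(occ, add)
    }
  }
  record <- function(idx, t0, t1) {
    occ_grow(tbl$size)
    for (w in seq_len(W)) {
      ov <- pmin(t1, breaks[w + 1L]) - pmax(t0, breaks[w])
      pos <- ov > 0
      if (any(pos)) {
        agg <- rowsum(ov[pos], id[idx[pos]])
        rows <- as.integer(rownames(agg))
        occ[w, rows] <<- occ[w, rows] + agg[, 1L]
      }
    }
  }

  t <- numeric(n_samp)
  done <- logical(n_samp)
  while (!all(done)) {
    act <- which(!done)
    uids <- unique(id[act])
    st_compute(tbl, uids[!tbl$computed[uids]])
    tot_a <- tbl$tot[id[act]]

    absorbing <- act[tot_a == 0]
    if (length(absorbing)) {
      record(absorbing, t[absorbing], rep(max_time, length(absorbing)))
      t[absorbing] <- max_time
      done[absorbing] <- TRUE
    }
    mv <- act[tot_a > 0]
    if (length(mv)) {
      dt <- stats::rexp(length(mv), rate = tot_a[tot_a > 0])
      tn <- t[mv] + dt
      t1 <- pmin(tn, max_time)
      record(mv, t[mv], t1)
      cross <- tn >= max_time
      fin <- mv[cross]
      if (length(fin)) {
        t[fin] <- max_time
        done[fin] <- TRUE
      }
      jmp <- mv[!cross]
      if (length(jmp)) {
        u <- stats::runif(length(jmp))
        rows <- id[jmp]
        j <- rowSums(u > tbl$cum[rows, , drop = FALSE]) + 1L
        id[jmp] <- tbl$tgt[cbind(rows, j)]
        t[jmp] <- tn[!cross]
      }
    }
  }

  used <- seq_len(tbl$size)
  keys <- tbl$keys[used]
  # each trajectory tiles every window, so row totals equal n_samp * width
  # exactly up to rounding; normalizing by the realized totals keeps each
  # window distribution summing to 1 without float residue
  state_probs <- occ[, used, drop = FALSE] / rowSums(occ)
  colnames(state_probs) <- keys
  bits <- tbl$bits[used, , drop = FALSE]
  node_probs <- state_probs %*% bits
  colnames(node_probs) <- model$node_names

  cnt <- tabulate(id, nbins = tbl$size)
  keep <- cnt > 0
  end_dist <- state_distribution(stats::setNames(cnt[keep] / n_samp, keys[keep]),
                                 model$node_names,
                                 total_mass = initial$total_mass)

  structure(list(time = breaks[-length(breaks)],
                 node_probs = node_probs,
                 state_probs = state_probs,
                 end_dist = end_dist,
                 sample_count = n_samp,
                 max_time = max_time,
                 time_tick = config$time_tick,
                 seed = seed),
            class = "bp_ensemble")
}

#' Transition-rate matrix of a model
#'
#' Builds the generator matrix Q of the continuous-time Markov chain over all
#' `2^n` states from [enabled_transitions()]: `Q[to, from]` is the rate of
#' the single flip `from -> to`, with diagonal entries closing each column to
#' zero.  Intended for small models, e.g. as input to a matrix-exponential
#' cross-check of ensemble estimates.
#'
#' @param model A network model (n <= 12 nodes).
#' @param variables Named external-variable values.
#' @return A dense `2^n x 2^n` matrix with dimnames the state bit strings.
#' @export
rate_matrix <- function(model, variables = NULL) {
  n <- length(model$node_names)
  if (n > 12L) bp_validation_error("rate_matrix is limited to 12 nodes (4096 states)")
  S <- 2L^n
  keys <- vapply(0:(S - 1L), function(s)
    bits_key(as.integer(intToBits(s)[1:n])), "")
  Q <- matrix(0, S, S, dimnames = list(keys, keys))
  for (s in seq_len(S)) {
    bits <- key_bits(keys[s], n)[1L, ]
    tr <- enabled_transitions(model, stats::setNames(bits, model$node_names),
                              variables)
    if (!nrow(tr)) next
    for (r in seq_len(nrow(tr))) {
      fb <- bits
      jj <- match(tr$node[r], model$node_names)
      fb[jj] <- 1L - fb[jj]
      Q[bits_key(fb), s] <- Q[bits_key(fb), s] + tr$rate[r]
    }
    Q[s, s] <- -sum(tr$rate)
  }
  Q
}

#' @export
print.bp_ensemble <- function(x, ...) {
  cat(sprintf("Ensemble of %d trajectories over [0, %g] (tick %g)\n",
              x$sample_count, x$max_time, x$time_tick))
  cat(sprintf("  %d reporting window(s), %d state(s) visited\n",
              length(x$time), ncol(x$state_probs)))
  cat("  final node marginals:\n")
  em <- vapply(colnames(x$node_probs), function(nm)
    joint_probability(x$end_dist, nm, 1L), 0)
  for (nm in names(em)) cat(sprintf("    %-12s %.4f\n", nm, em[[nm]]))
  invisible(x)
}
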