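# Readers and writers for the three plain-text model files:
#   .bnd  network definition  -- node blocks with logic / rate_up / rate_down
#   .cfg  configuration       -- $variables, istate lines, run parameters
#   .upp  population update   -- death/division nodes, step count, u= formulas
# plus the two-column bnet interchange format.
#
# Dialect conventions (normative for this package, documented in README):
# statements are semicolon-terminated, '//' starts a comment, update lines
# read `$name u= <expr>;`, and both "[A].istate" and "[A]. istate" spellings
# are accepted (the writer emits the former).

read_model_text <- function(path) {
  if (!file.exists(path))
    bp_error(sprintf("file not found: %s", path), "bp_input_error")
  txt <- readLines(path, warn = FALSE, encoding = "UTF-8")
  # strip // comments (the grammar has no string literals)
  sub("//.*$", "", txt)
}

#' Read a network-definition (bnd) file
#'
#' Parses node blocks of the form
#' `node A { logic = ...; rate_up = ...; rate_down = ...; }`.
#' Missing rate expressions default to `@logic ? 1.0 : 0.0` (up) and
#' `@logic ? 0.0 : 1.0` (down); a missing logic rule defaults to the node
#' itself.  External variables (`$name`) are declared implicitly by use, with
#' default value 0 (typically overridden by the cfg file).
#'
#' @param path Path to a bnd-dialect text file.
#' @return A network model (class `bp_model`).
#' @export
read_network <- function(path) {
  txt <- paste(read_model_text(path), collapse = "\n")
  # first pass: node names (needed to resolve references in any order)
  m <- gregexpr("node\\s+([A-Za-z_][A-Za-z0-9_]*)\\s*\\{", txt, perl = TRUE)
  starts <- m[[1]]
  if (starts[1] == -1L) bp_parse_error(sprintf("no node blocks found in '%s'", path))
  headers <- regmatches(txt, m)[[1]]
  node_names <- sub("^node\\s+", "", sub("\\s*\\{$", "", headers))
  if (anyDuplicated(node_names))
    bp_parse_error(sprintf("duplicate node definition(s): %s",
                           paste(unique(node_names[duplicated(node_names)]), collapse = ", ")))
  nodes <- list()
  for (i in seq_along(starts)) {
    open <- starts[i] + attr(m[[1]], "match.length")[i] - 1L
    close <- open
    depth <- 1L
    while (depth > 0L) {
      close <- close + 1L
      if (close > nchar(txt))
        bp_parse_error(sprintf("unterminated block for node '%s'", node_names[i]))
      ch <- substr(txt, close, close)
      if (ch == "{") depth <- depth + 1L
      if (ch == "}") depth <- depth - 1L
    }
    body <- substr(txt, open + 1L, close - 1L)
    stmts <- trimws(strsplit(body, ";", fixed = TRUE)[[1]])
    stmts <- stmts[nzchar(stmts)]
    slots <- list()
    for (s in stmts) {
      kv <- regmatches(s, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*(.+)$", s))[[1]]
      if (length(kv) != 3L)
        bp_parse_error(sprintf("cannot parse statement '%s' in node '%s' (%s)",
                               s, node_names[i], line_of(path, s)))
      key <- kv[2]
      if (!(key %in% c("logic", "rate_up", "rate_down")))
        bp_parse_error(sprintf("unknown attribute '%s' in node '%s'", key, node_names[i]))
      slots[[key]] <- kv[3]
    }
    nd <- tryCatch(
      make_node(node_names[i], logic = slots$logic, rate_up = slots$rate_up,
                rate_down = slots$rate_down, nodes = node_names, variables = NULL),
      bp_parse_error = function(c) {
        bp_parse_error(sprintf("in node '%s' of '%s': %s",
                               node_names[i], basename(path), conditionMessage(c)))
      })
    nodes[[node_names[i]]] <- nd
  }
  model <- new_network_model(nodes)
  vars <- model_variables_used(model)
  model$variables <- stats::setNames(rep(0, length(vars)), vars)
  model
}

# best-effort line number for error messages
line_of <- function(path, fragment) {
  lines <- readLines(path, warn = FALSE)
  hit <- grep(substr(trimws(fragment), 1, 30), lines, fixed = TRUE)
  if (length(hit)) sprintf("line %d", hit[1]) else "line unknown"
}

#' Read a configuration (cfg) file
#'
#' Accepts `$variable = value;` lines, `[A].istate = p1 [v], p2 [v];` lines
#' (single nodes or node tuples, with or without a space after the dot), and
#' the run parameters `max_time`, `time_tick`, `sample_count`, `seed`.
#' istate probabilities must sum to 1 (tolerance 1e-9); nodes without an
#' istate entry start at 0.
#'
#' @param path Path to a cfg-dialect text file.
#' @param model The already-parsed network model.
#' @return A `bp_config`.
#' @export
read_config <- function(path, model) {
  lines <- read_model_text(path)
  stmts <- trimws(strsplit(paste(lines, collapse = "\n"), ";", fixed = TRUE)[[1]])
  stmts <- stmts[nzchar(stmts)]
  variables <- model$variables
  istate <- list()
  pars <- list(max_time = 1, time_tick = 0.1, sample_count = 10000, seed = NULL)
  for (s in stmts) {
    s1 <- gsub("\\s+", " ", s)
    if (grepl("^\\$", s1)) {
      kv <- regmatches(s1, regexec("^\\$([A-Za-z_][A-Za-z0-9_]*) ?= ?(.+)$", s1))[[1]]
      if (length(kv) != 3L)
        bp_parse_error(sprintf("cannot parse variable line '%s' (%s)", s, line_of(path, s)))
      variables[[kv[2]]] <- as.numeric(kv[3])
      if (is.na(variables[[kv[2]]]))
        bp_parse_error(sprintf("non-numeric value for $%s", kv[2]))
    } else if (grepl("istate", s1, fixed = TRUE)) {
      istate[[length(istate) + 1L]] <- parse_istate_line(s1, path, s)
    } else {
      kv <- regmatches(s1, regexec("^([A-Za-z_][A-Za-z0-9_]*) ?= ?(.+)$", s1))[[1]]
      if (length(kv) != 3L)
        bp_parse_error(sprintf("cannot parse statement '%s' (%s)", s, line_of(path, s)))
      if (!(kv[2] %in% names(pars))) {
        warning(sprintf("ignoring unknown configuration parameter '%s'", kv[2]))
        next
      }
      pars[[kv[2]]] <- as.numeric(kv[3])
    }
  }
  cfg <- new_simulation_config(variables = variables, istate = istate,
                               max_time = pars$max_time, time_tick = pars$time_tick,
                               sample_count = pars$sample_count,
                               seed = if (is.null(pars$seed)) NULL else as.integer(pars$seed))
  validate_istate(cfg$istate, model$node_names)
  cfg
}

# "[A,B]. istate = 0.2 [0,0], 0.5 [0,1], ..." -> istate entry
parse_istate_line <- function(s, path, orig) {
  m <- regmatches(s, regexec(
    "^\\[ ?([A-Za-z_0-9, ]+?) ?\\] ?\\. ?istate ?= ?(.+)$", s))[[1]]
  if (length(m) != 3L)
    bp_parse_error(sprintf("cannot parse istate line '%s' (%s)", orig, line_of(path, orig)))
  nodes <- trimws(strsplit(m[2], ",", fixed = TRUE)[[1]])
  terms <- trimws(strsplit(m[3], ",(?![^\\[]*\\])", perl = TRUE)[[1]])
  values <- list(); probs <- numeric()
  for (tm in terms) {
    tv <- regmatches(tm, regexec("^([0-9.eE+-]+) ?\\[ ?([01, ]+) ?\\]$", tm))[[1]]
    if (length(tv) != 3L)
      bp_parse_error(sprintf("cannot parse istate term '%s' (%s)", tm, line_of(path, orig)))
    probs <- c(probs, as.numeric(tv[2]))
    values <- c(values, list(as.integer(trimws(strsplit(tv[3], ",")[[1]]))))
  }
  list(nodes = nodes, values = values, probs = probs)
}

#' Read a population-update (upp) file
#'
#' Accepts `death = Node;`, `division = Node;`, `steps = n;` and update lines
#' of the form `$var u= <formula>;` where formulas may contain
#' `p[(A,B) = (1,0)]` joint-probability terms.  Update formulas are applied in
#' file order after each simulation window; later formulas see earlier
#' assignments.
#'
#' @param path Path to a upp-dialect text file.
#' @param model The already-parsed network model.
#' @return A `bp_popspec`.
#' @export
read_population_spec <- function(path, model) {
  lines <- read_model_text(path)
  stmts <- trimws(strsplit(paste(lines, collapse = "\n"), ";", fixed = TRUE)[[1]])
  stmts <- stmts[nzchar(stmts)]
  death <- NULL; division <- NULL; steps <- NULL
  updates <- list()
  vars <- union(names(model$variables), model_variables_used(model))
  for (s in stmts) {
    s1 <- gsub("\\s+", " ", s)
    if (grepl("^\\$", s1)) {
      kv <- regmatches(s1, regexec("^\\$([A-Za-z_][A-Za-z0-9_]*) u= ?(.+)$", s1))[[1]]
      if (length(kv) != 3L)
        bp_parse_error(sprintf("malformed update line '%s' (%s)", s, line_of(path, s)))
      expr <- parse_expression(kv[3], nodes = model$node_names,
                               variables = union(vars, kv[2]), dialect = "update")
      updates[[length(updates) + 1L]] <- list(var = kv[2], expr = expr)
      vars <- union(vars, kv[2])
    } else {
      kv <- regmatches(s1, regexec("^([A-Za-z_][A-Za-z0-9_]*) ?= ?(.+)$", s1))[[1]]
      if (length(kv) != 3L)
        bp_parse_error(sprintf("cannot parse statement '%s' (%s)", s, line_of(path, s)))
      switch(kv[2],
        death = { death <- kv[3] },
        division = { division <- kv[3] },
        steps = { steps <- as.numeric(kv[3]) },
        bp_parse_error(sprintf("unknown population-update key '%s'", kv[2])))
    }
  }
  if (is.null(steps)) bp_validation_error("population-update file must set steps")
  new_population_spec(death_node = death, division_node = division,
                      steps = steps, updates = updates, model = model)
}

#' Import a two-column bnet logical model
#'
#' Reads the standard `targets, factors` bnet format: one node per line, the
#' second column giving its logic rule over other nodes.  Transition rates
#' default to `@logic ? 1.0 : 0.0` / `@logic ? 0.0 : 1.0`, i.e. rate 1.0 for
#' every permitted flip.  This is the entry path for standard single-cell
#' logical models that are then extended with death/division nodes and
#' population-update rules.
#'
#' @param path Path to a bnet text file.
#' @return A network model.
#' @export
import_bnet <- function(path) {
  lines <- read_model_text(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) && grepl("^targets\\s*,\\s*factors$", lines[1], ignore.case = TRUE))
    lines <- lines[-1]
  if (!length(lines)) bp_parse_error(sprintf("empty bnet model in '%s'", path))
  split <- regmatches(lines, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*,\\s*(.+)$", lines))
  bad <- which(vapply(split, length, 1L) != 3L)
  if (length(bad))
    bp_parse_error(sprintf("malformed bnet line %d: '%s'", bad[1], lines[bad[1]]))
  targets <- vapply(split, `[`, "", 2L)
  factors <- vapply(split, `[`, "", 3L)
  if (anyDuplicated(targets))
    bp_parse_error(sprintf("duplicate bnet target(s): %s",
                           paste(unique(targets[duplicated(targets)]), collapse = ", ")))
  nodes <- list()
  for (i in seq_along(targets)) {
    nodes[[targets[i]]] <- make_node(targets[i], logic = factors[i],
                                     nodes = targets, variables = character())
  }
  new_network_model(nodes)
}

# --- writers -----------------------------------------------------------------

#' Write a network model as a bnd-dialect file
#' @param model A network model.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(model, path) {
  out <- character()
  for (nd in model$nodes) {
    out <- c(out,
             sprintf("node %s {", nd$name),
             sprintf("  logic = %s;", deparse_expression(nd$logic)),
             sprintf("  rate_up = %s;", deparse_expression(nd$rate_up)),
             sprintf("  rate_down = %s;", deparse_expression(nd$rate_down)),
             "}")
  }
  writeLines(out, path)
  invisible(path)
}

#' Write a simulation configuration as a cfg-dialect file
#' @param config A `bp_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  out <- character()
  for (nm in names(config$variables))
    out <- c(out, sprintf("$%s = %s;", nm, num10(config$variables[[nm]])))
  for (ent in config$istate) {
    terms <- vapply(seq_along(ent$probs), function(j)
      sprintf("%s [%s]", num10(ent$probs[j]),
              paste(ent$values[[j]], collapse = ",")), "")
    out <- c(out, sprintf("[%s].istate = %s;",
                          paste(ent$nodes, collapse = ","),
                          paste(terms, collapse = ", ")))
  }
  out <- c(out,
           sprintf("max_time = %s;", num10(config$max_time)),
           sprintf("time_tick = %s;", num10(config$time_tick)),
           sprintf("sample_count = %d;", config$sample_count))
  if (!is.null(config$seed)) out <- c(out, sprintf("seed = %d;", config$seed))
  writeLines(out, path)
  invisible(path)
}

#' Write a population-update spec as a upp-dialect file
#' @param spec A `bp_popspec`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_population_spec <- function(spec, path) {
  out <- character()
  if (!is.null(spec$death_node)) out <- c(out, sprintf("death = %s;", spec$death_node))
  if (!is.null(spec$division_node)) out <- c(out, sprintf("division = %s;", spec$division_node))
  out <- c(out, sprintf("steps = %d;", spec$steps))
  for (u in spec$updates)
    out <- c(out, sprintf("$%s u= %s;", u$var, deparse_expression(u$expr)))
  writeLines(out, path)
  invisible(path)
}

num10 <- function(x) sprintf("%.10g", x)

#' Write population-run results to a directory
#'
#' Emits, with deterministic column order and floats at 10 significant
#' digits:
#' \itemize{
#'   \item `population.csv` -- `step,ratio,size` (step 0 is the baseline
#'     size 1, so a run of K steps yields K+1 rows);
#'   \item `node_probabilities.csv` -- `step,time,node,probability`
#'     (window-averaged occupancies on the reporting grid);
#'   \item `states_step_<k>.csv` -- `state,probability`, the distribution
#'     entering step k+1 (k = 0 is the initial distribution, k >= 1 the
#'     post-update distribution after step k);
#'   \item `metadata.json` -- seed, parameters, per-step variable values and
#'     any extra manifest fields supplied.
#' }
#'
#' @param traj A population trajectory from [run_population()] or
#'   [run_schedule()].
#' @param out_dir Output directory (created if needed).
#' @param manifest Optional named list of extra metadata (input paths,
#'   hashes, overrides, ...) merged into `metadata.json`.
#' @return `out_dir`, invisibly.
#' @export
write_results <- function(traj, out_dir, manifest = list()) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(out_dir, 2L) != 0L)
    bp_error(sprintf("cannot write to '%s'", out_dir), "bp_output_error")
  pop <- traj$population
  writeLines(c("step,ratio,size",
               sprintf("%d,%s,%s", pop$step, num10(pop$ratio), num10(pop$size))),
             file.path(out_dir, "population.csv"))
  np <- traj$node_probs
  writeLines(c("step,time,node,probability",
               sprintf("%d,%s,%s,%s", np$step, num10(np$time), np$node,
                       num10(np$probability))),
             file.path(out_dir, "node_probabilities.csv"))
  dists <- c(list(traj$initial_dist), traj$post_dists)
  for (k in seq_along(dists)) {
    d <- dists[[k]]
    if (is.null(d)) next
    ord <- order(names(d$p))
    writeLines(c("state,probability",
                 sprintf("%s,%s", names(d$p)[ord], num10(d$p[ord]))),
               file.path(out_dir, sprintf("states_step_%d.csv", k - 1L)))
  }
  meta <- c(list(
    seed = traj$seed,
    node_order = traj$nodes,
    steps = nrow(pop) - 1L,
    max_time = traj$max_time,
    time_tick = traj$time_tick,
    sample_count = traj$sample_count,
    death_node = traj$death_node,
    division_node = traj$division_node,
    truncated = isTRUE(traj$truncated),
    variables_per_step = traj$variables
  ), manifest)
  jsonlite::write_json(meta, file.path(out_dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  invisible(out_dir)
}
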