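write_tmp <- function(lines, ext) {
  f <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

test_that("bnd reader parses node blocks and synthesizes default rates", {
  f <- write_tmp(c("// a two-node chain",
                   "node I { logic = I; }",
                   "node A {",
                   "  logic = I;",
                   "  rate_up = @logic ? 2.0 : 0.0;",
                   "}"), ".bnd")
  m <- read_network(f)
  expect_identical(m$node_names, c("I", "A"))
  # defaults: rate_up = @logic ? 1 : 0, rate_down = @logic ? 0 : 1
  expect_same_ast(m$nodes$I$rate_up,
                  parse_expression("@logic ? 1.0 : 0.0", nodes = "I", dialect = "rate"))
  expect_same_ast(m$nodes$I$rate_down,
                  parse_expression("@logic ? 0.0 : 1.0", nodes = "I", dialect = "rate"))
  # explicit rate kept, missing one defaulted
  expect_identical(m$nodes$A$rate_up$yes$value, 2)
  expect_same_ast(m$nodes$A$rate_down,
                  parse_expression("@logic ? 0.0 : 1.0", nodes = "A", dialect = "rate"))
})

test_that("bnd reader rejects duplicates and unresolved references by name", {
  f <- write_tmp(c("node X { logic = X; }", "node X { logic = X; }"), ".bnd")
  expect_error(read_network(f), "duplicate")
  f <- write_tmp("node X { logic = Y; }", ".bnd")
  expect_error(read_network(f), "'Y'")
  expect_error(read_network(file.path(tempdir(), "missing.bnd")),
               class = "bp_input_error")
})

test_that("cfg reader handles istate lines, both spellings, and run parameters", {
  bnd <- write_tmp(c("node A { logic = A; }", "node B { logic = A; }"), ".bnd")
  m <- read_network(bnd)
  f <- write_tmp(c("[A]. istate = 0.2 [0], 0.8 [1];",
                   "max_time = 2; time_tick = 0.5;",
                   "sample_count = 500;"), ".cfg")
  cfg <- read_config(f, m)
  expect_equal(cfg$max_time, 2)
  expect_equal(cfg$time_tick, 0.5)
  expect_identical(cfg$sample_count, 500L)
  d <- initial_distribution(m, cfg)
  expect_equal(joint_probability(d, "A", 1), 0.8)
  expect_equal(joint_probability(d, "B", 0), 1)  # unspecified nodes start at 0

  f2 <- write_tmp("[A,B].istate = 0.2[0,0], 0.5[0,1], 0.1[1,0], 0.2[1,1];", ".cfg")
  d2 <- initial_distribution(m, read_config(f2, m))
  expect_equal(joint_probability(d2, c("A", "B"), c(0, 1)), 0.5)
  expect_equal(joint_probability(d2, "A", 1), 0.3)
})

test_that("cfg reader rejects bad probability sums and unknown nodes", {
  bnd <- write_tmp("node A { logic = A; }", ".bnd")
  m <- read_network(bnd)
  f <- write_tmp("[A].istate = 0.2 [0], 0.7 [1];", ".cfg")
  expect_error(read_config(f, m), "sum")
  f <- write_tmp("[Q].istate = 1 [1];", ".cfg")
  expect_error(read_config(f, m), "unknown node")
})

test_that("upp reader parses death/division/steps and update formulas", {
  bnd <- write_tmp(c("node NFkB { logic = NFkB; }",
                     "node Death { logic = !NFkB; }",
                     "node Division { logic = NFkB; }"), ".bnd")
  m <- read_network(bnd)
  f <- write_tmp(c("death = Death;",
                   "division = Division;",
                   "steps = 48;",
                   "$TNF_induc u= p[(NFkB)=(1)];"), ".upp")
  sp <- read_population_spec(f, m)
  expect_identical(sp$death_node, "Death")
  expect_identical(sp$division_node, "Division")
  expect_identical(sp$steps, 48L)
  expect_length(sp$updates, 1L)
  expect_identical(sp$updates[[1]]$var, "TNF_induc")
  expect_identical(sp$updates[[1]]$expr$type, "prob")

  # no death line: population can only grow or stay
  f2 <- write_tmp(c("division = Division;", "steps = 3;"), ".upp")
  expect_null(read_population_spec(f2, m)$death_node)
  # steps = 0 is invalid
  f3 <- write_tmp("steps = 0;", ".upp")
  expect_error(read_population_spec(f3, m), class = "bp_validation_error")
  f4 <- write_tmp(c("steps = 2;", "$x u 1;"), ".upp")
  expect_error(read_population_spec(f4, m), "malformed")
})

test_that("bnet import builds models with default rates", {
  f <- write_tmp(c("targets, factors",
                   "I, I",
                   "A, I",
                   "T2, (R & !A) | T2",
                   "R, A"), ".bnet")
  m <- import_bnet(f)
  expect_identical(m$node_names, c("I", "A", "T2", "R"))
  expect_same_ast(m$nodes$A$logic, parse_expression("I", nodes = m$node_names))
  expect_identical(m$nodes$T2$logic$type, "or")  # self-sustaining fate
  expect_error(import_bnet(write_tmp(character(), ".bnet")), "empty")
  expect_error(import_bnet(write_tmp("A; I", ".bnet")), "malformed")
})

test_that("every fixture round-trips through the writers and readers", {
  fixtures <- list(build_toy_model(0), build_telegraph(1, 3), build_iffl(),
                   build_random_network(4, seed = 5), build_population_motif())
  for (fx in fixtures) {
    bnd <- withr::local_tempfile(fileext = ".bnd")
    cfg <- withr::local_tempfile(fileext = ".cfg")
    upp <- withr::local_tempfile(fileext = ".upp")
    write_network(fx$model, bnd)
    write_config(fx$config, cfg)
    write_population_spec(fx$spec, upp)
    m2 <- read_network(bnd)
    expect_identical(m2$node_names, fx$model$node_names)
    for (nm in fx$model$node_names) {
      for (slot in c("logic", "rate_up", "rate_down"))
        expect_same_ast(m2$nodes[[nm]][[slot]], fx$model$nodes[[nm]][[slot]])
    }
    c2 <- read_config(cfg, m2)
    expect_equal(c2$max_time, fx$config$max_time)
    expect_equal(c2$sample_count, fx$config$sample_count)
    d1 <- initial_distribution(fx$model, fx$config)
    d2 <- initial_distribution(m2, c2)
    expect_equal(d2$p[order(names(d2$p))], d1$p[order(names(d1$p))],
                 tolerance = 1e-12)
    s2 <- read_population_spec(upp, m2)
    expect_identical(s2$death_node, fx$spec$death_node)
    expect_identical(s2$division_node, fx$spec$division_node)
    expect_identical(s2$steps, fx$spec$steps)
    expect_length(s2$updates, length(fx$spec$updates))
  }
})

test_that("any model runs under an all-defaults configuration", {
  fx <- build_toy_model(1)
  cfg <- default_config(fx$model, sample_count = 200)
  ens <- run_ensemble(fx$model, cfg, seed = 1)
  expect_s3_class(ens, "bp_ensemble")
  expect_equal(nrow(ens$node_probs), 10L)  # max_time 1 / tick 0.1
})

test_that("result files have the documented shape and are seed-deterministic", {
  fx <- build_population_motif()
  cfg <- fx$config; cfg$sample_count <- 300L
  spec <- fx$spec; spec$steps <- 2L
  traj <- run_population(fx$model, cfg, spec, seed = 9)
  out1 <- withr::local_tempdir()
  write_results(traj, out1)
  pop <- read.csv(file.path(out1, "population.csv"))
  expect_identical(names(pop), c("step", "ratio", "size"))
  expect_identical(nrow(pop), 3L)          # baseline + 2 steps
  expect_equal(pop$size[1], 1)
  np <- read.csv(file.path(out1, "node_probabilities.csv"))
  expect_identical(names(np), c("step", "time", "node", "probability"))
  expect_true(file.exists(file.path(out1, "states_step_0.csv")))
  expect_true(file.exists(file.path(out1, "states_step_2.csv")))

  meta <- jsonlite::read_json(file.path(out1, "metadata.json"))
  expect_identical(meta$seed, 9L)
  expect_identical(unlist(meta$node_order), fx$model$node_names)
  expect_false(meta$truncated)

  # same seed twice -> byte-identical files
  traj2 <- run_population(fx$model, cfg, spec, seed = 9)
  out2 <- withr::local_tempdir()
  write_results(traj2, out2)
  for (f in c("population.csv", "node_probabilities.csv", "states_step_2.csv"))
    expect_identical(readLines(file.path(out1, f)), readLines(file.path(out2, f)))
})
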