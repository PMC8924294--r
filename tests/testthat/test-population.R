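motif_dist <- function(p_death = 0.5, p_div = 0.25, p_quiet = 0.25) {
  # nodes X, Death, Division; the dividing state has X = 1 so that resetting
  # its division flag does not collide with the quiescent state
  state_distribution(c("010" = p_death, "101" = p_div, "000" = p_quiet),
                     nodes = c("X", "Death", "Division"))
}

test_that("the synchronous update reproduces the hand-enumerated weight algebra", {
  fx <- build_population_motif()
  upd <- apply_population_update(motif_dist(), fx$spec, fx$model)
  expect_false(upd$extinct)
  expect_equal(upd$ratio, 0.75)
  # division state doubles and its flag resets; death state is removed
  expect_equal(upd$dist$p[["100"]], 2 / 3)
  expect_equal(upd$dist$p[["000"]], 1 / 3)
  expect_equal(sum(upd$dist$p), 1)
  expect_equal(upd$dist$total_mass, 0.75)

  # daughters merging with an existing state: dividing state differs only by
  # its division flag
  d2 <- state_distribution(c("001" = 0.25, "000" = 0.75),
                           nodes = c("X", "Death", "Division"))
  u2 <- apply_population_update(d2, fx$spec, fx$model)
  expect_equal(u2$ratio, 1.25)
  expect_equal(u2$dist$p[["000"]], 1)
})

test_that("update is the identity without death or division and signals extinction", {
  fx <- build_population_motif()
  quiet_spec <- boolpop:::new_population_spec(steps = 3, model = fx$model)
  d <- motif_dist()
  u <- apply_population_update(d, quiet_spec, fx$model)
  expect_equal(u$ratio, 1)
  expect_equal(u$dist$p[names(d$p)], d$p)

  all_dead <- state_distribution(c("010" = 1), nodes = c("X", "Death", "Division"))
  u2 <- apply_population_update(all_dead, fx$spec, fx$model)
  expect_true(u2$extinct)
  expect_equal(u2$ratio, 0)

  # death takes precedence when both flags are active
  both <- state_distribution(c("011" = 1), nodes = c("X", "Death", "Division"))
  u3 <- apply_population_update(both, fx$spec, fx$model)
  expect_true(u3$extinct)
})

test_that("update formulas refresh variables in order against the distribution", {
  fx <- build_toy_model(0)
  d <- state_distribution(c("111000" = 0.2, "100000" = 0.8),
                          nodes = fx$model$node_names)
  vars <- refresh_variables(fx$spec, d, list(innerOn = 0, outerL = 0))
  expect_equal(vars$outerL, 1)  # 5 * P(L=1) = 5 * 0.2

  # later formulas see earlier assignments
  upd2 <- list(
    list(var = "a", expr = parse_expression("10 * p[(L) = (1)]",
                                            nodes = fx$model$node_names,
                                            variables = c("a", "b"),
                                            dialect = "update")),
    list(var = "b", expr = parse_expression("$a + 1",
                                            nodes = fx$model$node_names,
                                            variables = c("a", "b"),
                                            dialect = "update")))
  spec2 <- boolpop:::new_population_spec(steps = 1, updates = upd2,
                                         model = fx$model)
  vars2 <- refresh_variables(spec2, d, list())
  expect_equal(vars2$a, 2)
  expect_equal(vars2$b, 3)

  # silent ligand silences the receptor drive
  d0 <- state_distribution(c("100000" = 1), nodes = fx$model$node_names)
  expect_equal(refresh_variables(fx$spec, d0, list())$outerL, 0)

  # no update lines: variables unchanged
  expect_identical(refresh_variables(boolpop:::new_population_spec(steps = 1),
                                     d, list(k = 7))$k, 7)
})

test_that("population bookkeeping matches the ratio identity on every step", {
  fx <- build_population_motif()
  cfg <- fx$config; cfg$sample_count <- 1500L
  traj <- run_population(fx$model, cfg, fx$spec, seed = 81)
  pop <- traj$population
  expect_identical(nrow(pop), fx$spec$steps + 1L)
  expect_equal(pop$size, cumprod(pop$ratio), tolerance = 1e-12)
  for (k in seq_len(fx$spec$steps)) {
    pre <- traj$pre_dists[[k]]
    p_death <- joint_probability(pre, "Death", 1)
    p_div_live <- joint_probability(pre, c("Death", "Division"), c(0, 1))
    expect_equal(pop$ratio[k + 1], 1 - p_death + p_div_live, tolerance = 1e-12)
  }
})

test_that("death-only populations shrink and division-only populations grow", {
  fxd <- build_population_motif("death")
  cfgd <- fxd$config; cfgd$sample_count <- 1200L
  pd <- run_population(fxd$model, cfgd, fxd$spec, seed = 82)$population
  expect_true(all(diff(pd$size) <= 1e-12))
  expect_lt(pd$size[nrow(pd)], 1)

  fxv <- build_population_motif("division")
  pv <- run_population(fxv$model, cfgd, fxv$spec, seed = 83)$population
  expect_true(all(diff(pv$size) >= -1e-12))
  expect_gt(pv$size[nrow(pv)], 1)
})

test_that("an always-lethal model goes extinct with a truncation flag", {
  nn <- c("X", "Death")
  m <- boolpop:::new_network_model(list(
    X = boolpop:::make_node("X", rate_up = "0", rate_down = "0", nodes = nn),
    Death = boolpop:::make_node("Death", logic = "1", nodes = nn)))
  cfg <- default_config(m, sample_count = 300,
                        istate = list(list(nodes = "Death", values = list(1L),
                                           probs = 1)))
  spec <- boolpop:::new_population_spec(death_node = "Death", steps = 4,
                                        model = m)
  traj <- run_population(m, cfg, spec, seed = 84)
  expect_true(traj$truncated)
  pop <- traj$population
  expect_identical(nrow(pop), 5L)            # steps + baseline, padded with 0
  expect_equal(pop$size[-1], rep(0, 4))
})

test_that("toy coupling: T2 is reachable only through the population update", {
  fx1 <- build_toy_model(1)          # independent cells
  cfg <- fx1$config; cfg$sample_count <- 1500L
  spec <- fx1$spec; spec$steps <- 5L
  t1 <- run_population(fx1$model, cfg, spec, seed = 85)
  expect_equal(unname(final_marginals(t1)["T2"]), 0)
  expect_true(all(subset(t1$node_probs, node == "T2")$probability == 0))

  fx0 <- build_toy_model(0)          # interacting population
  t0 <- run_population(fx0$model, cfg, spec, seed = 85)
  expect_gt(unname(final_marginals(t0)["T2"]), 0.02)
  # no death or division nodes: population size stays exactly 1
  expect_equal(t0$population$ratio, rep(1, 6))
})

test_that("stepping without updates splices into one long run", {
  # two-node cascade, modest depth; compared window-by-window
  nn <- c("A", "B")
  m <- boolpop:::new_network_model(list(
    A = boolpop:::make_node("A", rate_up = "0.7", rate_down = "0.3", nodes = nn),
    B = boolpop:::make_node("B", logic = "A", nodes = nn)))
  n <- 4000L
  cfg_step <- default_config(m, max_time = 1, time_tick = 0.5, sample_count = n)
  spec <- boolpop:::new_population_spec(steps = 4, model = m)
  stepped <- run_population(m, cfg_step, spec, seed = 86)
  cfg_long <- default_config(m, max_time = 4, time_tick = 0.5, sample_count = n)
  long <- run_ensemble(m, cfg_long, seed = 87)
  np <- stepped$node_probs
  for (nm in nn) {
    a <- subset(np, node == nm)
    a <- a$probability[order(a$time)]
    b <- long$node_probs[, nm]
    se <- sqrt(pmax(b * (1 - b), 0.05) / n) * sqrt(2)
    expect_true(all(abs(a - b) < 4 * se))
  }
})
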