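test_that("packaged model fixtures load with the expected inventory", {
  thr <- threshold_model()
  expect_identical(length(thr$species), 1L)
  expect_identical(length(thr$parameters), 2L)
  expect_identical(length(thr$events), 0L)
  expect_identical(thr$viability$form, "predicate")
  osc <- oscillator_model()
  expect_identical(length(osc$species), 3L)
  expect_false(is.null(osc$mass))
  expect_identical(length(osc$events), 1L)
  expect_identical(osc$events[[1]]$name, "division")
})

test_that("model validation reports unresolved symbols and schema faults by name", {
  expect_error(define_model(species = c(X = 0), parameters = c(s = 1),
                            rates = c(X = "s - kd99*X"),
                            viability = list(expression = "X >= 1", horizon = 1)),
               "kd99", class = "tipigtow_parse_error")
  # several offences are reported together
  err <- tryCatch(define_model(species = c(X = 0), parameters = c(s = 1),
                               rates = c(X = "s - kd99*X"),
                               events = list(list(name = "e", trigger = "Y - 1",
                                                  direction = "sideways",
                                                  assignments = list(Z = "0"))),
                               viability = list(expression = "X >= 1", horizon = 1)),
                  error = identity)
  expect_s3_class(err, "tipigtow_parse_error")
  for (needle in c("kd99", "Y", "sideways", "Z")) {
    expect_match(conditionMessage(err), needle)
  }
  # arbitrary code is not a rate expression
  expect_error(define_model(species = c(X = 0), parameters = c(s = 1),
                            rates = c(X = "system('true')"),
                            viability = list(expression = "X >= 1", horizon = 1)),
               class = "tipigtow_parse_error")
  expect_error(define_model(species = c(X = 0, X = 1), parameters = c(s = 1),
                            rates = c(X = "s"),
                            viability = list(expression = "X >= 1", horizon = 1)),
               "duplicate", class = "tipigtow_parse_error")
})

test_that("threshold dynamics reach the analytic steady state s/kd", {
  thr <- threshold_model()
  for (kd in c(0.5, 1, 2, 4, 8)) {
    sim <- simulate_model(thr, mutant_spec(overrides = c(kd = kd)),
                          horizon = 80)
    xT <- unname(sim$state[nrow(sim$state), "X"])
    expect_equal(xT, 10 / kd, tolerance = 1e-6)
  }
})

test_that("simulation is deterministic and converges under tighter tolerances", {
  osc <- oscillator_model()
  a <- simulate_model(osc)
  b <- simulate_model(osc)
  expect_identical(a$state, b$state)
  expect_identical(a$division_times, b$division_times)
  tight <- simulate_model(osc, settings = list(rtol = 5e-9, atol = 5e-11))
  n <- min(length(a$division_times), length(tight$division_times))
  expect_true(n >= 3)
  rel <- abs(a$division_times[1:n] - tight$division_times[1:n]) /
    tight$division_times[1:n]
  expect_true(all(rel < 1e-3))
  thr_a <- simulate_model(threshold_model(), horizon = 30)
  thr_b <- simulate_model(threshold_model(), horizon = 30,
                          settings = list(rtol = 5e-9, atol = 5e-11))
  expect_equal(unname(thr_a$state[nrow(thr_a$state), "X"]),
               unname(thr_b$state[nrow(thr_b$state), "X"]), tolerance = 1e-6)
})

test_that("the oscillator divides with a near-constant period and is alive", {
  sim <- simulate_model(oscillator_model(), horizon = 500)
  expect_true(length(sim$division_times) >= 3)
  periods <- diff(sim$division_times)
  late <- periods[-(1:3)]  # discard the entrainment transient
  expect_lt(stats::sd(late) / mean(late), 0.05)
  expect_identical(sim$status, "alive")
  expect_identical(assess_viability(sim), "alive")
})

test_that("gene deletion zeroes synthesis and product and can kill the cycle", {
  thr <- threshold_model()
  del <- apply_deletion(thr, "G1")
  expect_identical(del$deleted_genes, "G1")
  expect_identical(unname(del$overrides["s"]), 0)
  sim <- simulate_model(thr, del, horizon = 10)
  expect_true(all(abs(sim$state[, "X"]) <= 1e-12))
  expect_error(apply_deletion(thr, "FOO1"), class = "tipigtow_invalid_input")
  # deleting the repressor abolishes downward threshold crossings: dead
  osc <- oscillator_model()
  rep_del <- apply_deletion(osc, "REP1")
  sim2 <- simulate_model(osc, rep_del)
  expect_true(all(abs(sim2$state[, "x3"]) <= 1e-10))
  expect_identical(sim2$status, "dead")
})

test_that("viability verdicts follow the division-count and mass rules", {
  osc <- oscillator_model()
  alive_sim <- simulate_model(osc)
  # no divisions within the horizon: dead
  arrested <- alive_sim
  arrested$events <- arrested$events[0, ]
  arrested$division_times <- numeric()
  expect_identical(assess_viability(arrested), "dead")
  # enough divisions but unbounded mass: dead regardless
  heavy <- alive_sim
  heavy$state[, "m"] <- heavy$state[, "m"] + 100
  expect_identical(assess_viability(heavy), "dead")
  # a run shorter than the rule horizon cannot be assessed
  short <- simulate_model(osc, horizon = 100)
  expect_true(is.na(short$status))
  expect_error(assess_viability(short), class = "tipigtow_invalid_input")
})

test_that("integration failures carry the last good time", {
  blowup <- define_model(species = c(X = 1), parameters = c(r = 3),
                         rates = c(X = "r*X^2"),
                         viability = list(expression = "X >= 0", horizon = 5),
                         name = "finite-time-blowup")
  err <- tryCatch(suppressWarnings(simulate_model(blowup, horizon = 5)),
                  error = identity)
  expect_s3_class(err, "tipigtow_simulation_error")
})
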