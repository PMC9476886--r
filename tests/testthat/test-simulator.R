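test_that("equilibration finds the resting fixed point", {
  p <- model_params()
  st <- equilibrate(p, p$L_min)
  expect_equal(st[["C"]], p$C0, tolerance = 1e-6)
  expect_equal(st[["S"]], p$S_floor)
  d <- state_derivative(st, p$L_min, p)
  expect_lt(max(abs(d)), 1e-7)
  # inhibition agrees with independent root finding on the full balance
  I_oracle <- uniroot(function(I) {
    Ra <- receptor_activity(p$L_min, I, p)
    p$k5 * (st[["C"]] - p$C0) * Ra + p$k6 * Ra - (1 - Ra) * I / p$tau_I
  }, c(0, 1e3), tol = 1e-12)$root
  expect_equal(st[["I"]], I_oracle, tolerance = 1e-6)
  # and with the closed form at the self-consistent receptor activity
  Ra_b <- receptor_activity(p$L_min, st[["I"]], p)
  expect_equal(st[["I"]], steady_state_inhibition(Ra_b, p),
               tolerance = 1e-4)
  expect_error(equilibrate(p, -1), class = "awa_invalid_input")
})

test_that("a constant-baseline stimulus yields a flat trajectory", {
  p <- model_params()
  flat <- step_protocol(schedule = list(), total_duration = 300)
  traj <- simulate_model(p, flat)
  expect_lt(max(abs(traj$data$C - p$C0)), 1e-5)
  expect_lt(diff(range(traj$data$I)), 1e-5)
})

test_that("simulation is deterministic and respects state bounds", {
  p <- model_params()
  a <- simulate_model(p, criterion_gradient_stimulus())
  b <- simulate_model(p, criterion_gradient_stimulus())
  expect_identical(a$data, b$data)
  d <- a$data
  expect_true(all(d$Ra > 0 & d$Ra < 1))
  expect_true(all(d$S >= p$S_floor & d$S <= 1))
  expect_true(all(d$C >= 0) && all(d$I >= 0))
  expect_equal(diff(range(diff(d$t))), 0, tolerance = 1e-9)
})

test_that("a step elicits one short pulse with exact adaptation", {
  p <- model_params()
  traj <- wt_step_traj()
  d <- traj$data
  pulses <- detect_pulses(traj, crit_sim(range_floor = 0.02 * p$C0))
  expect_equal(nrow(pulses), 1)
  expect_lt(pulses$duration[1], 60)
  peak_excess <- max(d$C) - p$C0
  end_on <- d$C[d$t == 360] - p$C0
  expect_lt(end_on / peak_excess, 0.05)
})

test_that("adaptive solution matches a 1 ms fixed-step reference", {
  p <- model_params()
  st <- step_protocol(schedule = list(c(20, 60)), total_duration = 120)
  adaptive <- simulate_model(p, st)
  reference <- simulate_fixed_step(p, st, dt = 0.001, thin = 100)
  common <- intersect(round(adaptive$data$t, 6),
                      round(reference$data$t, 6))
  Ca <- adaptive$data$C[round(adaptive$data$t, 6) %in% common]
  Cr <- reference$data$C[round(reference$data$t, 6) %in% common]
  peak_amp <- max(Cr) - p$C0
  expect_lt(max(abs(Ca - Cr)) / peak_amp, 0.01)
})

test_that("gradient steepness orders pulse count and amplitude", {
  p <- model_params()
  stats <- lapply(c(0.02, 0.05, 0.12), function(k) {
    sg <- sigmoid_gradient(steepness = k)
    pl <- detect_pulses(simulate_model(p, sg),
                        crit_sim(range_floor = 0.02 * p$C0))
    list(n = nrow(pl), amp = mean(pl$amplitude))
  })
  n <- vapply(stats, `[[`, numeric(1), "n")
  amp <- vapply(stats, `[[`, numeric(1), "amp")
  expect_true(all(diff(n) >= 0) || all(diff(amp) >= 0))
  expect_gte(stats[[3]]$amp, stats[[1]]$amp)
})

test_that("trajectories round-trip through CSV + JSON", {
  traj <- wt_step_traj()
  prefix <- tempfile()
  write_trajectory(traj, prefix)
  back <- read_trajectory(prefix)
  expect_equal(back$data$C, traj$data$C, tolerance = 1e-9)
  expect_equal(back$params, traj$params, tolerance = 1e-12)
  expect_equal(stimulus_level(back$stimulus, c(30, 200)),
               stimulus_level(traj$stimulus, c(30, 200)))
  unlink(paste0(prefix, c(".csv", ".json")))
})

test_that("the membrane module reduces to the simple model when disabled", {
  p <- model_params()
  st <- step_protocol(schedule = list(c(30, 60)), total_duration = 150)
  off <- simulate_detailed(p, membrane_params(w = 0, gS = 0), st)
  simple <- simulate_model(p, st)
  expect_lt(max(abs(off$data$C - simple$data$C)), 1e-6)
})

test_that("the detailed model keeps the wt/tax-6 contrast", {
  p <- model_params()
  two <- two_step_protocol("long")
  h <- habituation_metrics(simulate_detailed(p, membrane_params(), two),
                           two)
  expect_lt(h$second, h$first)
  p6 <- make_mutant(p, "tax-6")
  t6 <- simulate_detailed(p6, membrane_params(), criterion_step_stimulus())
  d6 <- t6$data
  base6 <- d6$C[d6$t == 50]
  peak6 <- max(d6$C) - base6
  on_tail <- d6$C[d6$t >= 90 & d6$t <= 360] - base6
  expect_gt(min(on_tail) / peak6, 0.2)  # no exact adaptation while on
  expect_true("V" %in% names(d6))
})
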