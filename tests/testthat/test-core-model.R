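test_that("receptor activity matches the logistic log-sensing form", {
  p <- model_params()
  expect_identical(receptor_activity(p$L0, 0, p), 0.5)
  # k2 * I = ln 9 shifts the curve to 1/(1+9)
  expect_equal(receptor_activity(p$L0, log(9) / p$k2, p), 0.1)
  p1 <- model_params(k1 = 1)
  expect_equal(receptor_activity(exp(1) * p1$L0, 0, p1),
               1 / (1 + exp(-1)), tolerance = 1e-12)
  expect_error(receptor_activity(NaN, 0, p), class = "awa_invalid_input")
  expect_error(receptor_activity(p$L0, -1, p), class = "awa_invalid_input")
})

test_that("receptor activity is bounded and monotone across random parameters", {
  set.seed(101)
  for (rep in 1:25) {
    p <- model_params(k1 = runif(1, 0.2, 4), k2 = runif(1, 1, 40),
                      L0 = 10^runif(1, -5, -2), Rt = runif(1, 0.1, 0.9))
    L <- sort(10^runif(7, -3.5, 1))  # above the L_min clamp
    I <- sort(runif(5, 0, 3))
    ra_L <- receptor_activity(L, 0.5, p)
    expect_true(all(ra_L > 0 & ra_L < 1))
    expect_true(all(diff(ra_L) > 0))
    ra_I <- receptor_activity(1e-2, I, p)
    expect_true(all(diff(ra_I) < 0))
  }
})

test_that("scaling ligand is exactly offset by a linear inhibition shift", {
  set.seed(7)
  p <- model_params(k1 = 1.3, k2 = 17)
  for (rep in 1:20) {
    L <- 10^runif(1, -2.5, 0)  # keep L and m*L above the L_min clamp
    I <- runif(1, 0, 1)
    m <- 10^runif(1, -1, 1)
    I2 <- I + p$k1 * log(m) / p$k2
    if (I2 < 0) next
    expect_equal(receptor_activity(m * L, I2, p),
                 receptor_activity(L, I, p), tolerance = 1e-12)
  }
})

test_that("mutant construction sets k5 = 0 and rejects unknown labels", {
  p <- model_params()
  m <- make_mutant(p, "tax-6")
  expect_identical(m$k5, 0)
  expect_identical(m[setdiff(awapulse:::param_names(), "k5")],
                   p[setdiff(awapulse:::param_names(), "k5")])
  expect_identical(make_mutant(p, "wild-type"), p)
  expect_error(make_mutant(p, "odr-10"), class = "awa_unknown_mutant")
  expect_error(make_mutant(p, "odr-10"), "valid labels")
})

test_that("parameter validation rejects non-physical values", {
  expect_error(model_params(k3 = -1), class = "awa_invalid_parameter")
  expect_error(model_params(Rt = 1.2), class = "awa_invalid_parameter")
  expect_error(model_params(tau_c = 0), class = "awa_invalid_parameter")
  expect_error(model_params(k5 = -0.1), class = "awa_invalid_parameter")
  expect_silent(model_params(k5 = 0, k6 = 0))
})

test_that("steady-state inhibition closed form matches root finding", {
  p <- model_params(k6 = 2 / 3, tau_I = 3)
  expect_equal(steady_state_inhibition(0.5, p), p$k6 * p$tau_I)
  p2 <- model_params(k6 = 2, tau_I = 3)
  expect_equal(steady_state_inhibition(0.9, p2), 54, tolerance = 1e-12)
  # same value from root-finding on the inhibition balance at C = C0
  root <- uniroot(function(I) p2$k6 * 0.9 - (1 - 0.9) * I / p2$tau_I,
                  c(0, 1e4), tol = 1e-12)$root
  expect_equal(steady_state_inhibition(0.9, p2), root, tolerance = 1e-6)
  expect_error(steady_state_inhibition(1, p), class = "awa_divergence")
  expect_error(steady_state_inhibition(0, p), class = "awa_invalid_input")
  expect_equal(steady_state_inhibition(1e-12, p), p$k6 * p$tau_I * 1e-12,
               tolerance = 1e-6)
})

test_that("adaptive threshold inverts the receptor curve at Rt", {
  p <- model_params()
  p5 <- model_params(Rt = 0.5)
  expect_equal(adaptive_threshold(0, p5), p5$L0, tolerance = 1e-12)
  # raising I by dI multiplies the threshold by exp(k2 dI / k1)
  dI <- 0.37
  expect_equal(adaptive_threshold(1 + dI, p) / adaptive_threshold(1, p),
               exp(p$k2 * dI / p$k1), tolerance = 1e-12)
  set.seed(11)
  for (I in runif(10, 0, 2)) {
    expect_equal(receptor_activity(adaptive_threshold(I, p), I, p), p$Rt,
                 tolerance = 1e-12)
  }
})

test_that("state derivatives transcribe the model equations exactly", {
  set.seed(42)
  p <- model_params()
  for (rep in 1:50) {
    S <- runif(1, 0.01, 0.99)
    C <- runif(1, 0.01, 6)
    I <- runif(1, 0.01, 2)
    L <- 10^runif(1, -4, 0.5)
    got <- state_derivative(c(S = S, C = C, I = I), L, p)
    want <- rhs_literal(S, C, I, L, p)
    expect_equal(got, want, tolerance = 1e-14)
  }
})

test_that("calcium at baseline makes the feedback k5-independent", {
  p <- model_params()
  p6 <- make_mutant(p, "tax-6")
  st <- c(S = 0.3, C = p$C0, I = 0.4)
  expect_identical(state_derivative(st, 0.01, p),
                   state_derivative(st, 0.01, p6))
})

test_that("the equilibrated fixed point zeroes the derivatives", {
  p <- model_params()
  Ra_b <- receptor_activity(p$L_min, 0, p)
  # construct the resting state: floor switch, baseline calcium, balanced I
  I_eq <- uniroot(function(I) {
    Ra <- receptor_activity(p$L_min, I, p)
    p$k6 * Ra - (1 - Ra) * I / p$tau_I
  }, c(0, 100), tol = 1e-14)$root
  d <- state_derivative(c(S = p$S_floor, C = p$C0, I = I_eq), p$L_min, p)
  expect_lt(abs(d[["I"]]), 1e-10)
  expect_equal(d[["C"]], p$k4 * p$S_floor, tolerance = 1e-9)
  expect_identical(d[["S"]], 0)  # outward at the floor, clamped
})

test_that("parameter sets round-trip through YAML and JSON", {
  p <- model_params(k2 = 12.5, tau_I = 987)
  for (ext in c(".yaml", ".json")) {
    f <- tempfile(fileext = ext)
    write_params(p, f)
    expect_equal(read_params(f), p, tolerance = 1e-12)
    unlink(f)
  }
  # tax-6 expressed as an override block
  f <- tempfile(fileext = ".yaml")
  write_params(p, f, override = list(k5 = 0))
  q <- read_params(f)
  expect_identical(q$k5, 0)
  expect_equal(q$k2, p$k2)
  unlink(f)
})
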