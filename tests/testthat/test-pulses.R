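test_that("simple bump fixtures are detected as specified", {
  # single triangular bump
  tri <- list(t = 0:20, value = c(seq(0, 1, by = 0.1),
                                  seq(0.9, 0, by = -0.1)))
  for (cr in list(crit_exp(), crit_sim())) {
    pl <- detect_pulses(tri, cr)
    expect_equal(nrow(pl), 1)
    expect_equal(pl$amplitude, 1)
    expect_equal(pl$t_peak, 10)
  }
  # three separated bumps 1.0 / 0.5 / 0.1: experimental 20% rule drops the
  # smallest, simulation 1% rule keeps all three
  fx <- fixture_pulses(data.frame(t_peak = c(30, 90, 150),
                                  amplitude = c(1, 0.5, 0.1),
                                  width = c(3, 3, 3)), duration = 200)
  expect_equal(nrow(detect_pulses(fx, crit_exp())), 2)
  expect_equal(count_pulses(fx, crit_exp()), 2L)
  expect_equal(nrow(detect_pulses(fx, crit_sim())), 3)
})

test_that("constant traces fall back to one pulse only experimentally", {
  flat <- list(t = seq(0, 50), value = rep(0.3, 51))
  expect_equal(count_pulses(flat, crit_exp()), 1L)
  expect_equal(count_pulses(flat, crit_sim()), 0L)
  expect_equal(nrow(detect_pulses(flat, crit_exp())), 0)
})

test_that("detectors agree with the brute-force oracle on random fixtures", {
  for (seed in 1:200) {
    tr <- random_trace(seed)
    for (cr in list(crit_exp(), crit_sim())) {
      got <- detect_pulses(tr, cr)
      want <- brute_force_pulses(tr$t, tr$value, cr)
      expect_equal(got, want, tolerance = 1e-9,
                   info = sprintf("seed %d, %s", seed, cr$variant))
    }
  }
})

test_that("detection is invariant to time shifts and positive rescaling", {
  set.seed(9)
  tr <- random_trace(17)
  for (cr in list(crit_exp(), crit_sim())) {
    base <- detect_pulses(tr, cr)
    shifted <- detect_pulses(list(t = tr$t + 55, value = 3 * tr$value + 2),
                             cr)
    expect_equal(nrow(shifted), nrow(base))
    if (nrow(base)) {
      expect_equal(shifted$t_peak, base$t_peak + 55, tolerance = 1e-9)
      expect_equal(shifted$amplitude, 3 * base$amplitude,
                   tolerance = 1e-9)
      expect_equal(shifted$duration, base$duration, tolerance = 1e-6)
    }
  }
})

test_that("detected pulses are well-ordered with valid boundaries", {
  for (seed in c(3, 14, 59)) {
    tr <- random_trace(seed)
    pl <- detect_pulses(tr, crit_sim())
    if (nrow(pl) < 2) next
    expect_true(all(diff(pl$t_peak) > 0))
    expect_true(all(pl$t_init <= pl$t_peak & pl$t_peak <= pl$t_term))
    expect_true(all(pl$amplitude >= 0))
  }
  expect_error(detect_pulses(list(t = c(1, 3, 2), value = c(0, 1, 0)),
                             crit_sim()), class = "awa_invalid_input")
  expect_error(detect_pulses(list(t = 1:2, value = c(0, 1)), crit_sim()),
               class = "awa_invalid_input")
})

test_that("interpulse growth recovers a geometric interval law exactly", {
  # peaks with intervals 2 * 1.5^j  ->  log-linear slope ln 1.5
  dt <- 2 * 1.5^(1:6)
  pulses <- data.frame(index = 1:7, t_peak = c(0, cumsum(dt)))
  fit <- interpulse_growth(pulses)
  expect_equal(fit$beta, log(1.5), tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_error(interpulse_growth(pulses[1:2, ]),
               class = "awa_insufficient_data")
})

test_that("fraction of early pulses counts initiation times", {
  pulses <- data.frame(t_init = c(10, 20, 30, 70), t_peak = c(12, 22, 32, 72))
  expect_equal(fraction_before(pulses, 50), 0.75)
  expect_equal(fraction_before(pulses, 100), 1)
  expect_error(fraction_before(pulses[0, ], 50),
               class = "awa_insufficient_data")
})

test_that("exponential decay fitting recovers parameters", {
  x <- seq(0, 40)
  f <- fit_decay(x, 3 * exp(-x / 5) + 0.2)
  expect_equal(f$a, 3, tolerance = 1e-6)
  expect_equal(f$tau, 5, tolerance = 1e-6)
  expect_equal(f$c, 0.2, tolerance = 1e-6)
  expect_lt(f$rss, 1e-10)
  expect_error(fit_decay(x, 0.1 + 0.02 * x), class = "awa_fit_error")
  expect_error(fit_decay(1:3, c(3, 2, 1)), class = "awa_invalid_input")
})

test_that("decay fits tolerate measurement noise", {
  x <- seq(0, 40)
  clean <- 3 * exp(-x / 5) + 0.2
  taus <- vapply(1:100, function(s) {
    set.seed(s)
    fit_decay(x, clean + rnorm(length(x), 0, 0.03))$tau
  }, numeric(1))
  expect_lt(abs(median(taus) - 5) / 5, 0.05)
})

test_that("habituation metrics compare step windows against baseline", {
  proto <- two_step_protocol("long")
  bump <- function(tt, t0) 2 * exp(-(tt - t0)^2 / (2 * 4^2))
  tt <- seq(0, proto$duration, by = 0.5)
  # identical responses in both windows -> zero difference
  tr <- list(t = tt, value = bump(tt, proto$events$start[1] + 10) +
               bump(tt, proto$events$start[2] + 10))
  h <- habituation_metrics(tr, proto)
  expect_equal(h$difference, 0, tolerance = 1e-9)
  # a weaker second response -> positive difference
  tr2 <- list(t = tt, value = bump(tt, proto$events$start[1] + 10) +
                0.4 * bump(tt, proto$events$start[2] + 10))
  expect_gt(habituation_metrics(tr2, proto)$difference, 0)
  expect_error(habituation_metrics(list(t = tt[tt < 400],
                                        value = tt[tt < 400] * 0),
                                   proto), class = "awa_window_error")
  expect_error(habituation_metrics(tr, step_protocol(
    schedule = list(c(10, 20)))), class = "awa_invalid_input")
})

test_that("min-max normalization is exact, idempotent and invertible", {
  expect_equal(normalize_trace(c(2, 4, 6)), c(0, 0.5, 1))
  v <- c(0, 0.25, 0.5, 1)
  expect_identical(normalize_trace(v), v)
  set.seed(5)
  x <- rnorm(50)
  nx <- normalize_trace(x)
  expect_equal(nx * diff(range(x)) + min(x), x, tolerance = 1e-12)
  expect_error(normalize_trace(rep(1, 5)),
               class = "awa_degenerate_normalization")
})

test_that("pulse tables export to CSV", {
  fx <- fixture_pulses(data.frame(t_peak = c(30, 90), amplitude = c(1, 2),
                                  width = c(3, 3)), duration = 150)
  pl <- detect_pulses(fx, crit_exp())
  f <- tempfile(fileext = ".csv")
  write_pulses_csv(pl, f, trace_id = "fx1")
  d <- read.csv(f)
  expect_equal(nrow(d), 2)
  expect_equal(d$trace_id, rep("fx1", 2))
  unlink(f)
})
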