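test_that("step protocols evaluate to the scheduled levels", {
  st <- step_protocol(1.2e-4, 1.15, schedule = list(c(60, 300), c(480, 30)))
  expect_equal(stimulus_level(st, c(30, 59.9)), rep(1.2e-4, 2))
  expect_identical(stimulus_level(st, 200), 1.15)
  expect_identical(stimulus_level(st, 490), 1.15)
  expect_equal(stimulus_level(st, 400), 1.2e-4)
  expect_equal(nrow(st$events), 2)
  # empty schedule is a constant baseline
  flat <- step_protocol(schedule = list())
  expect_equal(stimulus_level(flat, seq(0, 60, 5)), rep(1.2e-4, 13))
  expect_error(step_protocol(schedule = list(c(0, 100), c(50, 100))),
               class = "awa_schedule_error")
  expect_error(step_protocol(schedule = list(c(-5, 10))),
               class = "awa_schedule_error")
})

test_that("two-step presets encode the habituation schedules", {
  long <- two_step_protocol("long")
  expect_equal(long$events$end[1] - long$events$start[1], 300)   # 5 min on
  expect_equal(long$events$start[2] - long$events$end[1], 120)   # 2 min off
  short <- two_step_protocol("short")
  expect_equal(short$events$end[1] - short$events$start[1], 60)  # 1 min on
  expect_equal(short$events$start[2] - short$events$end[1], 360) # 6 min off
  train <- repetitive_steps(n_steps = 6)
  expect_equal(nrow(train$events), 6)
  expect_true(all(diff(train$events$start) ==
                    diff(train$events$start)[1]))
})

test_that("sigmoid gradients have the documented midpoint geometry", {
  sg <- sigmoid_gradient(1.2e-4, 1.15, t_mid = 600, steepness = 0.02,
                         duration = 1200)
  expect_equal(stimulus_level(sg, 600), (1.2e-4 + 1.15) / 2,
               tolerance = 1e-12)
  # derivative symmetric about the inflection
  h <- 1e-3
  dL <- function(t) (stimulus_level(sg, t + h) -
                       stimulus_level(sg, t - h)) / (2 * h)
  for (delta in c(30, 120, 300))
    expect_equal(dL(600 + delta), dL(600 - delta), tolerance = 1e-8)
  # maximal first derivative at t_mid equals k (peak - base) / 4
  expect_equal(dL(600), 0.02 * (1.15 - 1.2e-4) / 4, tolerance = 1e-6)
  expect_error(sigmoid_gradient(1, 0.5, 600, 0.02, 1200),
               class = "awa_invalid_gradient")
  expect_error(sigmoid_gradient(1.2e-4, 1.15, 1300, 0.02, 1200),
               class = "awa_invalid_gradient")
})

test_that("linear ramps are linear and error on bad inputs", {
  r <- linear_ramp(1.2e-4, 2e-5, 600)
  expect_equal(stimulus_level(r, 600), 1.2e-4 + 2e-5 * 600)
  flat <- linear_ramp(1.2e-4, 0, 600)
  expect_equal(stimulus_level(flat, c(0, 300, 600)), rep(1.2e-4, 3))
  r2 <- linear_ramp(1.2e-4, 4e-5, 600)
  tt <- c(10, 100, 400)
  expect_equal(stimulus_level(r2, tt) - 1.2e-4,
               2 * (stimulus_level(r, tt) - 1.2e-4), tolerance = 1e-12)
  expect_error(linear_ramp(1.2e-4, -1e-5, 600), class = "awa_invalid_input")
  expect_error(linear_ramp(1.2e-4, 1e-5, -5), class = "awa_invalid_input")
})

test_that("stimulus evaluation is pure and respects the baseline floor", {
  set.seed(3)
  for (rep in 1:10) {
    sg <- sigmoid_gradient(10^runif(1, -4, -3), 10^runif(1, -1, 1),
                           t_mid = runif(1, 100, 500),
                           steepness = runif(1, 0.005, 0.1),
                           duration = 900)
    tt <- runif(20, 0, 900)
    expect_identical(stimulus_level(sg, tt), stimulus_level(sg, tt))
    expect_true(all(stimulus_level(sg, tt) >= sg$baseline))
  }
})

test_that("protocols round-trip through YAML and export to CSV", {
  protos <- list(step_protocol(schedule = list(c(60, 300))),
                 sigmoid_gradient(),
                 linear_ramp(slope = 3e-5))
  tt <- seq(0, 400, by = 7)
  for (st in protos) {
    f <- tempfile(fileext = ".yaml")
    write_stimulus_yaml(st, f)
    st2 <- read_stimulus_yaml(f)
    expect_equal(stimulus_level(st2, tt), stimulus_level(st, tt))
    unlink(f)
  }
  f <- tempfile(fileext = ".csv")
  write_stimulus_csv(protos[[1]], f, dt = 1)
  d <- read.csv(f)
  expect_named(d, c("t", "L"))
  expect_equal(d$L, stimulus_level(protos[[1]], d$t))
  unlink(f)
})
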