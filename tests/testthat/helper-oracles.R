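# Independent oracles used across the suite.

# Literal transcription of the model equations (no clamping logic); valid
# for interior states where no boundary layer is active.
rhs_literal <- function(S, C, I, L, p) {
  Ra <- 1 / (1 + exp(-p$k1 * log(max(L, p$L_min) / p$L0) + p$k2 * I))
  c(S = p$k3 * (Ra - p$Rt) * S,
    C = p$k4 * S - (C - p$C0) / p$tau_c,
    I = p$k5 * (C - p$C0) * Ra + p$k6 * Ra - (1 - Ra) * I / p$tau_I)
}

# Brute-force O(n^2) pulse detector implementing the documented criteria
# directly with index-by-index scans; deliberately naive.
brute_force_pulses <- function(t, v, criteria) {
  n <- length(v)
  ref <- min(v)
  a <- v - ref
  gmax <- max(a)
  empty <- data.frame(index = integer(), t_peak = numeric(),
                      amplitude = numeric(), t_init = numeric(),
                      t_term = numeric(), duration = numeric())
  if (gmax <= criteria$range_floor) return(empty)

  # strict local maxima, plateaus collapsed to their first sample
  peaks <- c()
  for (i in 2:(n - 1)) {
    if (v[i] <= v[i - 1]) next
    j <- i
    while (j < n && v[j + 1] == v[i]) j <- j + 1
    if (j < n && v[j + 1] < v[i]) peaks <- c(peaks, i)
  }
  peaks <- peaks[a[peaks] > criteria$amplitude_fraction * gmax]

  if (criteria$variant == "experimental" && length(peaks)) {
    ok <- rep(FALSE, length(peaks))
    for (k in seq_along(peaks)) {
      i <- peaks[k]
      amp <- a[i]
      low <- (1 - criteria$decay_fraction) * amp
      left <- FALSE
      for (x in seq(i - 1, 1)) {
        if (a[x] > amp) break
        if (a[x] <= low) { left <- TRUE; break }
      }
      right <- FALSE
      for (x in seq(i + 1, n)) {
        if (a[x] > amp) break
        if (a[x] <= low) { right <- TRUE; break }
      }
      ok[k] <- left && right
    }
    peaks <- peaks[ok]
  }
  if (!length(peaks)) return(empty)

  # merge maxima that never re-initiated (no drop to the init level)
  kept <- peaks[1]
  if (length(peaks) > 1) {
    for (i in peaks[-1]) {
      last <- kept[length(kept)]
      valley <- min(a[last:i])
      if (valley <= criteria$init_fraction * a[i]) kept <- c(kept, i)
      else if (a[i] > a[last]) kept[length(kept)] <- i
    }
  }

  rows <- list()
  for (k in seq_along(kept)) {
    i <- kept[k]
    amp <- a[i]
    lev_i <- criteria$init_fraction * amp
    lev_t <- (1 - criteria$term_fraction) * amp
    lo <- if (k > 1) kept[k - 1] else 1
    hi <- if (k < length(kept)) kept[k + 1] else n
    t_init <- NA
    for (x in seq(i, lo)) {
      if (a[x] <= lev_i) {
        t_init <- if (x < i)
          t[x] + (lev_i - a[x]) / (a[x + 1] - a[x]) * (t[x + 1] - t[x])
        else t[x]
        break
      }
    }
    if (is.na(t_init)) {
      w <- seq(lo, i)
      t_init <- t[w[which.min(a[w])]]
    }
    t_term <- NA
    for (x in seq(i, hi)) {
      if (a[x] <= lev_t) {
        t_term <- if (x > i)
          t[x - 1] + (lev_t - a[x - 1]) / (a[x] - a[x - 1]) *
            (t[x] - t[x - 1])
        else t[x]
        break
      }
    }
    if (is.na(t_term)) {
      w <- seq(i, hi)
      t_term <- t[w[which.min(a[w])]]
    }
    rows[[k]] <- data.frame(t_peak = t[i], amplitude = amp,
                            t_init = min(t_init, t[i]),
                            t_term = max(t_term, t[i]))
  }
  out <- do.call(rbind, rows)
  data.frame(index = seq_len(nrow(out)), t_peak = out$t_peak,
             amplitude = out$amplitude, t_init = out$t_init,
             t_term = out$t_term, duration = out$t_term - out$t_init)
}

# random trace fixtures for detector equivalence testing: mixtures of
# bumps, ramps and noise on irregular but increasing grids
random_trace <- function(seed) {
  set.seed(seed)
  n <- sample(30:200, 1)
  t <- cumsum(runif(n, 0.2, 1.5))
  kind <- sample(1:3, 1)
  v <- switch(kind,
    cumsum(rnorm(n, 0, 0.3)),                         # random walk
    {                                                 # bumps + noise
      v <- rep(0, n)
      for (b in seq_len(sample(1:5, 1))) {
        tp <- runif(1, min(t), max(t))
        w <- runif(1, 1, 8)
        v <- v + runif(1, 0.2, 3) * exp(-(t - tp)^2 / (2 * w^2))
      }
      v + rnorm(n, 0, 0.05)
    },
    sin(t / runif(1, 1, 6)) * runif(1, 0.5, 2) + rnorm(n, 0, 0.1))
  list(t = t, value = v)
}

# short names for the two detector settings used everywhere in the suite
crit_exp <- function(...) pulse_criteria("experimental", ...)
crit_sim <- function(...) pulse_criteria("simulation", ...)

# default-parameter simulations reused across test files (memoised so the
# suite pays for each one once)
.sim_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (is.null(.sim_cache[[key]])) .sim_cache[[key]] <- force(expr)
  .sim_cache[[key]]
}
wt_step_traj <- function() cached("wt_step",
  simulate_model(model_params(), criterion_step_stimulus()))
wt_grad_traj <- function() cached("wt_grad",
  simulate_model(model_params(), criterion_gradient_stimulus()))
tax6_step_traj <- function() cached("tax6_step",
  simulate_model(make_mutant(model_params(), "tax-6"),
                 criterion_step_stimulus()))
tax6_grad_traj <- function() cached("tax6_grad",
  simulate_model(make_mutant(model_params(), "tax-6"),
                 criterion_gradient_stimulus()))
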