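#' Pulse detection criteria
#'
#' Two detector variants are used, mirroring how recorded worms and
#' simulated traces are scored:
#' \describe{
#'   \item{experimental}{a local maximum qualifies as a pulse when its
#'     amplitude exceeds `amplitude_fraction` (default 20%) of the trace's
#'     maximal amplitude AND the trace decays by at least `decay_fraction`
#'     (default 70%) of that amplitude on both sides of the peak before any
#'     sample exceeds the peak level again.  When no point qualifies the
#'     count falls back to 1 (`fallback_count_one`), scoring recordings
#'     with a single unresolvable transient.}
#'   \item{simulation}{a local maximum qualifies when its amplitude exceeds
#'     `amplitude_fraction` (default 1%) of the global maximal amplitude;
#'     no fallback.}
#' }
#' For both variants, a pulse's initiation time is when the trace has risen
#' more than `init_fraction` (default 10%) of the pulse amplitude, and its
#' termination when it has fallen more than `term_fraction` (default 90%)
#' of the amplitude, located by linear interpolation between samples.
#' Amplitudes are measured above the trace minimum, so detection is
#' invariant under shifts and positive rescaling.
#'
#' @param variant `"experimental"` or `"simulation"`.
#' @param amplitude_fraction fraction of the trace's maximal amplitude a
#'   local maximum must exceed; defaults 0.20 (experimental), 0.01
#'   (simulation).
#' @param decay_fraction required two-sided decay fraction (experimental).
#' @param init_fraction,term_fraction rise/fall fractions defining pulse
#'   boundaries.
#' @param fallback_count_one logical; report one pulse when none qualifies
#'   (experimental counting rule only).
#' @param range_floor absolute dynamic-range floor (trace units): traces
#'   whose max-minus-min is at or below it contain no pulses.  Defaults to
#'   0, meaning any numerical ripple in an otherwise flat trace could
#'   qualify; simulation-scoring helpers set it from the model's baseline
#'   calcium.
#' @return A list of class `awa_pulse_criteria`.
#' @export
pulse_criteria <- function(variant = c("experimental", "simulation"),
                           amplitude_fraction = NULL,
                           decay_fraction = 0.70,
                           init_fraction = 0.10, term_fraction = 0.90,
                           fallback_count_one = NULL,
                           range_floor = 0) {
  variant <- match.arg(variant)
  if (is.null(amplitude_fraction))
    amplitude_fraction <- if (variant == "experimental") 0.20 else 0.01
  if (is.null(fallback_count_one))
    fallback_count_one <- variant == "experimental"
  fr <- c(amplitude_fraction, decay_fraction, init_fraction, term_fraction)
  if (any(!is.finite(fr)) || any(fr <= 0) || any(fr >= 1))
    awa_stop("all criterion fractions must lie in (0, 1)",
             "awa_invalid_parameter")
  if (range_floor < 0)
    awa_stop("range_floor must be non-negative", "awa_invalid_parameter")
  structure(list(variant = variant,
                 amplitude_fraction = amplitude_fraction,
                 decay_fraction = decay_fraction,
                 init_fraction = init_fraction,
                 term_fraction = term_fraction,
                 fallback_count_one = fallback_count_one,
                 range_floor = range_floor),
            class = "awa_pulse_criteria")
}

# Accepts an awa_trajectory (calcium series), an awa_trace, or a
# data.frame/list with $t and $value(s); returns list(t, v).
as_trace_series <- function(trace) {
  if (inherits(trace, "awa_trajectory"))
    return(list(t = trace$data$t, v = trace$data$C))
  if (inherits(trace, "awa_trace"))
    return(list(t = trace$t, v = trace$values))
  if (is.list(trace)) {
    v <- if (!is.null(trace$value)) trace$value else trace$values
    if (!is.null(trace$t) && !is.null(v))
      return(list(t = as.numeric(trace$t), v = as.numeric(v)))
  }
  awa_stop("trace must be an awa_trajectory, awa_trace, or have $t and $value",
           "awa_invalid_input")
}

# indices of local maxima; a plateau is represented by its first sample
local_maxima <- function(v) {
  n <- length(v)
  if (n < 3) return(integer())
  idx <- integer()
  i <- 2
  while (i <= n - 1) {
    if (v[i] > v[i - 1]) {
      j <- i
      while (j < n && v[j + 1] == v[i]) j <- j + 1
      if (j <= n - 1 && v[j + 1] < v[i]) idx <- c(idx, i)
      i <- j + 1
    } else i <- i + 1
  }
  idx
}

# linear-interpolated time at which `v` crosses `level`
cross_time <- function(t1, v1, t2, v2, level) {
  if (v2 == v1) return(t1)
  t1 + (level - v1) / (v2 - v1) * (t2 - t1)
}

#' Detect calcium pulses in a trace
#'
#' Scans a fold-change (or calcium) time series for transient pulses under
#' either criteria variant (see [pulse_criteria()]).  Returned pulses are
#' time-ordered; boundary times are linearly interpolated at the
#' rise/fall fractions, searching between neighboring detected peaks (the
#' inter-peak minimum stands in when the trace never crosses the level,
#' e.g. for a final non-decaying pulse the termination is the end of the
#' trace).  Consecutive local maxima with no intervening drop to the
#' initiation level count as one pulse event (the later maximum never
#' initiated), so a flat-topped plateau is a single pulse.
#'
#' @param trace an `awa_trajectory` (its calcium series is scored), an
#'   `awa_trace`, or anything with `$t` and `$value`.
#' @param criteria an [pulse_criteria()] object.
#' @return A data.frame with one row per pulse: `index`, `t_peak`,
#'   `amplitude` (above the trace minimum), `t_init`, `t_term`, `duration`.
#' @export
detect_pulses <- function(trace, criteria = pulse_criteria("simulation")) {
  stopifnot(inherits(criteria, "awa_pulse_criteria"))
  ser <- as_trace_series(trace)
  t <- ser$t; v <- ser$v
  if (length(t) < 3)
    awa_stop("trace needs at least 3 samples", "awa_invalid_input")
  if (is.unsorted(t, strictly = TRUE))
    awa_stop("time grid must be strictly increasing", "awa_invalid_input")
  if (anyNA(v) || any(!is.finite(v)))
    awa_stop("trace values must be finite", "awa_invalid_input")

  empty <- data.frame(index = integer(), t_peak = numeric(),
                      amplitude = numeric(), t_init = numeric(),
                      t_term = numeric(), duration = numeric())
  ref <- min(v)
  a <- v - ref
  gmax <- max(a)
  if (gmax <= criteria$range_floor) return(empty)

  cand <- local_maxima(v)
  cand <- cand[a[cand] > criteria$amplitude_fraction * gmax]

  if (criteria$variant == "experimental" && length(cand)) {
    keep <- vapply(cand, function(i) {
      amp <- a[i]
      low <- (1 - criteria$decay_fraction) * amp
      ok_side <- function(path) {
        for (x in path) {
          if (a[x] > amp) return(FALSE)
          if (a[x] <= low) return(TRUE)
        }
        FALSE
      }
      ok_side(rev(seq_len(i - 1))) && ok_side(seq(i + 1, length(v)))
    }, logical(1))
    cand <- cand[keep]
  }

  # one event per rise: a maximum only starts a new pulse if the trace
  # dropped to/below its initiation level since the previous kept peak
  # (otherwise it never "initiated"); ties within a plateau keep the first
  if (length(cand) > 1) {
    merged <- cand[1]
    for (i in cand[-1]) {
      last <- merged[length(merged)]
      valley <- min(a[last:i])
      if (valley <= criteria$init_fraction * a[i]) merged <- c(merged, i)
      else if (a[i] > a[last]) merged[length(merged)] <- i
    }
    cand <- merged
  }
  if (!length(cand)) return(empty)

  n <- length(v)
  res <- lapply(seq_along(cand), function(k) {
    i <- cand[k]
    amp <- a[i]
    lev_i <- criteria$init_fraction * amp
    lev_t <- (1 - criteria$term_fraction) * amp
    lo <- if (k > 1) cand[k - 1] else 1
    hi <- if (k < length(cand)) cand[k + 1] else n
    # initiation: last fall to/below the rise level before the peak
    left <- seq(lo, i)
    below <- left[a[left] <= lev_i]
    t_init <- if (length(below)) {
      m <- max(below)
      if (m < i) cross_time(t[m], a[m], t[m + 1], a[m + 1], lev_i) else t[m]
    } else t[left[which.min(a[left])]]
    # termination: first fall below the fall level after the peak
    right <- seq(i, hi)
    below <- right[a[right] <= lev_t]
    t_term <- if (length(below)) {
      m <- min(below)
      if (m > i) cross_time(t[m - 1], a[m - 1], t[m], a[m], lev_t) else t[m]
    } else t[right[which.min(a[right])]]
    data.frame(t_peak = t[i], amplitude = amp,
               t_init = t_init, t_term = t_term)
  })
  res <- do.call(rbind, res)
  res$t_init <- pmin(res$t_init, res$t_peak)
  res$t_term <- pmax(res$t_term, res$t_peak)
  data.frame(index = seq_len(nrow(res)), t_peak = res$t_peak,
             amplitude = res$amplitude, t_init = res$t_init,
             t_term = res$t_term, duration = res$t_term - res$t_init)
}

#' Count pulses in a trace
#'
#' `nrow(detect_pulses(...))`, except that the experimental variant with
#' `fallback_count_one` reports 1 when no point qualifies (the convention
#' used to score worms whose response was a single unresolvable transient).
#' The simulation variant reports a true zero.
#'
#' @inheritParams detect_pulses
#' @return Integer pulse count.
#' @export
count_pulses <- function(trace, criteria = pulse_criteria("experimental")) {
  n <- nrow(detect_pulses(trace, criteria))
  if (n == 0 && criteria$variant == "experimental" &&
      criteria$fallback_count_one) 1L else as.integer(n)
}

#' Interpulse-interval growth
#'
#' Fits \eqn{\log \Delta t_j = \alpha + \beta j} over consecutive
#' peak-to-peak intervals.  Under a linear concentration ramp the model's
#' logarithmic receptor coding predicts `beta > 0`: each successive pulse
#' requires a multiplicatively larger concentration increment, so intervals
#' grow exponentially with pulse index.
#'
#' @param pulses a data.frame from [detect_pulses()] with >= 3 rows.
#' @return A list: `beta` (growth rate per index), `alpha`, `r_squared`,
#'   and `intervals`.
#' @export
interpulse_growth <- function(pulses) {
  if (!is.data.frame(pulses) || nrow(pulses) < 3)
    awa_stop("need at least 3 pulses to fit interval growth",
             "awa_insufficient_data")
  dt <- diff(pulses$t_peak)
  if (any(dt <= 0))
    awa_stop("pulse peaks must be strictly time-ordered",
             "awa_invalid_input")
  j <- seq_along(dt)
  fit <- lm(log(dt) ~ j)
  r2 <- if (length(dt) > 2)
    suppressWarnings(summary(fit)$r.squared) else 1
  list(beta = unname(coef(fit)[2]), alpha = unname(coef(fit)[1]),
       r_squared = r2, intervals = dt)
}

#' Fraction of pulses initiating before a time point
#'
#' Used with the sigmoid-gradient midpoint (the time of maximal first
#' derivative): under first-derivative adaptation, more than 55% of pulses
#' should initiate before it.
#'
#' @param pulses a non-empty data.frame from [detect_pulses()].
#' @param t_mid reference time (s).
#' @return Fraction in `[0, 1]`.
#' @export
fraction_before <- function(pulses, t_mid) {
  if (!is.data.frame(pulses) || nrow(pulses) == 0)
    awa_stop("no pulses supplied", "awa_insufficient_data")
  mean(pulses$t_init < t_mid)
}

#' Fit an exponential decay
#'
#' Nonlinear least-squares fit of \eqn{a e^{-x/\tau} + c} to a trace
#' segment starting at a pulse peak, via Levenberg-Marquardt
#' ([minpack.lm::nlsLM]) with a positivity bound on `tau`.  Segments that
#' do not decay (e.g. monotonically increasing) are rejected.
#'
#' @param t sample times of the segment (s); internally shifted to start
#'   at 0.
#' @param values trace values; >= 5 samples.
#' @return A list of class `awa_decay_fit`: `a`, `tau` (s), `c`, `rss`.
#' @examples
#' x <- seq(0, 30)
#' f <- fit_decay(x, 3 * exp(-x / 5) + 0.2)
#' c(f$a, f$tau, f$c)
#' @export
fit_decay <- function(t, values) {
  if (length(t) < 5 || length(t) != length(values))
    awa_stop("need >= 5 (t, value) samples", "awa_invalid_input")
  if (values[1] <= values[length(values)])
    awa_stop("segment does not decay; refusing to fit", "awa_fit_error")
  x <- t - t[1]
  c0 <- min(values)
  a0 <- values[1] - c0
  drop <- values - c0 <= a0 * exp(-1)
  tau0 <- if (any(drop)) max(x[which(drop)[1]], diff(range(x)) / 20) else
    diff(range(x)) / 2
  fit <- tryCatch(
    minpack.lm::nlsLM(values ~ a * exp(-x / tau) + c,
                      start = list(a = a0, tau = tau0, c = c0),
                      lower = c(a = 0, tau = 1e-9, c = -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      awa_stop(paste0("decay fit failed: ", conditionMessage(e)),
               "awa_fit_error"))
  est <- coef(fit)
  structure(list(a = unname(est["a"]), tau = unname(est["tau"]),
                 c = unname(est["c"]),
                 rss = sum(residuals(fit)^2)),
            class = "awa_decay_fit")
}

#' Habituation metrics for multi-step protocols
#'
#' Measures the response amplitude of each on-step relative to the
#' pre-protocol baseline (the trace level just before the first step) and
#' reports the first-versus-second difference.  A positive difference is
#' habituation: a weaker response to the repeated stimulus.
#'
#' @param trace an `awa_trajectory`, `awa_trace`, or `$t`/`$value` pair.
#' @param protocol the `awa_stimulus` containing >= 2 on-step events (used
#'   to place the measurement windows; each window runs from the step onset
#'   to the next onset or trace end).
#' @return A list: `amplitudes` (per step), `first`, `second`,
#'   `difference` (first - second).
#' @export
habituation_metrics <- function(trace, protocol) {
  stopifnot(inherits(protocol, "awa_stimulus"))
  ev <- protocol$events
  ev <- ev[grepl("^on_step", ev$label), , drop = FALSE]
  if (nrow(ev) < 2)
    awa_stop("protocol must contain at least two on-steps",
             "awa_invalid_input")
  ser <- as_trace_series(trace)
  if (max(ser$t) < ev$end[2])
    awa_stop("trace does not cover the second step window",
             "awa_window_error")
  pre <- ser$v[ser$t < ev$start[1]]
  baseline <- if (length(pre)) pre[length(pre)] else ser$v[1]
  starts <- ev$start
  ends <- c(starts[-1], max(ser$t) + 1)
  amplitudes <- vapply(seq_len(nrow(ev)), function(i) {
    win <- ser$t >= starts[i] & ser$t < ends[i]
    if (!any(win))
      awa_stop("a step window contains no samples", "awa_window_error")
    max(ser$v[win]) - baseline
  }, numeric(1))
  list(amplitudes = amplitudes, first = amplitudes[1],
       second = amplitudes[2],
       difference = amplitudes[1] - amplitudes[2])
}

#' Min-max normalize a trace
#'
#' Affine rescaling `(val - min(val)) / (max(val) - min(val))` to `[0, 1]`,
#' the normalization used for raster displays.
#'
#' @param values numeric series with non-zero range.
#' @return Values rescaled to `[0, 1]`.
#' @export
normalize_trace <- function(values) {
  if (anyNA(values) || any(!is.finite(values)))
    awa_stop("values must be finite", "awa_invalid_input")
  r <- range(values)
  if (r[1] == r[2])
    awa_stop("constant series cannot be min-max normalized",
             "awa_degenerate_normalization")
  (values - r[1]) / (r[2] - r[1])
}

#' Export detected pulses to CSV
#'
#' @param pulses a data.frame from [detect_pulses()].
#' @param path output CSV path.
#' @param trace_id identifier recorded in the first column.
#' @return The path, invisibly.
#' @export
write_pulses_csv <- function(pulses, path, trace_id = "trace") {
  out <- cbind(trace_id = trace_id, pulses)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
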