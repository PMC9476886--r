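#' Stimulus objects
#'
#' A stimulus is a deterministic ligand-concentration protocol L(t) in mM on
#' `[0, duration]` seconds, carrying an event table (ordered, non-overlapping
#' segments with descriptors) used by the habituation analyses to locate
#' step windows.  Evaluate one with [stimulus_level()].
#'
#' @name awa_stimulus
#' @keywords internal
NULL

new_stimulus <- function(duration, events, fun, spec, baseline) {
  if (!is.finite(duration) || duration <= 0)
    awa_stop("duration must be a positive number", "awa_invalid_input")
  if (nrow(events)) {
    if (any(events$start > events$end) || any(events$start < 0) ||
        any(events$end > duration + 1e-9))
      awa_stop("event boundaries must lie within [0, duration]",
               "awa_schedule_error")
    if (is.unsorted(events$start) ||
        any(utils::head(events$end, -1) > events$start[-1] + 1e-9))
      awa_stop("events must be ordered and non-overlapping",
               "awa_schedule_error")
  }
  structure(list(duration = duration, events = events, fun = fun,
                 spec = spec, baseline = baseline),
            class = "awa_stimulus")
}

#' Evaluate a stimulus
#'
#' @param stimulus an `awa_stimulus` object.
#' @param t times in seconds (vectorized); values outside `[0, duration]`
#'   are clamped to the endpoints.
#' @return Ligand concentration(s) in mM.
#' @export
stimulus_level <- function(stimulus, t) {
  stopifnot(inherits(stimulus, "awa_stimulus"))
  t <- pmin(pmax(t, 0), stimulus$duration)
  stimulus$fun(t)
}

#' @export
print.awa_stimulus <- function(x, ...) {
  cat(sprintf("AWA stimulus protocol [%s], duration %.0f s, %d event(s)\n",
              x$spec$type, x$duration, nrow(x$events)))
  if (nrow(x$events)) print(x$events, row.names = FALSE)
  invisible(x)
}

#' Piecewise-constant step protocol
#'
#' Builds an on/off step stimulus: `on_level` inside each scheduled
#' interval, `baseline` elsewhere.  The defaults correspond to the assay
#' concentrations: 1.15 mM diacetyl steps on a 0.12 uM buffer background.
#'
#' @param baseline background concentration (mM).
#' @param on_level step concentration (mM).
#' @param schedule list of `c(start, duration)` pairs (seconds), ordered and
#'   non-overlapping.
#' @param total_duration protocol length (s); defaults to 60 s past the last
#'   step.
#' @return An `awa_stimulus` object.
#' @seealso [two_step_protocol()], [repetitive_steps()] for presets.
#' @examples
#' st <- step_protocol(schedule = list(c(60, 300)))
#' stimulus_level(st, c(30, 200))
#' @export
step_protocol <- function(baseline = 1.2e-4, on_level = 1.15,
                          schedule = list(), total_duration = NULL) {
  if (baseline <= 0 || on_level <= 0)
    awa_stop("levels must be positive", "awa_invalid_input")
  sch <- if (length(schedule))
    do.call(rbind, lapply(schedule, function(s) {
      if (length(s) != 2 || any(!is.finite(s)) || s[2] <= 0 || s[1] < 0)
        awa_stop("schedule entries must be c(start >= 0, duration > 0)",
                 "awa_schedule_error")
      data.frame(start = s[1], end = s[1] + s[2])
    })) else data.frame(start = numeric(), end = numeric())
  if (nrow(sch) > 1 &&
      (is.unsorted(sch$start) || any(utils::head(sch$end, -1) > sch$start[-1])))
    awa_stop("step intervals must be ordered and non-overlapping",
             "awa_schedule_error")
  if (is.null(total_duration))
    total_duration <- if (nrow(sch)) max(sch$end) + 60 else 60
  events <- if (nrow(sch))
    data.frame(start = sch$start, end = sch$end,
               label = paste0("on_step_", seq_len(nrow(sch))),
               level = on_level) else
    data.frame(start = numeric(), end = numeric(),
               label = character(), level = numeric())
  fun <- function(t) {
    L <- rep(baseline, length(t))
    for (i in seq_len(nrow(sch)))
      L[t >= sch$start[i] & t < sch$end[i]] <- on_level
    L
  }
  new_stimulus(total_duration, events, fun,
               spec = list(type = "step_protocol", baseline = baseline,
                           on_level = on_level, schedule = schedule,
                           total_duration = total_duration),
               baseline = baseline)
}

#' Two-step habituation protocols
#'
#' The two paired protocols used to dissect habituation: a first on-step,
#' an off interval, then a short probe step.
#' \describe{
#'   \item{`"long"`}{5 min first step, 2 min off, then the probe — strong
#'     habituation, short recovery.}
#'   \item{`"short"`}{1 min first step, 6 min off, then the probe — weaker
#'     habituation, long recovery.}
#' }
#'
#' @param variant `"long"` or `"short"`.
#' @param baseline,on_level concentrations in mM.
#' @param probe_duration length of the second (probe) step, s.
#' @param t_start onset of the first step, s.
#' @return An `awa_stimulus` object.
#' @export
two_step_protocol <- function(variant = c("long", "short"),
                              baseline = 1.2e-4, on_level = 1.15,
                              probe_duration = 60, t_start = 60) {
  variant <- match.arg(variant)
  first_on <- if (variant == "long") 300 else 60
  off_gap  <- if (variant == "long") 120 else 360
  step_protocol(baseline, on_level,
                schedule = list(c(t_start, first_on),
                                c(t_start + first_on + off_gap,
                                  probe_duration)))
}

#' Repetitive short-step train
#'
#' High-frequency repeated on-steps, the protocol under which the circuit
#' shows periodic skipping: inhibition decays too slowly between steps for
#' every stimulus to elicit a calcium response.
#'
#' @param n_steps number of steps.
#' @param on_duration,off_duration step and gap lengths, s.
#' @param baseline,on_level concentrations in mM.
#' @param t_start onset of the first step, s.
#' @return An `awa_stimulus` object.
#' @export
repetitive_steps <- function(n_steps = 10, on_duration = 30,
                             off_duration = 15, baseline = 1.2e-4,
                             on_level = 1.15, t_start = 60) {
  starts <- t_start + (seq_len(n_steps) - 1) * (on_duration + off_duration)
  step_protocol(baseline, on_level,
                schedule = lapply(starts, function(s) c(s, on_duration)))
}

#' Smooth sigmoidal gradient
#'
#' \deqn{L(t) = base + (peak - base) / (1 + e^{-k (t - t_{mid})})}
#' The first derivative is maximal exactly at `t_mid` (the inflection
#' point), so under first-derivative adaptation most calcium pulses should
#' initiate before `t_mid`.  Defaults span the assay range (0.12 uM to
#' 1.15 mM) over a 20-minute protocol with a rise lasting a few minutes.
#'
#' @param baseline,peak start and saturation concentrations (mM),
#'   `peak > baseline`.
#' @param t_mid inflection time (s), strictly inside `(0, duration)`.
#' @param steepness logistic rate k (1/s, > 0).
#' @param duration protocol length (s).
#' @return An `awa_stimulus` object; the event table records the midpoint.
#' @export
sigmoid_gradient <- function(baseline = 1.2e-4, peak = 1.15,
                             t_mid = 600, steepness = 0.02,
                             duration = 1200) {
  if (peak <= baseline)
    awa_stop("peak must exceed baseline", "awa_invalid_gradient")
  if (steepness <= 0 || t_mid <= 0 || t_mid >= duration)
    awa_stop("need steepness > 0 and 0 < t_mid < duration",
             "awa_invalid_gradient")
  fun <- function(t)
    baseline + (peak - baseline) / (1 + exp(-steepness * (t - t_mid)))
  events <- data.frame(start = t_mid, end = t_mid, label = "midpoint",
                       level = (baseline + peak) / 2)
  new_stimulus(duration, events, fun,
               spec = list(type = "sigmoid_gradient", baseline = baseline,
                           peak = peak, t_mid = t_mid,
                           steepness = steepness, duration = duration),
               baseline = baseline)
}

#' Linear concentration ramp
#'
#' `L(t) = baseline + slope * t`.  Under a linear ramp the model's
#' logarithmic receptor coding makes consecutive interpulse intervals grow
#' exponentially with pulse index, and the first interval scales inversely
#' with the slope.
#'
#' @param baseline starting concentration (mM).
#' @param slope ramp rate (mM/s, >= 0).
#' @param duration protocol length (s).
#' @return An `awa_stimulus` object.
#' @export
linear_ramp <- function(baseline = 1.2e-4, slope = 2e-5, duration = 1200) {
  if (slope < 0) awa_stop("slope must be non-negative", "awa_invalid_input")
  if (!is.finite(duration) || duration <= 0)
    awa_stop("duration must be positive", "awa_invalid_input")
  fun <- function(t) baseline + slope * t
  new_stimulus(duration,
               data.frame(start = 0, end = duration, label = "ramp",
                          level = baseline + slope * duration),
               fun,
               spec = list(type = "linear_ramp", baseline = baseline,
                           slope = slope, duration = duration),
               baseline = baseline)
}

# Sampled forcing table for the compiled solver: dense grid plus duplicated
# points an epsilon on either side of step edges so linear interpolation
# keeps the edges sharp.
stimulus_forcing <- function(stimulus, dt = 0.25, eps = 1e-6) {
  tt <- seq(0, stimulus$duration, by = dt)
  if (tt[length(tt)] < stimulus$duration) tt <- c(tt, stimulus$duration)
  if (identical(stimulus$spec$type, "step_protocol") &&
      nrow(stimulus$events)) {
    edges <- sort(unique(c(stimulus$events$start, stimulus$events$end)))
    edges <- edges[edges > 0 & edges < stimulus$duration]
    tt <- sort(unique(c(tt, edges - eps, edges + eps)))
  }
  cbind(t = tt, L = stimulus_level(stimulus, tt))
}

#' Serialize or sample a stimulus
#'
#' `write_stimulus_yaml()` stores the constructor spec (name and arguments)
#' so `read_stimulus_yaml()` can rebuild the identical protocol;
#' `write_stimulus_csv()` exports the sampled waveform as two-column CSV
#' `(t, L)` for plotting and record keeping.
#'
#' @param stimulus an `awa_stimulus` object.
#' @param path output file path.
#' @param dt sampling interval for the CSV export (s).
#' @return The path, invisibly (writers), or an `awa_stimulus` (reader).
#' @export
write_stimulus_yaml <- function(stimulus, path) {
  stopifnot(inherits(stimulus, "awa_stimulus"))
  yaml::write_yaml(stimulus$spec, path)
  invisible(path)
}

#' @rdname write_stimulus_yaml
#' @export
read_stimulus_yaml <- function(path) {
  stimulus_from_spec(yaml::read_yaml(path))
}

# rebuild a stimulus from its stored constructor spec (shared by the YAML
# reader and the trajectory JSON sidecar reader)
stimulus_from_spec <- function(spec) {
  type <- spec$type
  args <- spec[setdiff(names(spec), "type")]
  builders <- list(step_protocol = step_protocol,
                   sigmoid_gradient = sigmoid_gradient,
                   linear_ramp = linear_ramp)
  if (is.null(builders[[type]]))
    awa_stop(paste0("unknown stimulus type: ", type), "awa_invalid_input")
  if (!is.null(args$schedule)) {
    sch <- args$schedule
    if (is.matrix(sch) || is.data.frame(sch)) {
      sch <- lapply(seq_len(nrow(sch)), function(i) as.numeric(sch[i, ]))
    } else {
      sch <- lapply(sch, function(s) as.numeric(unlist(s)))
    }
    args$schedule <- sch
  }
  do.call(builders[[type]], args)
}

#' @rdname write_stimulus_yaml
#' @export
write_stimulus_csv <- function(stimulus, path, dt = 0.5) {
  stopifnot(inherits(stimulus, "awa_stimulus"))
  tt <- seq(0, stimulus$duration, by = dt)
  write.csv(data.frame(t = tt, L = stimulus_level(stimulus, tt)),
            path, row.names = FALSE)
  invisible(path)
}
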