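#' Noise model for synthetic recordings
#'
#' Measurement noise applied to synthetic fold-change traces:
#' multiplicative noise (per-sample gain jitter), additive noise scaled to
#' the trace's peak fold change, and an optional linear baseline drift.
#' Defaults perturb traces visibly without defeating the experimental
#' 20%/70% pulse detector on model-like signals.
#'
#' @param multiplicative_sd standard deviation of the per-sample gain
#'   factor (dimensionless; 0.02 = 2%).
#' @param additive_sd_frac additive noise SD as a fraction of the trace's
#'   peak fold change.
#' @param drift_slope linear baseline drift (fold-change units per second).
#' @return A list of class `awa_noise`.
#' @export
noise_model <- function(multiplicative_sd = 0.02, additive_sd_frac = 0.01,
                        drift_slope = 0) {
  if (multiplicative_sd < 0 || additive_sd_frac < 0)
    awa_stop("noise scales must be non-negative", "awa_invalid_noise")
  structure(list(multiplicative_sd = multiplicative_sd,
                 additive_sd_frac = additive_sd_frac,
                 drift_slope = drift_slope),
            class = "awa_noise")
}

new_trace <- function(t, values, frame_rate, noise, seed, provenance) {
  structure(list(t = t, values = values, frame_rate = frame_rate,
                 noise = noise, seed = seed, provenance = provenance),
            class = "awa_trace")
}

#' @export
print.awa_trace <- function(x, ...) {
  cat(sprintf(
    "Synthetic GCaMP trace: %d frames at %.1f fps (%.0f s), fold change in [%.3g, %.3g]\n",
    length(x$t), x$frame_rate, max(x$t), min(x$values), max(x$values)))
  invisible(x)
}

#' Synthesize a GCaMP fold-change recording from a trajectory
#'
#' Maps the simulated calcium series to fluorescence fold change
#' \eqn{(F - F_0)/F_0 = g (C - C_0)/C_0} (linear indicator with gain `g`;
#' F0 is the pre-stimulus baseline), samples it at the imaging frame rate,
#' and applies the seeded measurement noise: per-sample multiplicative
#' gain jitter, additive noise scaled to the peak, and optional drift.
#'
#' @param traj an `awa_trajectory`.
#' @param frame_rate imaging rate (frames/s); the assay used 1.4 fps (dual
#'   channel) and 3.3 fps (single channel).
#' @param noise an [noise_model()] object.
#' @param seed integer seed making the noise realization reproducible.
#' @param gain linear fluorescence gain `g`.
#' @return An object of class `awa_trace`: sample times `t`, fold-change
#'   `values`, `frame_rate`, `noise`, `seed` and a `provenance` record.
#' @export
trace_from_trajectory <- function(traj, frame_rate = 1.4,
                                  noise = noise_model(), seed = 1,
                                  gain = 1) {
  stopifnot(inherits(traj, "awa_trajectory"),
            inherits(noise, "awa_noise"))
  if (!is.finite(frame_rate) || frame_rate <= 0)
    awa_stop("frame_rate must be positive", "awa_invalid_input")
  C0 <- traj$params$C0
  tt <- seq(0, max(traj$data$t), by = 1 / frame_rate)
  fc <- gain * (approx(traj$data$t, traj$data$C, xout = tt)$y - C0) / C0
  peak <- max(abs(fc))
  values <- with_seed(seed, {
    v <- fc * (1 + rnorm(length(fc), 0, noise$multiplicative_sd))
    if (peak > 0 && noise$additive_sd_frac > 0)
      v <- v + rnorm(length(fc), 0, noise$additive_sd_frac * peak)
    v + noise$drift_slope * tt
  })
  new_trace(tt, values, frame_rate, noise, seed,
            provenance = list(type = "trajectory",
                              params = traj$params[param_names()],
                              stimulus = traj$stimulus$spec,
                              gain = gain))
}

#' Simulate a cohort of individuals
#'
#' Emulates across-animal variability: `n` parameter sets are drawn
#' log-uniformly within `jitter_fold` of the base set (each constant in
#' `[x/sqrt(j), x*sqrt(j)]`), each individual is simulated once under the
#' protocol, and converted to a noisy fold-change trace.  Repeated
#' recordings of one individual would reuse its parameter draw — the
#' within-animal variability is measurement noise only, matching the low
#' in-worm / high between-worm variability of the recordings.
#'
#' @param base an [model_params()] object.
#' @param jitter_fold total multiplicative jitter range per parameter
#'   (>= 1; 1 = identical individuals).
#' @param n cohort size.
#' @param protocol an `awa_stimulus`.
#' @param frame_rate imaging rate (frames/s).
#' @param seed integer seed (drives both parameter draws and noise).
#' @param noise an [noise_model()] object.
#' @param vary which parameters receive jitter (default: all model
#'   constants except the structural guards).
#' @return A list of `n` `awa_trace` objects; each records its drawn
#'   parameter set in `provenance`.
#' @export
cohort <- function(base, jitter_fold = 1.5, n = 8,
                   protocol = criterion_gradient_stimulus(),
                   frame_rate = 1.4, seed = 1, noise = noise_model(),
                   vary = setdiff(scannable_params(), "Rt")) {
  validate_params(base)
  if (n < 1) awa_stop("n must be >= 1", "awa_invalid_input")
  if (jitter_fold < 1)
    awa_stop("jitter_fold must be >= 1", "awa_invalid_input")
  half <- log(sqrt(jitter_fold))
  draws <- with_seed(seed, {
    matrix(exp(runif(n * length(vary), -half, half)), nrow = n,
           dimnames = list(NULL, vary))
  })
  lapply(seq_len(n), function(i) {
    p <- base
    for (pn in vary) p[[pn]] <- base[[pn]] * unname(draws[i, pn])
    traj <- simulate_model(p, protocol)
    tr <- trace_from_trajectory(traj, frame_rate = frame_rate,
                                noise = noise, seed = seed + i)
    tr$provenance$individual <- i
    tr$provenance$multipliers <- draws[i, ]
    tr
  })
}

#' Ground-truth pulse fixtures
#'
#' Builds a trace as a sum of well-separated smooth (Gaussian) bumps on a
#' zero baseline, with the generating pulse list stored in `provenance` —
#' ground truth for testing the detectors.
#'
#' @param spec a data.frame (or list of rows) with columns `t_peak`,
#'   `amplitude`, `width` (Gaussian SD, s).  Consecutive bumps must be
#'   separated by more than 3 times the sum of their widths so they are
#'   resolvable.
#' @param duration trace length (s).
#' @param frame_rate sampling rate (frames/s).
#' @param noise optional [noise_model()]; `NULL` for a clean fixture.
#' @param seed integer seed for the noise.
#' @return An `awa_trace`; `provenance$truth` holds the generating spec.
#' @export
fixture_pulses <- function(spec, duration = 120, frame_rate = 3.3,
                           noise = NULL, seed = 1) {
  spec <- as.data.frame(spec)
  if (nrow(spec)) {
    need <- c("t_peak", "amplitude", "width")
    if (!all(need %in% names(spec)))
      awa_stop("spec needs columns t_peak, amplitude, width",
               "awa_fixture_error")
    spec <- spec[order(spec$t_peak), , drop = FALSE]
    if (any(spec$amplitude <= 0) || any(spec$width <= 0))
      awa_stop("amplitudes and widths must be positive",
               "awa_fixture_error")
    if (nrow(spec) > 1) {
      gaps <- diff(spec$t_peak)
      wsum <- spec$width[-nrow(spec)] + spec$width[-1]
      if (any(gaps <= 3 * wsum))
        awa_stop("bumps overlap: peaks must be separated by > 3x the sum of their widths",
                 "awa_fixture_error")
    }
  }
  tt <- seq(0, duration, by = 1 / frame_rate)
  v <- rep(0, length(tt))
  for (i in seq_len(nrow(spec)))
    v <- v + spec$amplitude[i] *
      exp(-(tt - spec$t_peak[i])^2 / (2 * spec$width[i]^2))
  if (!is.null(noise)) {
    stopifnot(inherits(noise, "awa_noise"))
    peak <- max(abs(v), 1)
    v <- with_seed(seed, {
      out <- v * (1 + rnorm(length(v), 0, noise$multiplicative_sd))
      if (noise$additive_sd_frac > 0)
        out <- out + rnorm(length(v), 0, noise$additive_sd_frac * peak)
      out + noise$drift_slope * tt
    })
  }
  new_trace(tt, v, frame_rate, noise, seed,
            provenance = list(type = "fixture", truth = spec))
}

#' Write or read a synthetic trace
#'
#' Two-column CSV `(t, fold_change)` plus a JSON sidecar with the frame
#' rate, seed, noise model and provenance — the same format the pulse
#' analyses consume.
#'
#' @param trace an `awa_trace`.
#' @param prefix path prefix; `<prefix>.csv` and `<prefix>.json` are
#'   written.
#' @return The prefix, invisibly (writer); an `awa_trace` (reader).
#' @export
write_trace <- function(trace, prefix) {
  stopifnot(inherits(trace, "awa_trace"))
  write.csv(data.frame(t = trace$t, fold_change = trace$values),
            paste0(prefix, ".csv"), row.names = FALSE)
  jsonlite::write_json(
    list(frame_rate = trace$frame_rate, seed = trace$seed,
         noise = if (is.null(trace$noise)) NULL else unclass(trace$noise),
         provenance = trace$provenance),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(prefix)
}

#' @rdname write_trace
#' @export
read_trace <- function(prefix) {
  d <- read.csv(paste0(prefix, ".csv"))
  side <- jsonlite::read_json(paste0(prefix, ".json"),
                              simplifyVector = TRUE)
  noise <- if (!is.null(side$noise))
    do.call(noise_model, side$noise) else NULL
  new_trace(d$t, d$fold_change, side$frame_rate, noise, side$seed,
            side$provenance)
}
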