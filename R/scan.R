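#' Canonical criterion protocols
#'
#' The two stimulus protocols against which every parameter set in the
#' robustness study is scored: a single 1.15 mM step (60 s background,
#' 300 s on, 60 s off) and the standard 20-minute sigmoidal gradient from
#' the 0.12 uM background to 1.15 mM with its inflection at 600 s.
#'
#' @param on_level step concentration / gradient peak (mM).
#' @param baseline background concentration (mM).
#' @return An `awa_stimulus` object.
#' @export
criterion_step_stimulus <- function(on_level = 1.15, baseline = 1.2e-4) {
  step_protocol(baseline, on_level, schedule = list(c(60, 300)),
                total_duration = 420)
}

#' @rdname criterion_step_stimulus
#' @param peak gradient saturation level (mM).
#' @export
criterion_gradient_stimulus <- function(peak = 1.15, baseline = 1.2e-4) {
  sigmoid_gradient(baseline, peak, t_mid = 600, steepness = 0.02,
                   duration = 1200)
}

# simulation-variant criteria with an absolute floor tied to baseline
# calcium, so numerically flat traces carry no pulses
scan_criteria <- function(params) {
  pulse_criteria("simulation", range_floor = 0.02 * params$C0)
}

#' Step-response pass criterion
#'
#' A parameter set passes the step feature when the single-step protocol
#' elicits exactly one detected pulse (simulation criteria) whose duration
#' is shorter than 60 s — i.e. a transient response with exact adaptation.
#'
#' @param trajectory an `awa_trajectory` simulated under a single-step
#'   protocol (see [criterion_step_stimulus()]).
#' @return Logical; attributes `n_pulses` and `duration` carry the
#'   measured values.
#' @export
passes_step_criterion <- function(trajectory) {
  stopifnot(inherits(trajectory, "awa_trajectory"))
  if (!identical(trajectory$stimulus$spec$type, "step_protocol") ||
      nrow(trajectory$stimulus$events) != 1)
    awa_stop("trajectory was not simulated under a single-step protocol",
             "awa_protocol_mismatch")
  pulses <- detect_pulses(trajectory, scan_criteria(trajectory$params))
  ok <- nrow(pulses) == 1 && pulses$duration[1] < 60
  structure(ok, n_pulses = nrow(pulses),
            duration = if (nrow(pulses)) pulses$duration[1] else NA_real_)
}

#' Gradient-response pass criterion
#'
#' A parameter set passes the gradient feature when the sigmoidal gradient
#' elicits between 3 and 100 pulses with more than 55% of them initiating
#' before the gradient midpoint (the point of maximal first derivative) —
#' pulsatile activity that adapts to the gradient's first derivative.
#'
#' @param trajectory an `awa_trajectory` simulated under a sigmoid
#'   gradient.
#' @param t_mid gradient midpoint (s); defaults to the one recorded in the
#'   stimulus.
#' @return Logical; attributes `n_pulses` and `fraction_before` carry the
#'   measured values.
#' @export
passes_gradient_criterion <- function(trajectory, t_mid = NULL) {
  stopifnot(inherits(trajectory, "awa_trajectory"))
  if (!identical(trajectory$stimulus$spec$type, "sigmoid_gradient"))
    awa_stop("trajectory was not simulated under a sigmoid gradient",
             "awa_protocol_mismatch")
  if (is.null(t_mid)) t_mid <- trajectory$stimulus$spec$t_mid
  pulses <- detect_pulses(trajectory, scan_criteria(trajectory$params))
  frac <- if (nrow(pulses)) mean(pulses$t_init < t_mid) else NA_real_
  ok <- nrow(pulses) >= 3 && nrow(pulses) <= 100 &&
    !is.na(frac) && frac > 0.55
  structure(ok, n_pulses = nrow(pulses), fraction_before = frac)
}

# evaluate both criteria for one parameter set; never short-circuits so
# per-criterion rates are reportable
evaluate_criteria <- function(params, step_stim = criterion_step_stimulus(),
                              grad_stim = criterion_gradient_stimulus(),
                              sample_dt = 0.1) {
  safe <- function(expr) tryCatch(expr, error = function(e) NULL)
  step_traj <- safe(simulate_model(params, step_stim,
                                   sample_dt = sample_dt))
  grad_traj <- safe(simulate_model(params, grad_stim,
                                   sample_dt = sample_dt))
  step_pass <- if (is.null(step_traj)) FALSE else
    as.logical(passes_step_criterion(step_traj))
  grad_pass <- if (is.null(grad_traj)) FALSE else
    as.logical(passes_gradient_criterion(grad_traj))
  list(step_pass = step_pass, gradient_pass = grad_pass)
}

scannable_params <- function() {
  c("k1", "k2", "k3", "k4", "k5", "k6", "L0", "Rt", "tau_c", "tau_I", "C0")
}

#' One-at-a-time parameter sweep
#'
#' Varies each model parameter independently over a log-spaced grid of
#' multipliers (default 0.1- to 10-fold of its calibrated value, a 100-fold
#' range in total) and scores the step and gradient criteria at each point.
#' Multipliers that would push `Rt` out of (0, 1) or `k5` is zero are
#' recorded with `NA` passes.
#'
#' @param base an [model_params()] object (the calibrated set).
#' @param fold_range length-2 multiplier range, e.g. `c(0.1, 10)`.
#' @param n_points grid points per parameter (log-spaced).
#' @param parameters which parameters to sweep (default: all model
#'   constants).
#' @return An object of class `awa_scan`: `results` is a data.frame with
#'   one row per (parameter, multiplier), with `step_pass` and
#'   `gradient_pass` flags.
#' @export
scan_one_at_a_time <- function(base, fold_range = c(0.1, 10), n_points = 9,
                               parameters = scannable_params()) {
  validate_params(base)
  if (length(fold_range) != 2 || any(fold_range <= 0) ||
      fold_range[1] >= fold_range[2])
    awa_stop("fold_range must be an increasing pair of positive multipliers",
             "awa_invalid_range")
  if (n_points < 2)
    awa_stop("need at least 2 grid points", "awa_invalid_range")
  bad <- setdiff(parameters, scannable_params())
  if (length(bad))
    awa_stop(paste0("unknown parameter(s): ", paste(bad, collapse = ", ")),
             "awa_config_error")
  mult <- exp(seq(log(fold_range[1]), log(fold_range[2]),
                  length.out = n_points))
  rows <- list()
  for (pn in parameters) {
    for (m in mult) {
      p <- base
      p[[pn]] <- base[[pn]] * m
      valid <- !inherits(try(validate_params(p), silent = TRUE),
                         "try-error") && p[[pn]] > 0
      if (pn == "Rt") valid <- valid && p$Rt > 0 && p$Rt < 1
      if (valid) {
        ev <- evaluate_criteria(p)
        rows[[length(rows) + 1]] <- data.frame(
          parameter = pn, multiplier = m,
          step_pass = ev$step_pass, gradient_pass = ev$gradient_pass)
      } else {
        rows[[length(rows) + 1]] <- data.frame(
          parameter = pn, multiplier = m,
          step_pass = NA, gradient_pass = NA)
      }
    }
  }
  results <- do.call(rbind, rows)
  both <- results$step_pass & results$gradient_pass
  structure(list(mode = "one_at_a_time", results = results,
                 pass_fraction = mean(both, na.rm = TRUE),
                 config = list(fold_range = fold_range,
                               n_points = n_points,
                               parameters = parameters)),
            class = "awa_scan")
}

#' Joint log-uniform robustness scan
#'
#' Draws `n_sets` parameter sets with every included constant sampled
#' independently from a log-uniform distribution over a symmetric
#' `fold_range`-fold interval around its calibrated value
#' (`[x/sqrt(f), x*sqrt(f)]`, total ratio `f`), holding `Rt` fixed (its
#' usable dynamic range is comparatively small).  Each set is scored
#' against both response criteria; the pass fraction is the share of sets
#' passing both.
#'
#' @param base an [model_params()] object.
#' @param fold_range total multiplicative range (default 10).
#' @param n_sets number of random parameter sets.
#' @param seed integer seed; the scan is fully reproducible from it.
#' @param exclude parameter names held fixed (default `"Rt"`).
#' @return An `awa_scan` object: `results` has one row per set with the
#'   multipliers and pass flags; `pass_fraction` is
#'   `mean(step_pass & gradient_pass)`.
#' @export
scan_joint <- function(base, fold_range = 10, n_sets = 1000, seed = 1,
                       exclude = "Rt") {
  validate_params(base)
  if (fold_range < 1)
    awa_stop("fold_range must be >= 1", "awa_invalid_range")
  if (n_sets < 1)
    awa_stop("n_sets must be >= 1", "awa_invalid_range")
  bad <- setdiff(exclude, scannable_params())
  if (length(bad))
    awa_stop(paste0("unknown excluded parameter(s): ",
                    paste(bad, collapse = ", ")), "awa_config_error")
  varied <- setdiff(scannable_params(), exclude)
  half <- log(sqrt(fold_range))
  draws <- with_seed(seed, {
    m <- matrix(exp(runif(n_sets * length(varied), -half, half)),
                nrow = n_sets)
    colnames(m) <- varied
    m
  })
  step_stim <- criterion_step_stimulus()
  grad_stim <- criterion_gradient_stimulus()
  step_pass <- logical(n_sets)
  grad_pass <- logical(n_sets)
  for (i in seq_len(n_sets)) {
    p <- base
    for (pn in varied) p[[pn]] <- base[[pn]] * unname(draws[i, pn])
    ev <- evaluate_criteria(p, step_stim, grad_stim)
    step_pass[i] <- ev$step_pass
    grad_pass[i] <- ev$gradient_pass
  }
  results <- data.frame(draws, step_pass = step_pass,
                        gradient_pass = grad_pass)
  structure(list(mode = "joint", results = results,
                 pass_fraction = mean(step_pass & grad_pass),
                 step_pass_fraction = mean(step_pass),
                 gradient_pass_fraction = mean(grad_pass),
                 seed = seed,
                 config = list(fold_range = fold_range, n_sets = n_sets,
                               exclude = exclude)),
            class = "awa_scan")
}

#' Stimulus-amplitude robustness sweep
#'
#' Re-runs both criterion protocols with only the stimulus amplitude
#' changed (step level and gradient peak), all model parameters fixed.
#' The circuit's logarithmic front end makes both features hold across
#' more than four orders of magnitude of stimulus concentration.
#'
#' @param params an [model_params()] object.
#' @param amplitudes stimulus concentrations to test (mM); default a
#'   log-spaced grid spanning 10,000-fold around the 1.15 mM assay level.
#' @param baseline background concentration (mM); every amplitude must
#'   exceed it.
#' @return An `awa_scan` object; `results` has one row per amplitude.
#' @export
scan_stimulus_amplitude <- function(params,
                                    amplitudes = 1.15 * 10^seq(-2, 2),
                                    baseline = 1.2e-4) {
  validate_params(params)
  if (any(!is.finite(amplitudes)) || any(amplitudes <= baseline))
    awa_stop("amplitudes must exceed the baseline", "awa_invalid_input")
  rows <- lapply(amplitudes, function(amp) {
    ev <- evaluate_criteria(params,
                            criterion_step_stimulus(on_level = amp,
                                                    baseline = baseline),
                            criterion_gradient_stimulus(peak = amp,
                                                        baseline = baseline))
    data.frame(amplitude = amp, step_pass = ev$step_pass,
               gradient_pass = ev$gradient_pass)
  })
  results <- do.call(rbind, rows)
  structure(list(mode = "amplitude", results = results,
                 pass_fraction = mean(results$step_pass &
                                        results$gradient_pass),
                 config = list(amplitudes = amplitudes,
                               baseline = baseline)),
            class = "awa_scan")
}

#' @export
print.awa_scan <- function(x, ...) {
  cat(sprintf("AWA robustness scan (%s): %d evaluation(s), pass fraction %.3f\n",
              x$mode, nrow(x$results), x$pass_fraction))
  invisible(x)
}

#' Write scan results
#'
#' One CSV row per evaluated set plus a JSON summary (mode, configuration,
#' pass fractions, seed).
#'
#' @param scan an `awa_scan` object.
#' @param prefix path prefix; `<prefix>.csv` and `<prefix>.json` are
#'   written.
#' @return The prefix, invisibly.
#' @export
write_scan <- function(scan, prefix) {
  stopifnot(inherits(scan, "awa_scan"))
  write.csv(scan$results, paste0(prefix, ".csv"), row.names = FALSE)
  summary <- list(mode = scan$mode, pass_fraction = scan$pass_fraction,
                  step_pass_fraction = scan$step_pass_fraction,
                  gradient_pass_fraction = scan$gradient_pass_fraction,
                  seed = scan$seed, config = scan$config)
  jsonlite::write_json(summary[!vapply(summary, is.null, logical(1))],
                       paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(prefix)
}
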