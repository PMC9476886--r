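#' Equilibrate the circuit under a constant background
#'
#' Finds the resting state under a constant ligand level: the switch sits at
#' its floor, calcium at `C0` plus the negligible floor leak, and inhibition
#' at the level where production by the active receptors balances removal
#' (cf. [steady_state_inhibition()]).  A closed-form/root-finding guess is
#' refined by simulating under the constant background until the largest
#' absolute state derivative falls below `tol`.
#'
#' @param params an [model_params()] object.
#' @param baseline constant ligand concentration (mM, >= `L_min`).
#' @param tol derivative tolerance for convergence (per second).
#' @param t_max simulated time cap before giving up (s).
#' @return A named state vector `c(S, C, I)` (see [model_state()]).
#' @export
equilibrate <- function(params, baseline, tol = 1e-7, t_max = 2e4) {
  validate_params(params)
  if (!is.finite(baseline) || baseline < params$L_min)
    awa_stop("baseline must be a number >= L_min", "awa_invalid_input")
  C_eq <- params$C0 + params$k4 * params$tau_c * params$S_floor
  resid <- function(I) {
    Ra <- receptor_activity(baseline, I, params)
    params$k5 * (C_eq - params$C0) * Ra + params$k6 * Ra -
      (1 - Ra) * I / params$tau_I
  }
  hi <- 1
  while (resid(hi) > 0 && hi < 1e12) hi <- hi * 2
  I_eq <- uniroot(resid, c(0, hi), tol = 1e-12)$root
  state <- c(S = params$S_floor, C = C_eq, I = I_eq)

  const <- step_protocol(baseline = baseline, on_level = baseline,
                         schedule = list(), total_duration = 1000)
  elapsed <- 0
  repeat {
    d <- state_derivative(state, baseline, params)
    if (max(abs(d)) < tol) return(state)
    if (elapsed >= t_max)
      awa_stop(sprintf(
        "equilibration did not converge within %g s (residual derivatives S=%.3g C=%.3g I=%.3g)",
        t_max, d[["S"]], d[["C"]], d[["I"]]), "awa_equilibration_error")
    traj <- simulate_model(params, const, init_state = state,
                           sample_dt = 10)
    n <- nrow(traj$data)
    state <- c(S = traj$data$S[n], C = traj$data$C[n], I = traj$data$I[n])
    elapsed <- elapsed + const$duration
  }
}

#' Simulate the feedback model against a stimulus
#'
#' Integrates the three-variable circuit from its equilibrated resting
#' state with an adaptive stiff-capable solver (lsoda, compiled
#' right-hand side).  The maximum internal step is capped (default 0.5 s)
#' so the rapid switch-like channel transitions are never stepped over, and
#' output is returned on a uniform grid by the solver's dense interpolation.
#'
#' @param params an [model_params()] object.
#' @param stimulus an `awa_stimulus` object.
#' @param sample_dt output sampling interval (s).
#' @param rtol,atol relative/absolute solver tolerances.
#' @param hmax maximum internal step (s).
#' @param method a `deSolve` integration method (default `"lsoda"`).
#' @param forcing_dt sampling interval of the ligand forcing table (s);
#'   step edges are additionally sharpened with bracketing points.
#' @param init_state optional starting state `c(S, C, I)`; defaults to
#'   [equilibrate()] at `L(0)`.
#' @return An object of class `awa_trajectory`: a list with `data`
#'   (data.frame `t, L, Ra, S, C, I`), `stimulus`, `params`, and `meta`
#'   (solver settings).
#' @examples
#' \donttest{
#' traj <- simulate_model(model_params(), step_protocol(
#'   schedule = list(c(60, 300))))
#' range(traj$data$C)
#' }
#' @export
simulate_model <- function(params, stimulus, sample_dt = 0.1,
                           rtol = 1e-6, atol = 1e-9, hmax = 0.5,
                           method = "lsoda", forcing_dt = 0.25,
                           init_state = NULL) {
  validate_params(params)
  stopifnot(inherits(stimulus, "awa_stimulus"))
  y0 <- if (is.null(init_state))
    equilibrate(params, max(stimulus_level(stimulus, 0), params$L_min))
  else model_state(init_state[["S"]], init_state[["C"]], init_state[["I"]],
                   params)
  times <- seq(0, stimulus$duration, by = sample_dt)
  if (times[length(times)] < stimulus$duration)
    times <- c(times, stimulus$duration)
  forc <- stimulus_forcing(stimulus, dt = forcing_dt)
  out <- deSolve::ode(
    y = y0, times = times, func = "awa_deriv",
    parms = unlist(params[param_names()]),
    dllname = "awapulse", initfunc = "awa_init", initforc = "awa_forc",
    forcings = forc, fcontrol = list(method = "linear", rule = 2),
    nout = 1, outnames = "Ra",
    rtol = rtol, atol = atol, hmax = hmax, method = method,
      maxsteps = 50000)
  if (nrow(out) < length(times))
    awa_stop(sprintf("integration failed at t = %.3f s",
                     out[nrow(out), "time"]), "awa_integration_error")
  build_trajectory(out, stimulus, params,
                   meta = list(sample_dt = sample_dt, rtol = rtol,
                               atol = atol, hmax = hmax, method = method,
                               forcing_dt = forcing_dt))
}

build_trajectory <- function(out, stimulus, params, meta) {
  tt <- out[, "time"]
  S <- out[, "S"]; C <- out[, "C"]; I <- out[, "I"]
  slack <- 1e-3
  if (any(S < params$S_floor - slack) || any(S > 1 + slack) ||
      any(C < -slack) || any(I < -slack))
    awa_stop("solver output violates state bounds",
             "awa_internal_consistency_error")
  S <- pmin(pmax(S, params$S_floor), 1)
  C <- pmax(C, 0)
  I <- pmax(I, 0)
  L <- stimulus_level(stimulus, tt)
  data <- data.frame(t = tt, L = L,
                     Ra = receptor_activity(L, I, params),
                     S = S, C = C, I = I)
  structure(list(data = data, stimulus = stimulus, params = params,
                 meta = meta),
            class = "awa_trajectory")
}

#' @export
print.awa_trajectory <- function(x, ...) {
  d <- x$data
  cat(sprintf(
    "AWA trajectory: %d samples over %.0f s; C in [%.4g, %.4g]%s\n",
    nrow(d), max(d$t), min(d$C), max(d$C),
    if ("V" %in% names(d)) " (detailed model, with V)" else ""))
  invisible(x)
}

#' Fixed-step reference integration
#'
#' Integrates the same compiled right-hand side with a classical
#' fixed-step fourth-order Runge-Kutta scheme.  Used as an independent
#' integration cross-check for the adaptive solver (at e.g. 1 ms steps);
#' far slower than [simulate_model()] and not meant for production runs.
#'
#' @inheritParams simulate_model
#' @param dt fixed integration step (s).
#' @param thin keep every `thin`-th sample in the returned trajectory.
#' @return An `awa_trajectory` object.
#' @export
simulate_fixed_step <- function(params, stimulus, dt = 0.001, thin = 100,
                                forcing_dt = 0.25, init_state = NULL) {
  validate_params(params)
  stopifnot(inherits(stimulus, "awa_stimulus"))
  y0 <- if (is.null(init_state))
    equilibrate(params, max(stimulus_level(stimulus, 0), params$L_min))
  else init_state
  times <- seq(0, stimulus$duration, by = dt)
  forc <- stimulus_forcing(stimulus, dt = forcing_dt)
  out <- deSolve::ode(
    y = y0, times = times, func = "awa_deriv",
    parms = unlist(params[param_names()]),
    dllname = "awapulse", initfunc = "awa_init", initforc = "awa_forc",
    forcings = forc, fcontrol = list(method = "linear", rule = 2),
    nout = 1, outnames = "Ra", method = "rk4")
  keep <- unique(c(seq(1, nrow(out), by = thin), nrow(out)))
  out <- out[keep, , drop = FALSE]
  # project recorded states onto the bounds: the fixed-step scheme has no
  # error control, so the switch can overshoot its clamp between steps
  # (the compiled right-hand side already evaluates with clamped states)
  out[, "S"] <- pmin(pmax(out[, "S"], params$S_floor), 1)
  out[, "C"] <- pmax(out[, "C"], 0)
  out[, "I"] <- pmax(out[, "I"], 0)
  build_trajectory(out, stimulus, params,
                   meta = list(method = "rk4", dt = dt, thin = thin))
}

#' Membrane module parameters
#'
#' Parameters of the minimal two-conductance membrane extension used by
#' [simulate_detailed()]: a TRPV-like drive conductance proportional to the
#' switch S, a voltage-gated calcium conductance with sigmoidal
#' instantaneous activation, a delayed-rectifier potassium conductance and
#' a leak.  Units are nominal (mV, conductances relative to unit
#' capacitance); values were chosen to give a second-scale upstroke and
#' tens-of-seconds calcium decay.
#'
#' @param Cm membrane capacitance (nominal units).
#' @param gS,ES TRPV-like drive conductance and reversal (mV).
#' @param gCa,ECa voltage-gated calcium conductance and reversal (mV).
#' @param Vm_half,km half-activation voltage (mV) and slope (mV) of the
#'   calcium conductance.
#' @param gK,EK delayed-rectifier conductance and reversal (mV).
#' @param Vn_half,kn half-activation and slope of the potassium gate (mV).
#' @param tau_n potassium gate time constant (s).
#' @param gL,EL leak conductance and reversal (mV).
#' @param w weight of the voltage-gated pathway in the calcium influx term
#'   (0 recovers the abstract switch of the simple model exactly).
#' @return A named list of class `awa_membrane`.
#' @export
membrane_params <- function(Cm = 1, gS = 2, ES = 60,
                            gCa = 1, ECa = 120, Vm_half = -25, km = 6,
                            gK = 2, EK = -80, Vn_half = -25, kn = 5,
                            tau_n = 2, gL = 0.5, EL = -65, w = 1) {
  m <- list(Cm = Cm, gS = gS, ES = ES, gCa = gCa, ECa = ECa,
            Vm_half = Vm_half, km = km, gK = gK, EK = EK,
            Vn_half = Vn_half, kn = kn, tau_n = tau_n,
            gL = gL, EL = EL, w = w)
  if (any(!vapply(m, is.finite, logical(1))))
    awa_stop("membrane parameters must be finite", "awa_invalid_parameter")
  if (m$Cm <= 0 || m$tau_n <= 0 || m$gL < 0 || m$w < 0 || m$w > 1)
    awa_stop("need Cm > 0, tau_n > 0, gL >= 0 and w in [0, 1]",
             "awa_invalid_parameter")
  structure(m, class = "awa_membrane")
}

membrane_names <- function() {
  c("Cm", "gS", "ES", "gCa", "ECa", "Vm_half", "km", "gK", "EK",
    "Vn_half", "kn", "tau_n", "gL", "EL", "w")
}

#' Simulate the detailed model with a membrane-potential module
#'
#' Extends the circuit with a minimal conductance-based voltage module: the
#' switch S depolarizes the membrane through a TRPV-like drive, a
#' voltage-gated calcium conductance then carries the dominant calcium
#' influx, and a delayed-rectifier potassium conductance and leak
#' repolarize.  Receptor activity and the inhibition balance are unchanged.
#' With `w = 0` (membrane decoupled from the calcium influx) and the drive
#' disabled the calcium dynamics reduce to [simulate_model()].
#'
#' @inheritParams simulate_model
#' @param membrane an [membrane_params()] object.
#' @param settle_time baseline pre-run used to settle the membrane states
#'   before the protocol starts (s).
#' @return An `awa_trajectory` whose `data` additionally carries `V` (mV)
#'   and the potassium gate `n`.
#' @export
simulate_detailed <- function(params, membrane = membrane_params(),
                              stimulus, sample_dt = 0.1,
                              rtol = 1e-6, atol = 1e-9, hmax = 0.5,
                              method = "lsoda", forcing_dt = 0.25,
                              settle_time = 300) {
  validate_params(params)
  stopifnot(inherits(membrane, "awa_membrane"),
            inherits(stimulus, "awa_stimulus"))
  base <- equilibrate(params, max(stimulus_level(stimulus, 0),
                                  params$L_min))
  ninf0 <- 1 / (1 + exp(-(membrane$EL - membrane$Vn_half) / membrane$kn))
  y0 <- c(base, V = membrane$EL, n = ninf0)
  parms <- c(unlist(params[param_names()]),
             unlist(membrane[membrane_names()]))
  run <- function(y0, stim) {
    times <- seq(0, stim$duration, by = sample_dt)
    forc <- stimulus_forcing(stim, dt = forcing_dt)
    out <- deSolve::ode(
      y = y0, times = times, func = "awa_det_deriv", parms = parms,
      dllname = "awapulse", initfunc = "awa_det_init",
      initforc = "awa_det_forc",
      forcings = forc, fcontrol = list(method = "linear", rule = 2),
      nout = 1, outnames = "Ra",
      rtol = rtol, atol = atol, hmax = hmax, method = method,
      maxsteps = 50000)
    if (nrow(out) < length(times))
      awa_stop(sprintf("integration failed at t = %.3f s",
                       out[nrow(out), "time"]), "awa_integration_error")
    out
  }
  if (settle_time > 0) {
    pre <- run(y0, step_protocol(baseline = stimulus$baseline,
                                 on_level = stimulus$baseline,
                                 total_duration = settle_time))
    y0 <- pre[nrow(pre), c("S", "C", "I", "V", "n")]
  }
  out <- run(y0, stimulus)
  traj <- build_trajectory(out, stimulus, params,
                           meta = list(sample_dt = sample_dt, rtol = rtol,
                                       atol = atol, hmax = hmax,
                                       method = method,
                                       membrane = unclass(membrane)))
  traj$data$V <- out[, "V"]
  traj$data$n <- out[, "n"]
  traj
}

#' Write or read a trajectory
#'
#' Writes the time courses as tidy CSV (`t, L, Ra, S, C, I[, V, n]`) plus a
#' JSON sidecar with the parameter set, stimulus spec and solver settings.
#'
#' @param traj an `awa_trajectory` object.
#' @param prefix path prefix; `<prefix>.csv` and `<prefix>.json` are
#'   written.
#' @return The prefix, invisibly (writer); an `awa_trajectory` (reader;
#'   its stimulus is rebuilt from the stored spec).
#' @export
write_trajectory <- function(traj, prefix) {
  stopifnot(inherits(traj, "awa_trajectory"))
  write.csv(traj$data, paste0(prefix, ".csv"), row.names = FALSE)
  sidecar <- list(params = traj$params[param_names()],
                  stimulus = traj$stimulus$spec, meta = traj$meta)
  jsonlite::write_json(sidecar, paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(prefix)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(prefix) {
  data <- read.csv(paste0(prefix, ".csv"))
  side <- jsonlite::read_json(paste0(prefix, ".json"),
                              simplifyVector = TRUE)
  params <- do.call(model_params, lapply(side$params, as.numeric))
  stimulus <- stimulus_from_spec(side$stimulus)
  structure(list(data = data, stimulus = stimulus, params = params,
                 meta = side$meta),
            class = "awa_trajectory")
}
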