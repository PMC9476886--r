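#' Model parameters for the AWA negative-feedback circuit
#'
#' Constructs the full parameter set of the four-variable GPCR -> calcium
#' model.  Receptor activity is a logistic function of log ligand
#' concentration (gain `k1`) shifted by the lumped inhibition level I
#' (coupling `k2`).  A self-amplifying channel switch S opens when the
#' active-receptor fraction Ra crosses the threshold `Rt` (rate `k3`) and
#' drives calcium influx (`k4`); calcium is removed back to its baseline
#' `C0` with time constant `tau_c`.  Inhibition accumulates through a
#' calcium-dependent pathway (`k5`, calcineurin-like) and a
#' calcium-independent pathway (`k6`), and is removed in proportion to the
#' inactive-receptor fraction with time constant `tau_I` — an integral
#' feedback that yields exact adaptation.
#'
#' The defaults are a calibrated wild-type set (the package's reference
#' regime, see the methods vignette): a 1.15 mM diacetyl step on the
#' 0.12 uM buffer background elicits a single calcium pulse shorter than
#' 60 s with exact adaptation, and the standard sigmoidal gradient elicits
#' pulsatile activity concentrated before the gradient midpoint.
#'
#' @param k1 receptor log-sensitivity gain (dimensionless, > 0).
#' @param k2 inhibition coupling (per inhibition unit, > 0).
#' @param k3 channel self-amplification rate (1/s, > 0).
#' @param k4 calcium influx rate per open-channel fraction
#'   (concentration units/s, > 0).
#' @param k5 calcium-dependent inhibition rate
#'   (1/(concentration units * s), >= 0; 0 models the tax-6 mutant).
#' @param k6 calcium-independent inhibition rate (inhibition units/s, > 0).
#' @param L0 reference ligand concentration (mM, > 0); Ra = 1/2 at
#'   L = L0 when I = 0.
#' @param Rt channel-opening threshold on the active-receptor fraction,
#'   strictly inside (0, 1).
#' @param tau_c calcium removal time constant (s, > 0).
#' @param tau_I inhibition removal time constant (s, > 0).
#' @param C0 baseline calcium concentration (concentration units, > 0).
#' @param S_floor lower clamp on the open-channel fraction (> 0); keeps the
#'   multiplicative switch re-triggerable (S = 0 would be absorbing).
#' @param L_min lower clamp on ligand concentration before the logarithm
#'   (mM, > 0); defaults to the 0.12 uM assay buffer background.
#'
#' @return An object of class `awa_params`: a named list of the thirteen
#'   constants above.
#' @seealso [make_mutant()], [receptor_activity()], [state_derivative()]
#' @examples
#' p <- model_params()
#' receptor_activity(p$L0, 0, p)  # 0.5 by construction
#' @export
model_params <- function(k1 = 1, k2 = 10, k3 = 200, k4 = 4.5,
                         k5 = 0.04, k6 = 9e-4,
                         L0 = 1.2e-4, Rt = 0.5,
                         tau_c = 1, tau_I = 1550, C0 = 0.1,
                         S_floor = 1e-8, L_min = 1.2e-4) {
  p <- list(k1 = k1, k2 = k2, k3 = k3, k4 = k4, k5 = k5, k6 = k6,
            L0 = L0, Rt = Rt, tau_c = tau_c, tau_I = tau_I, C0 = C0,
            S_floor = S_floor, L_min = L_min)
  validate_params(p)
  structure(p, class = "awa_params")
}

param_names <- function() {
  c("k1", "k2", "k3", "k4", "k5", "k6", "L0", "Rt", "tau_c", "tau_I", "C0",
    "S_floor", "L_min")
}

validate_params <- function(p) {
  vals <- unlist(p[param_names()])
  if (anyNA(vals) || any(!is.finite(vals)))
    awa_stop("all model parameters must be finite numbers",
             "awa_invalid_parameter")
  pos <- c("k1", "k2", "k3", "k4", "L0", "tau_c", "tau_I", "C0",
           "S_floor", "L_min")
  bad <- pos[vapply(pos, function(nm) p[[nm]] <= 0, logical(1))]
  if (length(bad))
    awa_stop(paste0("parameters must be strictly positive: ",
                    paste(bad, collapse = ", ")), "awa_invalid_parameter")
  if (p$k5 < 0 || p$k6 < 0)
    awa_stop("k5 and k6 must be non-negative (0 disables the pathway)",
             "awa_invalid_parameter")
  if (p$Rt <= 0 || p$Rt >= 1)
    awa_stop("Rt must lie strictly inside (0, 1)", "awa_invalid_parameter")
  if (p$S_floor >= 1)
    awa_stop("S_floor must be below 1", "awa_invalid_parameter")
  invisible(p)
}

#' @export
print.awa_params <- function(x, ...) {
  cat("AWA feedback-model parameters\n")
  v <- unlist(x[param_names()])
  cat(paste0("  ", format(names(v), width = 8), " ",
             format(v, digits = 6, scientific = FALSE), collapse = "\n"),
      "\n")
  if (x$k5 == 0) cat("  (k5 = 0: tax-6 variant, no calcium feedback)\n")
  invisible(x)
}

#' Derive a mutant parameter set
#'
#' The tax-6/calcineurin loss-of-function mutant is modeled by removing the
#' calcium-dependent inhibition pathway, i.e. setting `k5 = 0` and leaving
#' every other constant unchanged.
#'
#' @param params an [model_params()] object.
#' @param mutant_name `"wild-type"` (returns `params` unchanged) or
#'   `"tax-6"`.
#' @return An `awa_params` object.
#' @examples
#' make_mutant(model_params(), "tax-6")$k5  # 0
#' @export
make_mutant <- function(params, mutant_name) {
  validate_params(params)
  known <- c("wild-type", "tax-6")
  if (!is.character(mutant_name) || length(mutant_name) != 1 ||
      !(mutant_name %in% known))
    awa_stop(paste0("unknown mutant label; valid labels: ",
                    paste(known, collapse = ", ")), "awa_unknown_mutant")
  if (mutant_name == "wild-type") return(params)
  params$k5 <- 0
  params
}

#' Active-receptor fraction
#'
#' The fraction of active (unliganded-state-shifted) ODR-10 receptors as a
#' logistic function of log ligand concentration, shifted linearly by the
#' inhibition level:
#' \deqn{R_a = (1 + \exp(-k_1 \log(L/L_0) + k_2 I))^{-1}}
#' The logarithm is natural.  L is clamped below at `L_min` before the log,
#' mirroring the low odor background kept in the assay buffer.
#'
#' @param L ligand concentration (mM); vectorized.
#' @param I inhibition level (>= 0); vectorized (recycled against `L`).
#' @param params an [model_params()] object.
#' @return Active-receptor fraction(s), strictly inside (0, 1);
#'   increasing in `L`, decreasing in `I`.
#' @examples
#' p <- model_params()
#' receptor_activity(p$L0, 0, p)            # 0.5
#' receptor_activity(exp(1) * p$L0, 0, p)   # plogis(k1)
#' @export
receptor_activity <- function(L, I, params) {
  validate_params(params)
  if (length(L) == 0 || length(I) == 0 || anyNA(L) || anyNA(I) ||
      any(!is.finite(L)) || any(!is.finite(I)))
    awa_stop("L and I must be finite", "awa_invalid_input")
  if (any(I < 0))
    awa_stop("inhibition level I must be non-negative", "awa_invalid_input")
  L <- pmax(L, params$L_min)
  1 / (1 + exp(-params$k1 * log(L / params$L0) + params$k2 * I))
}

#' Model state constructor
#'
#' Bundles the three dynamic variables of the circuit: open-channel
#' fraction `S` (clamped to `[S_floor, 1]`), calcium `C` (>= 0) and
#' inhibition `I` (>= 0).  The active-receptor fraction Ra is not state: it
#' is an algebraic function of the ligand and `I` ([receptor_activity()]).
#'
#' @param S open-channel fraction.
#' @param C calcium concentration (concentration units).
#' @param I inhibition level.
#' @param params an [model_params()] object (supplies the `S` clamp).
#' @return A named numeric vector `c(S, C, I)`.
#' @export
model_state <- function(S, C, I, params) {
  validate_params(params)
  v <- c(S = S, C = C, I = I)
  if (anyNA(v) || any(!is.finite(v)))
    awa_stop("state variables must be finite", "awa_invalid_state")
  if (S < params$S_floor - 1e-12 || S > 1 + 1e-12)
    awa_stop("S must lie in [S_floor, 1]", "awa_invalid_state")
  if (C < 0 || I < 0)
    awa_stop("C and I must be non-negative", "awa_invalid_state")
  v
}

#' Time derivatives of the model state
#'
#' Evaluates the right-hand side of the three coupled ODEs at a given state
#' and ligand concentration:
#' \deqn{dS/dt = k_3 (R_a - R_t) S}
#' \deqn{dC/dt = k_4 S - (C - C_0)/\tau_c}
#' \deqn{dI/dt = k_5 (C - C_0) R_a + k_6 R_a - (1 - R_a) I/\tau_I}
#' with \eqn{R_a} from [receptor_activity()].  Derivatives pointing outward
#' toward a clamped bound (`S` at `S_floor` or 1, `C` or `I` at 0) taper
#' linearly to zero across a narrow boundary layer and vanish at the bound
#' — the identical rule used inside the compiled solver core, which keeps
#' the vector field continuous for the adaptive integrator.
#'
#' @param state named numeric vector `c(S, C, I)` (see [model_state()]).
#' @param L ligand concentration (mM, scalar).
#' @param params an [model_params()] object.
#' @return Named numeric vector of derivatives `c(S, C, I)` (per second).
#' @export
state_derivative <- function(state, L, params) {
  validate_params(params)
  state <- model_state(state[["S"]], state[["C"]], state[["I"]], params)
  if (!is.finite(L)) awa_stop("L must be finite", "awa_invalid_input")
  S <- min(max(state[["S"]], params$S_floor), 1)
  C <- max(state[["C"]], 0)
  I <- max(state[["I"]], 0)
  Ra <- receptor_activity(L, I, params)
  dS <- params$k3 * (Ra - params$Rt) * S
  dC <- params$k4 * S - (C - params$C0) / params$tau_c
  dI <- params$k5 * (C - params$C0) * Ra + params$k6 * Ra -
    (1 - Ra) * I / params$tau_I
  taper <- function(x, bound, layer) min(max((x - bound) / layer, 0), 1)
  dS <- if (dS > 0) dS * taper(1 - state[["S"]], 0, 1e-3) else
    dS * taper(state[["S"]], params$S_floor, params$S_floor)
  if (dC < 0) dC <- dC * taper(state[["C"]], 0, 1e-9)
  if (dI < 0) dI <- dI * taper(state[["I"]], 0, 1e-9)
  c(S = unname(dS), C = unname(dC), I = unname(dI))
}

#' Steady-state inhibition at baseline calcium
#'
#' Closed form of the inhibition balance at `dI/dt = 0` with calcium at its
#' baseline (`C = C0`), where production `k6 * Ra` matches removal
#' `(1 - Ra) I / tau_I`:
#' \deqn{I^\ast = k_6 \tau_I R_a / (1 - R_a)}
#'
#' @param Ra active-receptor fraction, strictly inside (0, 1).
#' @param params an [model_params()] object.
#' @return Steady-state inhibition level (vectorized over `Ra`).
#' @export
steady_state_inhibition <- function(Ra, params) {
  validate_params(params)
  if (anyNA(Ra) || any(!is.finite(Ra)) || any(Ra <= 0))
    awa_stop("Ra must be finite and strictly positive", "awa_invalid_input")
  if (any(Ra >= 1))
    awa_stop("steady-state inhibition diverges as Ra approaches 1",
             "awa_divergence")
  params$k6 * params$tau_I * Ra / (1 - Ra)
}

#' Adaptive ligand threshold
#'
#' The ligand concentration at which the active-receptor fraction crosses
#' the channel-opening threshold `Rt`, given the current inhibition level:
#' \deqn{L_{th}(I) = L_0 \exp\{(k_2 I + \mathrm{logit}(R_t))/k_1\}}
#' This is the closed-form "adaptive threshold" view of the circuit: the
#' firing threshold rises exponentially with the accumulated inhibition,
#' i.e. with stimulus history.
#'
#' @param I inhibition level (>= 0); vectorized.
#' @param params an [model_params()] object.
#' @return Threshold ligand concentration(s) in mM.
#' @export
adaptive_threshold <- function(I, params) {
  validate_params(params)
  if (anyNA(I) || any(!is.finite(I)) || any(I < 0))
    awa_stop("I must be finite and non-negative", "awa_invalid_input")
  logit_Rt <- log(params$Rt / (1 - params$Rt))
  params$L0 * exp((params$k2 * I + logit_Rt) / params$k1)
}

#' Read or write a parameter set
#'
#' Parameter sets serialize to a flat mapping of field name to value, in
#' YAML or JSON (chosen from the file extension).  A file may carry an
#' optional `override` block (e.g. `k5: 0` for the tax-6 variant) applied
#' on top of the `base` mapping; a plain flat mapping is also accepted.
#'
#' @param params an [model_params()] object.
#' @param path file path ending in `.yaml`, `.yml` or `.json`.
#' @param override optional named list written as an override block.
#' @return `read_params()` returns an `awa_params` object;
#'   `write_params()` returns `path` invisibly.
#' @export
write_params <- function(params, path, override = NULL) {
  validate_params(params)
  payload <- if (is.null(override)) params[param_names()] else
    list(base = params[param_names()], override = override)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(payload, path)
  }
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE) else
      yaml::read_yaml(path)
  if (!is.null(raw$base)) {
    flat <- modifyList(raw$base, as.list(raw$override))
  } else flat <- raw
  do.call(model_params, lapply(flat[param_names()], as.numeric))
}
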