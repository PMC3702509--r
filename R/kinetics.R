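# Closed-form 1:1 Langmuir interaction model on an SPR surface and the
# scalar quantities derived from it (theoretical Rmax, equilibrium response,
# KD, ligand efficiency, dissociation half-life, detection limit).

#' Gas constant in kcal mol^-1 K^-1 (5 significant figures)
#' @keywords internal
.R_KCAL <- 1.9872e-3

#' Kinetic parameters of a 1:1 interaction
#'
#' Bundles the association rate constant `ka` (M^-1 s^-1), the dissociation
#' rate constant `kd` (s^-1) and the analyte binding capacity `rmax` (RU).
#' The equilibrium dissociation constant KD = kd/ka is derived, never stored.
#'
#' @param ka Association rate constant, M^-1 s^-1. Must be > 0.
#' @param kd Dissociation rate constant, s^-1. Must be > 0.
#' @param rmax Analyte binding capacity, RU. Must be >= 0.
#' @return An object of class `kinetic_params`.
#' @examples
#' p <- kinetic_params(ka = 1e5, kd = 1e-2, rmax = 50)
#' kd_from_rates(p) # 1e-7 M
#' @export
kinetic_params <- function(ka, kd, rmax) {
  stopifnot(is.numeric(ka), length(ka) == 1L, is.finite(ka),
            is.numeric(kd), length(kd) == 1L, is.finite(kd),
            is.numeric(rmax), length(rmax) == 1L, is.finite(rmax))
  if (ka <= 0) stop("'ka' must be > 0", call. = FALSE)
  if (kd <= 0) stop("'kd' must be > 0", call. = FALSE)
  if (rmax < 0) stop("'rmax' must be >= 0", call. = FALSE)
  structure(list(ka = ka, kd = kd, rmax = rmax), class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf("1:1 kinetic parameters: ka = %.4g M-1s-1, kd = %.4g s-1, Rmax = %.4g RU (KD = %.4g M)\n",
              x$ka, x$kd, x$rmax, x$kd / x$ka))
  invisible(x)
}

#' Description of the protein surface of a capture-format SPR assay
#'
#' @param protein_mw Molecular weight of the captured protein, Da.
#' @param capture_level Captured protein level, RU.
#' @param stoichiometry Analyte binding sites per captured protein
#'   (dimensionless). Kept as an explicit multiplier so capture formats
#'   with non-1:1 capture chemistry stay auditable.
#' @param activity_fraction Fraction of the captured protein that is
#'   binding-competent, in `[0, 1]`.
#' @return An object of class `surface_model`.
#' @examples
#' surf <- surface_model(protein_mw = 55000, capture_level = 16000)
#' theoretical_rmax(150, surf)
#' @export
surface_model <- function(protein_mw, capture_level = 16000, stoichiometry = 1,
                          activity_fraction = 1) {
  stopifnot(is.numeric(protein_mw), is.numeric(capture_level),
            is.numeric(stoichiometry), is.numeric(activity_fraction))
  if (protein_mw <= 0) stop("'protein_mw' must be > 0", call. = FALSE)
  if (capture_level < 0) stop("'capture_level' must be >= 0", call. = FALSE)
  if (stoichiometry <= 0) stop("'stoichiometry' must be > 0", call. = FALSE)
  if (activity_fraction < 0 || activity_fraction > 1)
    stop("'activity_fraction' must be in [0, 1]", call. = FALSE)
  structure(list(protein_mw = protein_mw, capture_level = capture_level,
                 stoichiometry = stoichiometry,
                 activity_fraction = activity_fraction),
            class = "surface_model")
}

#' Injection protocol for one sensorgram cycle
#'
#' Times are laid out as a pre-injection baseline segment, the sample
#' contact (association) phase, and the buffer-flow (dissociation) phase.
#' The sample grid starts at 0 s; the injection starts at `baseline_time`.
#'
#' @param contact_time Sample contact time, s (> 0).
#' @param dissociation_time Buffer-flow time after injection stop, s (>= 0).
#' @param baseline_time Pre-injection baseline, s (>= 0). Default 10 s.
#' @param flow_rate Flow rate, ul/min. Metadata only.
#' @param sample_hz Sampling rate, Hz, used when `sample_times` is NULL.
#' @param sample_times Optional explicit grid (strictly increasing, from 0).
#' @return An object of class `injection_protocol`.
#' @export
injection_protocol <- function(contact_time = 50, dissociation_time = 60,
                               baseline_time = 10, flow_rate = 30,
                               sample_hz = 1, sample_times = NULL) {
  if (contact_time <= 0) stop("'contact_time' must be > 0", call. = FALSE)
  if (dissociation_time < 0) stop("'dissociation_time' must be >= 0", call. = FALSE)
  if (baseline_time < 0) stop("'baseline_time' must be >= 0", call. = FALSE)
  if (is.null(sample_times)) {
    sample_times <- seq(0, baseline_time + contact_time + dissociation_time,
                        by = 1 / sample_hz)
  }
  if (sample_times[1] != 0 || any(diff(sample_times) <= 0))
    stop("'sample_times' must be strictly increasing and start at 0", call. = FALSE)
  structure(list(contact_time = contact_time,
                 dissociation_time = dissociation_time,
                 baseline_time = baseline_time,
                 flow_rate = flow_rate,
                 sample_times = sample_times),
            class = "injection_protocol")
}

.SENSORGRAM_ROLES <- c("fragment", "buffer", "solvent_calibration",
                       "reference_ligand", "dose_point")
.SENSORGRAM_SPOTS <- c("target", "reference", "offtarget_CA", "offtarget_GST")

#' A single injection-cycle trace with its metadata
#'
#' @param times Sample times, s.
#' @param responses Responses, RU; same length as `times`.
#' @param cycle_id Cycle identifier.
#' @param role One of `"fragment"`, `"buffer"`, `"solvent_calibration"`,
#'   `"reference_ligand"`, `"dose_point"`.
#' @param analyte_id Analyte identifier ("" for buffer).
#' @param concentration Analyte concentration, M (0 for buffer).
#' @param spot One of `"target"`, `"reference"`, `"offtarget_CA"`,
#'   `"offtarget_GST"`.
#' @param t_inject,t_stop Injection start/stop, s on the `times` axis.
#'   May be `NA` for imported data lacking timing metadata.
#' @return An object of class `sensorgram`.
#' @export
sensorgram <- function(times, responses, cycle_id = 1L, role = "fragment",
                       analyte_id = "", concentration = 0, spot = "target",
                       t_inject = NA_real_, t_stop = NA_real_) {
  if (length(times) != length(responses))
    stop("'times' and 'responses' must have equal length", call. = FALSE)
  role <- match.arg(role, .SENSORGRAM_ROLES)
  spot <- match.arg(spot, .SENSORGRAM_SPOTS)
  if (!is.na(concentration) && concentration < 0)
    stop("'concentration' must be >= 0", call. = FALSE)
  structure(list(times = as.numeric(times), responses = as.numeric(responses),
                 cycle_id = cycle_id, role = role, analyte_id = analyte_id,
                 concentration = concentration, spot = spot,
                 t_inject = t_inject, t_stop = t_stop),
            class = "sensorgram")
}

#' @export
print.sensorgram <- function(x, ...) {
  cat(sprintf("sensorgram: cycle %s [%s/%s] analyte '%s' at %.3g M, %d points (%.4g..%.4g s)\n",
              as.character(x$cycle_id), x$role, x$spot, x$analyte_id,
              x$concentration, length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

#' Theoretical maximal analyte response (Rmax) of a surface
#'
#' Assuming the refractive-index change is linear in molecular weight, the
#' maximal response of an analyte on a protein surface is
#' `Rmax = (MW_analyte / MW_protein) * R_protein * stoichiometry * activity`,
#' where `R_protein` is the captured protein level in RU.
#'
#' @param analyte_mw Analyte molecular weight, Da (> 0).
#' @param surface A [surface_model()].
#' @return Theoretical Rmax, RU.
#' @examples
#' theoretical_rmax(150, surface_model(55000, 16000)) # ~43.6 RU
#' @export
theoretical_rmax <- function(analyte_mw, surface) {
  stopifnot(inherits(surface, "surface_model"), is.numeric(analyte_mw))
  if (any(analyte_mw <= 0)) stop("'analyte_mw' must be > 0", call. = FALSE)
  if (surface$capture_level <= 0)
    stop("surface capture level must be > 0 for an Rmax estimate", call. = FALSE)
  (analyte_mw / surface$protein_mw) * surface$capture_level *
    surface$stoichiometry * surface$activity_fraction
}

#' Equilibrium (steady-state) response of a 1:1 interaction
#'
#' `Req(C) = Rmax * C / (C + KD)` with `KD = kd/ka`.
#'
#' @param params A [kinetic_params()].
#' @param concentration Analyte concentration, M (>= 0). Vectorised.
#' @return Equilibrium response, RU.
#' @export
equilibrium_response <- function(params, concentration) {
  stopifnot(inherits(params, "kinetic_params"))
  if (any(concentration < 0)) stop("'concentration' must be >= 0", call. = FALSE)
  kd_eq <- params$kd / params$ka
  params$rmax * concentration / (concentration + kd_eq)
}

#' Equilibrium dissociation constant from rate constants
#'
#' @param params A [kinetic_params()].
#' @return KD = kd/ka, M.
#' @export
kd_from_rates <- function(params) {
  stopifnot(inherits(params, "kinetic_params"))
  params$kd / params$ka
}

#' Simulate one noiseless sensorgram cycle under the 1:1 model
#'
#' Association follows `R(t) = Req * (1 - exp(-(ka*C + kd) * t))` from the
#' injection start, with `Req = Rmax * C / (C + KD)`; dissociation follows
#' `R(t) = R_stop * exp(-kd * (t - t_stop))`. The response is zero before
#' injection and never exceeds `Rmax`.
#'
#' @param params A [kinetic_params()].
#' @param concentration Analyte concentration, M (>= 0).
#' @param protocol An [injection_protocol()].
#' @param cycle_id,role,analyte_id,spot Metadata passed to [sensorgram()].
#' @return A [sensorgram()] on the protocol's sample grid.
#' @export
simulate_cycle <- function(params, concentration, protocol = injection_protocol(),
                           cycle_id = 1L, role = "dose_point",
                           analyte_id = "", spot = "target") {
  stopifnot(inherits(params, "kinetic_params"),
            inherits(protocol, "injection_protocol"))
  if (concentration < 0) stop("'concentration' must be >= 0", call. = FALSE)
  t0 <- protocol$baseline_time
  t_stop <- t0 + protocol$contact_time
  resp <- model_response_1to1(protocol$sample_times, params$ka, params$kd,
                              params$rmax, concentration, t0, t_stop)
  sensorgram(protocol$sample_times, resp, cycle_id = cycle_id, role = role,
             analyte_id = analyte_id, concentration = concentration,
             spot = spot, t_inject = t0, t_stop = t_stop)
}

# Closed-form 1:1 response on an arbitrary grid; shared by the simulator and
# the kinetic fitter so the fitted model is exactly the generating model.
model_response_1to1 <- function(times, ka, kd, rmax, conc, t_inject, t_stop) {
  resp <- numeric(length(times))
  if (conc > 0 && rmax > 0) {
    kobs <- ka * conc + kd
    req <- rmax * conc / (conc + kd / ka)
    assoc <- times >= t_inject & times <= t_stop
    resp[assoc] <- req * (1 - exp(-kobs * (times[assoc] - t_inject)))
    r_stop <- req * (1 - exp(-kobs * (t_stop - t_inject)))
    dissoc <- times > t_stop
    resp[dissoc] <- r_stop * exp(-kd * (times[dissoc] - t_stop))
  }
  resp
}

#' Ligand efficiency
#'
#' Binding free energy per heavy atom:
#' `LE = -R * T * ln(KD) / Nh` in kcal mol^-1 per heavy atom, with
#' R = 1.9872e-3 kcal mol^-1 K^-1 and T defaulting to 298.15 K (25 C assay
#' temperature).
#'
#' @param kd_value Equilibrium dissociation constant, M (> 0). Vectorised.
#' @param heavy_atoms Heavy (non-hydrogen) atom count, >= 1. Vectorised.
#' @param temperature_k Temperature, K.
#' @return Ligand efficiency, kcal mol^-1 per heavy atom. A KD >= 1 M gives
#'   a non-positive value and raises a warning.
#' @examples
#' ligand_efficiency(18.3e-6, 13) # ~0.50
#' @export
ligand_efficiency <- function(kd_value, heavy_atoms, temperature_k = 298.15) {
  if (any(kd_value <= 0)) stop("'kd_value' must be > 0", call. = FALSE)
  if (any(heavy_atoms < 1)) stop("'heavy_atoms' must be >= 1", call. = FALSE)
  if (any(kd_value >= 1))
    warning("KD >= 1 M yields a non-positive ligand efficiency", call. = FALSE)
  (-.R_KCAL * temperature_k * log(kd_value)) / heavy_atoms
}

#' Dissociation half-life
#'
#' `t1/2 = ln(2) / kd`, the time for half of the complexes to dissociate.
#'
#' @param kd_rate Dissociation rate constant, s^-1 (> 0). Vectorised.
#' @return Half-life, s.
#' @export
half_life <- function(kd_rate) {
  if (any(kd_rate <= 0)) stop("'kd_rate' must be > 0", call. = FALSE)
  log(2) / kd_rate
}

#' Weakest detectable affinity of a single-concentration screen
#'
#' The largest KD whose equilibrium response at the screening concentration
#' still reaches the limit of detection:
#' `KD_max = C_screen * (Rmax_eff / LOD - 1)`.
#'
#' @param screen_conc Screening concentration, M.
#' @param effective_rmax Effective (activity-adjusted) Rmax of the analyte, RU.
#' @param lod Limit of detection, RU. Must satisfy `0 < lod < effective_rmax`;
#'   a LOD at or above the effective Rmax means the analyte is undetectable
#'   at any affinity and is signalled as an error of class
#'   `sprscreen_undetectable`.
#' @return The largest detectable KD, M.
#' @export
detection_limit_kd <- function(screen_conc, effective_rmax, lod) {
  if (screen_conc <= 0) stop("'screen_conc' must be > 0", call. = FALSE)
  if (lod <= 0) stop("'lod' must be > 0", call. = FALSE)
  if (lod >= effective_rmax) {
    stop(structure(class = c("sprscreen_undetectable", "error", "condition"),
                   list(message = "limit of detection is at or above the effective Rmax: undetectable at any affinity",
                        call = sys.call(-1))))
  }
  screen_conc * (effective_rmax / lod - 1)
}
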