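# Single-concentration screen analysis: background threshold, activity
# normalisation, %Rmax, quantitative QC flags, hit calling, promiscuity
# filtering, and the end-to-end screen pipeline.

#' Background statistics and 3-sigma threshold from buffer blanks
#'
#' @param buffer_levels Binding levels (RU) of running-buffer injections;
#'   at least 2.
#' @return An object of class `screen_stats` with `buffer_mean`,
#'   `buffer_sigma` (sample SD), `threshold` (mean + 3 sigma) and `n_buffer`.
#' @examples
#' background_threshold(c(0, 0, 0, 4)) # mean 1, sigma 2, threshold 7
#' @export
background_threshold <- function(buffer_levels) {
  buffer_levels <- as.numeric(buffer_levels)
  if (length(buffer_levels) < 2)
    stop("need at least 2 buffer levels", call. = FALSE)
  m <- mean(buffer_levels)
  s <- stats::sd(buffer_levels)
  structure(list(buffer_mean = m, buffer_sigma = s, threshold = m + 3 * s,
                 n_buffer = length(buffer_levels)),
            class = "screen_stats")
}

#' @export
print.screen_stats <- function(x, ...) {
  cat(sprintf("background: mean %.3g RU, sigma %.3g RU, 3-sigma threshold %.3g RU (n = %d blanks)\n",
              x$buffer_mean, x$buffer_sigma, x$threshold, x$n_buffer))
  invisible(x)
}

#' Per-cycle surface-activity factors from reference-ligand probes
#'
#' Probe binding levels are normalised to the first probe and linearly
#' interpolated between probe cycles (held constant outside them), giving a
#' factor in (0, 1] for every cycle of the run.
#'
#' @param probe_levels Probe binding levels, RU (>= 2 probes).
#' @param probe_cycles Cycle indices of the probes.
#' @param n_cycles Total number of cycles in the run.
#' @return An object of class `activity_series` with the probe data and a
#'   `factors` vector of length `n_cycles`.
#' @export
activity_factors <- function(probe_levels, probe_cycles, n_cycles) {
  if (length(probe_levels) < 2) stop("need at least 2 probes", call. = FALSE)
  if (length(probe_levels) != length(probe_cycles))
    stop("probe levels and cycles must have equal length", call. = FALSE)
  o <- order(probe_cycles)
  probe_cycles <- probe_cycles[o]
  probe_levels <- probe_levels[o]
  if (probe_levels[1] <= 0)
    stop("first probe level must be positive", call. = FALSE)
  rel <- probe_levels / probe_levels[1]
  f <- stats::approx(probe_cycles, rel, xout = seq_len(n_cycles), rule = 2)$y
  f <- pmin(1, pmax(.Machine$double.eps, f))
  structure(list(probe_cycles = probe_cycles, probe_levels = probe_levels,
                 factors = f),
            class = "activity_series")
}

#' Binding level as a percentage of the theoretical Rmax
#'
#' `%Rmax = 100 * (level - background mean) / (Rmax_theoretical * factor)`,
#' the molecular-weight- and protein-activity-normalised binding metric.
#'
#' @param level Corrected binding level, RU. Vectorised.
#' @param fragment_mw Analyte molecular weight, Da. Vectorised.
#' @param surface A [surface_model()].
#' @param factor Surface-activity factor in (0, 1]. Vectorised.
#' @param stats Optional [background_threshold()] result; its buffer mean is
#'   subtracted from `level` (0 if NULL).
#' @return Percent of theoretical Rmax.
#' @export
percent_rmax <- function(level, fragment_mw, surface, factor = 1, stats = NULL) {
  bg <- if (is.null(stats)) 0 else stats$buffer_mean
  100 * (level - bg) / (theoretical_rmax(fragment_mw, surface) * factor)
}

#' QC thresholds for sensorgram ill-behaviour flags
#'
#' Defaults were chosen against the artifact generator so that clean 1:1
#' cycles at typical screen noise never trip a flag while each generated
#' artifact kind does.
#'
#' @param drift_slope Late-association slope above which the upward-drift
#'   flag trips, RU/s.
#' @param carryover_level Pre-injection baseline (vs. zero) above which the
#'   carryover flag trips, RU.
#' @param super_stoich_factor Multiple of the expected Rmax above which the
#'   super-stoichiometry flag trips.
#' @param non11_rms Residual RMS of the single-exponential dissociation fit
#'   above which the non-1:1 dissociation flag trips, RU.
#' @param dissoc_skip Seconds after injection stop excluded from the
#'   dissociation fit (bulk-shift transient).
#' @return A named list of thresholds.
#' @export
qc_thresholds <- function(drift_slope = 0.05, carryover_level = 1,
                          super_stoich_factor = 1.2, non11_rms = 0.8,
                          dissoc_skip = 1) {
  list(drift_slope = drift_slope, carryover_level = carryover_level,
       super_stoich_factor = super_stoich_factor, non11_rms = non11_rms,
       dissoc_skip = dissoc_skip)
}

# Single-exponential fit of the dissociation phase; returns residual RMS.
.dissoc_exp_rms <- function(tau, y) {
  if (length(tau) < 4) return(0)
  r0 <- y[1]
  if (!is.finite(r0) || abs(r0) < 1e-9) r0 <- 1e-9
  span <- tau[length(tau)] - tau[1]
  ratio <- max(abs(y[1]), 1e-9) / max(abs(y[length(y)]), 1e-9)
  k0 <- min(1, max(1e-4, log(max(ratio, 1.0001)) / span))
  fit <- tryCatch(
    minpack.lm::nls.lm(par = c(r0 = r0, lk = log(k0)),
                       fn = function(p) p[["r0"]] * exp(-exp(p[["lk"]]) * tau) - y,
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(stats::sd(y))
  sqrt(mean(fit$fvec^2))
}

#' Quantitative ill-behaviour QC of one sensorgram
#'
#' Operationalises visual sensorgram inspection as four metrics with
#' configurable thresholds: late-association slope (upward drift),
#' pre-injection baseline (carryover), binding level relative to the
#' expected Rmax (super-stoichiometry), and the residual RMS of a
#' single-exponential fit to the dissociation phase (non-1:1 dissociation).
#'
#' @param s A (reference-subtracted) [sensorgram()] with injection timing.
#' @param expected_rmax Expected (activity-adjusted) theoretical Rmax, RU.
#' @param thresholds A [qc_thresholds()] list.
#' @return An object of class `qc_flags`: logical `flags` plus the
#'   `metrics` behind them.
#' @export
qc_sensorgram <- function(s, expected_rmax, thresholds = qc_thresholds()) {
  stopifnot(inherits(s, "sensorgram"))
  if (is.na(s$t_inject) || is.na(s$t_stop))
    stop("sensorgram lacks injection timing metadata", call. = FALSE)
  t <- s$times; y <- s$responses
  late <- t >= s$t_inject + 0.6 * (s$t_stop - s$t_inject) & t <= s$t_stop
  slope <- if (sum(late) >= 3)
    unname(stats::coef(stats::lm(y[late] ~ t[late]))[2]) else 0
  pre <- t < s$t_inject
  baseline <- if (any(pre)) mean(y[pre]) else 0
  lvl <- binding_level(s)$level
  post <- t >= s$t_stop + thresholds$dissoc_skip
  rms <- .dissoc_exp_rms(t[post] - s$t_stop, y[post])
  metrics <- list(late_association_slope = slope,
                  pre_injection_baseline = baseline,
                  level = lvl, expected_rmax = expected_rmax,
                  dissociation_fit_rms = rms)
  flags <- c(upward_drift = slope > thresholds$drift_slope,
             carryover = baseline > thresholds$carryover_level,
             super_stoichiometry =
               lvl > thresholds$super_stoich_factor * expected_rmax,
             non11_dissociation = rms > thresholds$non11_rms)
  structure(list(flags = flags, metrics = metrics), class = "qc_flags")
}

#' Call single-concentration hits
#'
#' A fragment is a hit when its corrected binding level exceeds the
#' background threshold and no QC flag is set. Fragments whose level on an
#' off-target spot exceeds that spot's own threshold are marked
#' promiscuous; they are reported but excluded from the clean hit list.
#'
#' @param records A data frame with columns `fragment_id`,
#'   `corrected_level`, logical QC columns `qc_upward_drift`,
#'   `qc_carryover`, `qc_super_stoichiometry`, `qc_non11_dissociation`
#'   (NA counts as not flagged), and optional off-target level columns
#'   named after the spots.
#' @param stats Target-spot [background_threshold()] result.
#' @param offtarget_stats Optional named list of per-spot
#'   [background_threshold()] results for the off-target columns.
#' @return `records` with `is_hit` and `promiscuous` columns added; the
#'   clean hit subset is in the `"clean_hits"` attribute.
#' @export
call_hits <- function(records, stats, offtarget_stats = NULL) {
  stopifnot(is.data.frame(records), inherits(stats, "screen_stats"))
  qc_cols <- grep("^qc_", names(records), value = TRUE)
  flagged <- if (length(qc_cols)) {
    m <- as.matrix(records[qc_cols])
    m[is.na(m)] <- FALSE
    rowSums(m) > 0
  } else rep(FALSE, nrow(records))
  records$is_hit <- records$corrected_level > stats$threshold & !flagged
  prom <- rep(FALSE, nrow(records))
  for (sp in names(offtarget_stats)) {
    if (!sp %in% names(records)) next
    prom <- prom | (records[[sp]] > offtarget_stats[[sp]]$threshold)
  }
  records$promiscuous <- prom
  attr(records, "clean_hits") <- records[records$is_hit & !records$promiscuous, ]
  records
}

#' Run the full single-concentration triage pipeline on a screen
#'
#' Reference subtraction, optional DMSO solvent correction, report-point
#' extraction, 3-sigma background threshold from the buffer blanks,
#' activity factors from the reference-ligand probes, %Rmax normalisation,
#' QC of every above-threshold cycle, hit calling and promiscuity
#' filtering.
#'
#' @param screen An `spr_screen` (from [generate_screen()] or
#'   [screen_from_sensorgrams()]).
#' @param library Fragment table with `id`, `mw` (and `heavy_atoms`)
#'   columns for every screened analyte.
#' @param surface A [surface_model()] describing the target spot.
#' @param qc A [qc_thresholds()] list.
#' @param solvent_correct Apply solvent correction when at least 3
#'   calibration cycles span a bulk range wider than `solvent_min_span` RU.
#' @param solvent_degree Polynomial degree of the solvent curve.
#' @param solvent_min_span Minimal calibrated bulk span (RU) for the
#'   correction to be applied; guards against fitting pure noise when no
#'   DMSO titration was run.
#' @return An object of class `screen_analysis`: background statistics per
#'   spot, the activity series, the per-fragment record table, the clean
#'   hit table and a run summary.
#' @export
process_screen <- function(screen, library, surface,
                           qc = qc_thresholds(),
                           solvent_correct = TRUE, solvent_degree = 2,
                           solvent_min_span = 2) {
  stopifnot(inherits(screen, "spr_screen"), is.data.frame(library),
            inherits(surface, "surface_model"))
  meta <- screen$meta
  spots <- unique(meta$spot)
  n_spots <- length(spots)
  if (!"reference" %in% spots)
    stop("screen has no reference spot", call. = FALSE)
  t0 <- screen$t_inject; t_stop <- screen$t_stop
  in_rep <- screen$times >= t_stop - 5 & screen$times <= t_stop
  in_base <- screen$times >= max(0, t0 - 10) & screen$times < t0
  lvl_raw <- colMeans(screen$traces[in_rep, , drop = FALSE]) -
    colMeans(screen$traces[in_base, , drop = FALSE])

  cyc <- meta$cycle_id[meta$spot == "target"]
  roles <- meta$role[meta$spot == "target"]
  cyc_pos <- seq_along(cyc)  # run-order index, robust to non-numeric ids
  lvl <- matrix(lvl_raw, nrow = n_spots,
                dimnames = list(meta$spot[seq_len(n_spots)], NULL))
  ref <- lvl["reference", ]
  corrected <- sweep(lvl, 2, ref)  # per-spot reference-subtracted levels

  # solvent correction per active spot, calibrated on the DMSO cycles
  cal_idx <- which(roles == "solvent_calibration")
  active_spots <- setdiff(rownames(lvl), "reference")
  solvent_curves <- list()
  if (isTRUE(solvent_correct) && length(cal_idx) >= 3) {
    for (sp in active_spots) {
      cal_sgs <- unlist(lapply(cyc[cal_idx], function(id)
        list(get_sensorgram(screen, id, "reference"),
             get_sensorgram(screen, id, sp))), recursive = FALSE)
      curve <- fit_solvent_curve(cal_sgs, degree = solvent_degree)
      if (diff(curve$range) >= solvent_min_span) {
        solvent_curves[[sp]] <- curve
        corrected[sp, ] <- corrected[sp, ] -
          suppressWarnings(as.numeric(predict(curve, ref)))
      }
    }
  }

  # background statistics per spot from the buffer blanks
  buf <- roles == "buffer"
  if (sum(buf) < 2) stop("screen contains fewer than 2 buffer blanks", call. = FALSE)
  stats_target <- background_threshold(corrected["target", buf])
  offtarget_stats <- lapply(setdiff(active_spots, "target"), function(sp)
    background_threshold(corrected[sp, buf]))
  names(offtarget_stats) <- setdiff(active_spots, "target")

  # surface-activity factors from the reference-ligand probes
  pr <- which(roles == "reference_ligand")
  activity <- if (length(pr) >= 2)
    activity_factors(corrected["target", pr], cyc_pos[pr], length(cyc))
  else NULL

  # per-fragment records
  fr <- which(roles == "fragment")
  fid <- meta$analyte_id[meta$spot == "target"][fr]
  mw <- library$mw[match(fid, library$id)]
  if (anyNA(mw))
    stop("screened analytes missing from the library table: ",
         paste(utils::head(unique(fid[is.na(mw)])), collapse = ", "), call. = FALSE)
  fac <- if (is.null(activity)) rep(1, length(fr)) else activity$factors[cyc_pos[fr]]
  prmax <- percent_rmax(corrected["target", fr], mw, surface, fac, stats_target)
  records <- data.frame(fragment_id = fid, cycle_id = cyc[fr],
                        raw_level = lvl["target", fr],
                        corrected_level = corrected["target", fr],
                        percent_rmax = prmax,
                        activity_factor = fac,
                        qc_upward_drift = NA, qc_carryover = NA,
                        qc_super_stoichiometry = NA,
                        qc_non11_dissociation = NA,
                        stringsAsFactors = FALSE)
  for (sp in names(offtarget_stats)) records[[sp]] <- corrected[sp, fr]

  # QC of every above-threshold cycle (the ones a screener would inspect)
  cand <- which(records$corrected_level > stats_target$threshold)
  for (i in cand) {
    s <- reference_subtract(get_sensorgram(screen, records$cycle_id[i], "target"),
                            get_sensorgram(screen, records$cycle_id[i], "reference"))
    qcf <- qc_sensorgram(s, theoretical_rmax(mw[i], surface) * fac[i], qc)
    records$qc_upward_drift[i] <- qcf$flags[["upward_drift"]]
    records$qc_carryover[i] <- qcf$flags[["carryover"]]
    records$qc_super_stoichiometry[i] <- qcf$flags[["super_stoichiometry"]]
    records$qc_non11_dissociation[i] <- qcf$flags[["non11_dissociation"]]
  }

  records <- call_hits(records, stats_target, offtarget_stats)
  clean <- attr(records, "clean_hits")
  summary <- list(
    n_fragments = nrow(records),
    n_above_threshold = length(cand),
    n_hits = sum(records$is_hit),
    n_clean_hits = nrow(clean),
    n_promiscuous = sum(records$promiscuous),
    hit_rate_pct = 100 * sum(records$is_hit) / nrow(records),
    clean_hit_rate_pct = 100 * nrow(clean) / nrow(records),
    promiscuity_rate_pct = 100 * sum(records$promiscuous) / nrow(records),
    threshold = stats_target$threshold,
    buffer_mean = stats_target$buffer_mean,
    buffer_sigma = stats_target$buffer_sigma,
    activity_first = if (is.null(activity)) NA_real_ else activity$factors[1],
    activity_last = if (is.null(activity)) NA_real_ else
      activity$factors[length(activity$factors)])
  structure(list(stats = stats_target, offtarget_stats = offtarget_stats,
                 activity = activity, records = records, hits = clean,
                 solvent_curves = solvent_curves, summary = summary),
            class = "screen_analysis")
}

#' @export
print.screen_analysis <- function(x, ...) {
  s <- x$summary
  cat(sprintf("screen analysis: %d fragments, threshold %.3g RU\n",
              s$n_fragments, s$threshold))
  cat(sprintf("  hits: %d (%.2f%%), clean hits: %d, promiscuous: %d (%.2f%%)\n",
              s$n_hits, s$hit_rate_pct, s$n_clean_hits, s$n_promiscuous,
              s$promiscuity_rate_pct))
  invisible(x)
}
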