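# Turning raw cycles into corrected binding levels: reference subtraction,
# blank subtraction, DMSO solvent correction, report-point extraction.

.same_grid <- function(a, b) {
  length(a$times) == length(b$times) && all(a$times == b$times)
}

#' Subtract a reference-spot trace from a sample trace
#'
#' Pointwise difference on identical time grids; sample metadata is
#' preserved. Mismatched grids raise an error rather than being silently
#' resampled, because interpolation hides injection artifacts.
#'
#' @param sample,reference [sensorgram()]s on the same time grid.
#' @return The referenced sensorgram.
#' @export
reference_subtract <- function(sample, reference) {
  stopifnot(inherits(sample, "sensorgram"), inherits(reference, "sensorgram"))
  if (!.same_grid(sample, reference))
    stop("time grids of sample and reference do not match; refusing to resample",
         call. = FALSE)
  sample$responses <- sample$responses - reference$responses
  sample
}

#' Subtract the average of buffer blanks from a sample trace
#'
#' The second half of double referencing: the mean of one or more
#' buffer-blank cycles (on the same grid) is subtracted pointwise.
#'
#' @param sample A [sensorgram()].
#' @param buffer_blanks A list of one or more blank [sensorgram()]s.
#' @return The blank-subtracted sensorgram.
#' @export
blank_subtract <- function(sample, buffer_blanks) {
  stopifnot(inherits(sample, "sensorgram"))
  if (inherits(buffer_blanks, "sensorgram")) buffer_blanks <- list(buffer_blanks)
  if (length(buffer_blanks) < 1) stop("at least one blank required", call. = FALSE)
  for (b in buffer_blanks) {
    stopifnot(inherits(b, "sensorgram"))
    if (!.same_grid(sample, b))
      stop("time grid of a blank does not match the sample; refusing to resample",
           call. = FALSE)
  }
  avg <- Reduce(`+`, lapply(buffer_blanks, `[[`, "responses")) / length(buffer_blanks)
  sample$responses <- sample$responses - avg
  sample
}

#' Report-point binding level of a cycle
#'
#' Mean response over a report window late in the association phase minus
#' the mean over a pre-injection baseline window. Defaults: report = last
#' 5 s of sample contact, baseline = 10 s immediately before injection.
#'
#' @param s A [sensorgram()] with injection timing (or explicit windows).
#' @param report_window Numeric `c(start, end)` in seconds, or NULL for the
#'   default.
#' @param baseline_window Numeric `c(start, end)` in seconds, or NULL for
#'   the default.
#' @return An object of class `binding_level` with fields `cycle_id`,
#'   `level` (RU), `baseline` (RU) and `window`.
#' @export
binding_level <- function(s, report_window = NULL, baseline_window = NULL) {
  stopifnot(inherits(s, "sensorgram"))
  if (is.null(report_window)) {
    if (is.na(s$t_stop)) stop("no injection timing: supply 'report_window'", call. = FALSE)
    report_window <- c(s$t_stop - 5, s$t_stop)
  }
  if (is.null(baseline_window)) {
    if (is.na(s$t_inject)) stop("no injection timing: supply 'baseline_window'", call. = FALSE)
    baseline_window <- c(max(0, s$t_inject - 10), s$t_inject)
  }
  rng <- range(s$times)
  if (report_window[1] < rng[1] || report_window[2] > rng[2] ||
      baseline_window[1] < rng[1] || baseline_window[2] > rng[2])
    stop("report/baseline window outside the cycle's time span", call. = FALSE)
  in_rep <- s$times >= report_window[1] & s$times <= report_window[2]
  in_base <- s$times >= baseline_window[1] & s$times < baseline_window[2]
  if (!any(in_rep) || !any(in_base))
    stop("empty report or baseline window", call. = FALSE)
  base <- mean(s$responses[in_base])
  structure(list(cycle_id = s$cycle_id,
                 level = mean(s$responses[in_rep]) - base,
                 baseline = base,
                 window = report_window),
            class = "binding_level")
}

#' Fit a DMSO solvent-correction curve
#'
#' Calibration cycles inject buffers of varying DMSO content; the bulk
#' refractive-index step measured on the reference spot is mapped to the
#' excess (active-spot minus reference-spot) response by a least-squares
#' polynomial. Applying the curve to a screened cycle removes the
#' spot-dependent excluded-volume mismatch.
#'
#' @param calibration_cycles A list of [sensorgram()]s from
#'   solvent-calibration cycles: for each cycle id, one trace on the
#'   `"reference"` spot and one on an active spot.
#' @param degree Polynomial degree, 1-3. Default 2.
#' @return An object of class `solvent_curve` with coefficients, the
#'   calibrated bulk-response range, and the residual RMS.
#' @export
fit_solvent_curve <- function(calibration_cycles, degree = 2) {
  stopifnot(degree %in% 1:3)
  if (!length(calibration_cycles) || !all(vapply(calibration_cycles, inherits,
                                                 logical(1), "sensorgram")))
    stop("'calibration_cycles' must be a list of sensorgrams", call. = FALSE)
  ids <- vapply(calibration_cycles, function(s) as.character(s$cycle_id), character(1))
  spots <- vapply(calibration_cycles, `[[`, character(1), "spot")
  xy <- lapply(unique(ids), function(id) {
    ref <- calibration_cycles[ids == id & spots == "reference"]
    act <- calibration_cycles[ids == id & spots != "reference"]
    if (length(ref) != 1L || length(act) != 1L) return(NULL)
    x <- binding_level(ref[[1]])$level
    y <- binding_level(reference_subtract(act[[1]], ref[[1]]))$level
    c(x = x, y = y)
  })
  xy <- do.call(rbind, xy)
  if (is.null(xy) || nrow(xy) < 3)
    stop("insufficient calibration: need >= 3 solvent cycles with reference and active traces",
         call. = FALSE)
  x <- xy[, "x"]; y <- xy[, "y"]
  fit <- stats::lm(y ~ stats::poly(x, degree, raw = TRUE))
  structure(list(coefficients = unname(stats::coef(fit)),
                 degree = degree,
                 range = range(x),
                 rms = sqrt(mean(stats::residuals(fit)^2)),
                 n = nrow(xy)),
            class = "solvent_curve")
}

#' Evaluate a solvent-correction curve
#'
#' @param object A `solvent_curve` from [fit_solvent_curve()].
#' @param x Bulk response measured on the reference spot, RU. Values
#'   outside the calibrated range raise a warning and are flagged in the
#'   `"extrapolated"` attribute of the result.
#' @param ... Unused.
#' @return Correction in RU to subtract from the referenced binding level.
#' @export
predict.solvent_curve <- function(object, x, ...) {
  out_of_range <- x < object$range[1] | x > object$range[2]
  if (any(out_of_range))
    warning(sum(out_of_range),
            " bulk response(s) outside the calibrated solvent range; extrapolating",
            call. = FALSE)
  corr <- numeric(length(x))
  for (k in seq_along(object$coefficients))
    corr <- corr + object$coefficients[k] * x^(k - 1)
  attr(corr, "extrapolated") <- out_of_range
  corr
}

#' @export
print.solvent_curve <- function(x, ...) {
  cat(sprintf("solvent curve: degree %d on %d cycles, bulk range [%.3g, %.3g] RU, residual RMS %.3g RU\n",
              x$degree, x$n, x$range[1], x$range[2], x$rms))
  invisible(x)
}
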