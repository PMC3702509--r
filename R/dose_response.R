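# Confirmation stage: global/local 1:1 kinetic fitting of concentration
# series, steady-state affinity fitting, the confirmation rule, and derived
# quantities (KD, ligand efficiency, dissociation half-life).

#' Bundle sensorgrams into a dose-response series
#'
#' @param sensorgrams List of [sensorgram()]s, one per concentration.
#' @param fragment_id Analyte identifier.
#' @param mode Default fit mode, `"global"` or `"local"`.
#' @return An object of class `dose_series` (concentrations sorted
#'   decreasing).
#' @export
dose_series <- function(sensorgrams, fragment_id = NULL, mode = "global") {
  stopifnot(length(sensorgrams) >= 1,
            all(vapply(sensorgrams, inherits, logical(1), "sensorgram")))
  mode <- match.arg(mode, c("global", "local"))
  conc <- vapply(sensorgrams, `[[`, numeric(1), "concentration")
  if (anyDuplicated(conc))
    stop("concentrations must be distinct", call. = FALSE)
  o <- order(conc, decreasing = TRUE)
  if (is.null(fragment_id)) fragment_id <- sensorgrams[[o[1]]]$analyte_id
  structure(list(sensorgrams = sensorgrams[o], fragment_id = fragment_id,
                 concentrations = conc[o], mode = mode),
            class = "dose_series")
}

.as_dose_series <- function(series) {
  if (inherits(series, "dose_series")) series else dose_series(series)
}

# Deterministic derivative-free initialisation: kd from a log-linear fit to
# the dissociation tail of the top concentration, KD guess = top
# concentration, rmax from the largest observed level.
.init_kinetics <- function(ds) {
  top <- ds$sensorgrams[[1]]
  c_top <- ds$concentrations[1]
  y <- top$responses; t <- top$times
  post <- t >= top$t_stop + 1
  kd0 <- NA_real_
  ymax <- max(vapply(ds$sensorgrams, function(s) max(s$responses), numeric(1)))
  if (sum(post) >= 4) {
    tau <- t[post] - top$t_stop
    yy <- y[post]
    keep <- yy > 0.02 * max(ymax, 1e-9)
    if (sum(keep) >= 4) {
      fit <- stats::lm(log(yy[keep]) ~ tau[keep])
      kd0 <- -unname(stats::coef(fit)[2])
    }
  }
  if (!is.finite(kd0) || kd0 <= 0) kd0 <- 1e-2
  kd0 <- min(max(kd0, 1e-6), 10)
  ka0 <- kd0 / c_top
  rmax0 <- ymax * (1 + 1)  # level at C = KD guess is half-saturating
  kinetic_params(ka0, kd0, max(rmax0, 1e-6))
}

.fit_curves_1to1 <- function(sgs, concs, init) {
  times <- lapply(sgs, `[[`, "times")
  resp <- lapply(sgs, `[[`, "responses")
  t0 <- vapply(sgs, `[[`, numeric(1), "t_inject")
  ts <- vapply(sgs, `[[`, numeric(1), "t_stop")
  if (anyNA(t0) || anyNA(ts))
    stop("sensorgrams lack injection timing metadata", call. = FALSE)
  resid_fun <- function(p) {
    ka <- exp(p[["lka"]]); kd <- exp(p[["lkd"]]); rmax <- p[["rmax"]]
    unlist(lapply(seq_along(sgs), function(i)
      model_response_1to1(times[[i]], ka, kd, rmax, concs[i], t0[i], ts[i]) -
        resp[[i]]))
  }
  par0 <- c(lka = log(init$ka), lkd = log(init$kd), rmax = init$rmax)
  fit <- minpack.lm::nls.lm(
    par = par0, fn = resid_fun,
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12,
                                         ptol = 1e-12))
  n <- length(fit$fvec)
  dof <- max(1, n - 3)
  sigma2 <- sum(fit$fvec^2) / dof
  se_log <- tryCatch(sqrt(diag(solve(fit$hessian)) * sigma2),
                     error = function(e) rep(NA_real_, 3))
  ka <- exp(fit$par[["lka"]]); kd <- exp(fit$par[["lkd"]])
  list(params = kinetic_params(ka, kd, max(fit$par[["rmax"]], 0)),
       se = c(ka = ka * se_log[1], kd = kd * se_log[2], rmax = se_log[3]),
       residual_rms = sqrt(mean(fit$fvec^2)),
       converged = fit$info %in% 1:4,
       n_obs = n, n_iter = fit$niter,
       message = fit$message)
}

#' Fit the 1:1 kinetic model to a dose-response series
#'
#' Nonlinear least squares on the closed-form 1:1 association/dissociation
#' model. In `"global"` mode a single (ka, kd, Rmax) triplet is shared
#' across all concentrations; in `"local"` mode each concentration is
#' fitted separately and the rate constants are combined as geometric
#' means. Non-convergence is reported, never silent.
#'
#' @param series A [dose_series()] or list of [sensorgram()]s (>= 2
#'   concentrations with signal).
#' @param init Optional [kinetic_params()] starting point; the default is a
#'   deterministic start (dissociation-tail log-linear fit for kd, KD guess
#'   at the top concentration, Rmax from the largest level).
#' @param mode `"global"` (default) or `"local"`.
#' @return An object of class `spr_fit` with the fitted [kinetic_params()],
#'   `kd_value` (KD, M), standard errors, residual RMS, and a `converged`
#'   flag with diagnostics.
#' @export
fit_kinetic_1to1 <- function(series, init = NULL, mode = NULL) {
  ds <- .as_dose_series(series)
  if (is.null(mode)) mode <- ds$mode
  mode <- match.arg(mode, c("global", "local"))
  keep <- ds$concentrations > 0
  sgs <- ds$sensorgrams[keep]
  concs <- ds$concentrations[keep]
  ymax <- if (length(sgs))
    max(vapply(sgs, function(s) max(abs(s$responses)), numeric(1))) else 0
  fail <- function(msg) structure(
    list(params = NULL, kd_value = NA_real_, se = c(ka = NA, kd = NA, rmax = NA),
         residual_rms = NA_real_, converged = FALSE, mode = mode,
         n_obs = 0L, n_iter = 0L, message = msg, fragment_id = ds$fragment_id),
    class = "spr_fit")
  if (length(sgs) < 2)
    return(fail("fewer than 2 non-zero concentrations"))
  if (!is.finite(ymax) || ymax < 1e-9)
    return(fail("no signal: all traces are (near) zero"))
  if (is.null(init)) init <- .init_kinetics(dose_series(sgs))
  if (mode == "global") {
    f <- .fit_curves_1to1(sgs, concs, init)
  } else {
    fits <- lapply(seq_along(sgs), function(i)
      .fit_curves_1to1(sgs[i], concs[i], init))
    ka <- exp(mean(log(vapply(fits, function(x) x$params$ka, numeric(1)))))
    kd <- exp(mean(log(vapply(fits, function(x) x$params$kd, numeric(1)))))
    rmax <- mean(vapply(fits, function(x) x$params$rmax, numeric(1)))
    f <- list(params = kinetic_params(ka, kd, rmax),
              se = c(ka = NA_real_, kd = NA_real_, rmax = NA_real_),
              residual_rms = sqrt(mean(unlist(lapply(fits, function(x)
                x$residual_rms^2 * x$n_obs)) / sum(vapply(fits, `[[`,
                numeric(1), "n_obs")))),
              converged = all(vapply(fits, `[[`, logical(1), "converged")),
              n_obs = sum(vapply(fits, `[[`, integer(1), "n_obs")),
              n_iter = max(vapply(fits, `[[`, integer(1), "n_iter")),
              message = "local per-concentration fits")
    f$local_fits <- fits
  }
  structure(c(f, list(kd_value = f$params$kd / f$params$ka, mode = mode,
                      fragment_id = ds$fragment_id)),
            class = "spr_fit")
}

#' @export
print.spr_fit <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    cat(sprintf("spr_fit (%s): NOT converged - %s\n", x$mode, x$message))
    return(invisible(x))
  }
  if (!is.null(x$params))
    cat(sprintf("spr_fit (%s): ka %.4g M-1s-1, kd %.4g s-1, Rmax %.4g RU, KD %.4g M (rms %.3g RU)\n",
                x$mode, x$params$ka, x$params$kd, x$params$rmax, x$kd_value,
                x$residual_rms))
  else
    cat(sprintf("spr_fit (steady state): KD %.4g M, Rmax %.4g RU (rms %.3g RU)\n",
                x$kd_value, x$rmax, x$residual_rms))
  invisible(x)
}

#' Fit a steady-state 1:1 binding isotherm
#'
#' Least squares of `Req(C) = Rmax * C / (C + KD)` to equilibrium binding
#' levels, for (Rmax, KD).
#'
#' @param levels Data frame (or 2-column matrix) with concentration (M) and
#'   level (RU); >= 3 points.
#' @return An `spr_fit` with `kd_value` (M) and `rmax`, plus a
#'   `kd_poorly_determined` flag set when the measured concentrations span
#'   less than 0.2 x the fitted KD (affinity not identifiable from the
#'   sampled range).
#' @export
fit_steady_state <- function(levels) {
  levels <- as.data.frame(levels)
  if (ncol(levels) < 2) stop("'levels' needs concentration and level columns",
                             call. = FALSE)
  conc <- levels[[1]]; y <- levels[[2]]
  if (length(conc) < 3) stop("need at least 3 concentration points", call. = FALSE)
  if (any(conc <= 0)) stop("concentrations must be > 0", call. = FALSE)
  ymax <- max(y)
  kd0 <- conc[which.min(abs(y - ymax / 2))]
  fit <- minpack.lm::nls.lm(
    par = c(lkd = log(kd0), rmax = 1.05 * ymax),
    fn = function(p) p[["rmax"]] * conc / (conc + exp(p[["lkd"]])) - y,
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12,
                                         ptol = 1e-12))
  kd <- exp(fit$par[["lkd"]])
  dof <- max(1, length(y) - 2)
  sigma2 <- sum(fit$fvec^2) / dof
  se_log <- tryCatch(sqrt(diag(solve(fit$hessian)) * sigma2),
                     error = function(e) rep(NA_real_, 2))
  structure(list(params = NULL, kd_value = kd, rmax = fit$par[["rmax"]],
                 se = c(kd = kd * se_log[1], rmax = se_log[2]),
                 residual_rms = sqrt(mean(fit$fvec^2)),
                 converged = fit$info %in% 1:4, mode = "steady_state",
                 n_obs = length(y), n_iter = fit$niter,
                 kd_poorly_determined = max(conc) < 0.2 * kd,
                 message = fit$message),
            class = "spr_fit")
}

#' Apply the dose-response confirmation rule
#'
#' A hit is confirmed when it binds in a concentration-dependent manner at
#' three or more concentrations, its %Rmax at the top clean concentration
#' is at least `min_percent_rmax`, and no disqualifying QC flag occurs
#' below the top clean concentration. A level counts as concentration-
#' dependent when it exceeds the level at the previous (lower)
#' concentration by more than one buffer sigma.
#'
#' @param levels Data frame with concentration (M) and binding level (RU)
#'   columns.
#' @param qc Optional per-concentration QC: a logical vector (TRUE =
#'   disqualified) or list of [qc_sensorgram()] results, aligned with
#'   `levels` rows.
#' @param noise_sigma Buffer sigma used as the increase tolerance, RU.
#' @param percent_rmax_at_top %Rmax at the top clean concentration; if NULL
#'   it is computed from `fragment` (column `mw`), `surface` and
#'   `activity_factor`.
#' @param fit Optional converged [fit_kinetic_1to1()] result; KD, LE and
#'   t1/2 are attached to a confirmed hit (requires `fragment$heavy_atoms`).
#' @param fragment Optional single-row fragment record.
#' @param surface Optional [surface_model()] (for %Rmax).
#' @param activity_factor Surface-activity factor for %Rmax.
#' @param min_concentrations Minimum concentration-dependent points, default 3.
#' @param min_percent_rmax Minimal top %Rmax, default 10.
#' @return An object of class `confirmation_result`.
#' @export
confirm_hit <- function(levels, qc = NULL, noise_sigma = 0,
                        percent_rmax_at_top = NULL, fit = NULL,
                        fragment = NULL, surface = NULL, activity_factor = 1,
                        min_concentrations = 3, min_percent_rmax = 10) {
  levels <- as.data.frame(levels)
  conc <- levels[[1]]; lvl <- levels[[2]]
  o <- order(conc)
  conc <- conc[o]; lvl <- lvl[o]
  flagged <- rep(FALSE, length(conc))
  if (!is.null(qc)) {
    flagged <- if (is.logical(qc)) qc[o]
    else vapply(qc, function(f) any(f$flags), logical(1))[o]
  }
  illbehaved_above <- if (any(flagged)) min(conc[flagged]) else NA_real_
  clean <- if (is.na(illbehaved_above)) rep(TRUE, length(conc))
  else conc < illbehaved_above
  n_dep <- 0L
  if (any(clean)) {
    lc <- lvl[clean]
    run <- 1L; best <- 1L
    if (length(lc) > 1) {
      for (i in 2:length(lc)) {
        if (lc[i] > lc[i - 1] + noise_sigma) run <- run + 1L else run <- 1L
        best <- max(best, run)
      }
    }
    n_dep <- best
  }
  if (is.null(percent_rmax_at_top)) {
    if (!is.null(fragment) && !is.null(surface) && any(clean)) {
      top_lvl <- lvl[clean][sum(clean)]
      percent_rmax_at_top <- percent_rmax(top_lvl, fragment$mw, surface,
                                          activity_factor)
    } else {
      percent_rmax_at_top <- NA_real_
    }
  }
  confirmed <- n_dep >= min_concentrations &&
    isTRUE(percent_rmax_at_top >= min_percent_rmax)
  res <- list(confirmed = confirmed,
              n_concentration_dependent = n_dep,
              percent_rmax_at_top = percent_rmax_at_top,
              illbehaved_above = illbehaved_above,
              kd_value = NA_real_, le = NA_real_, t_half_min = NA_real_)
  if (confirmed && !is.null(fit) && isTRUE(fit$converged) &&
      !is.null(fragment) && "heavy_atoms" %in% names(fragment)) {
    s <- summarize_hit(fit, fragment)
    res$kd_value <- s$kd_value
    res$le <- s$le
    res$t_half_min <- s$t_half_min
  }
  structure(res, class = "confirmation_result")
}

#' @export
print.confirmation_result <- function(x, ...) {
  cat(sprintf("confirmation: %s (%d concentration-dependent points, top %%Rmax %.3g)\n",
              if (x$confirmed) "CONFIRMED" else "not confirmed",
              x$n_concentration_dependent, x$percent_rmax_at_top))
  if (!is.na(x$kd_value))
    cat(sprintf("  KD %.4g M, LE %.2f kcal/mol/heavy atom, t1/2 %.2f min\n",
                x$kd_value, x$le, x$t_half_min))
  invisible(x)
}

#' Derived quantities for a confirmed hit
#'
#' Ligand efficiency from the fitted KD and the fragment's heavy-atom
#' count, and the dissociation half-life in minutes from the fitted kd.
#'
#' @param fit A converged [fit_kinetic_1to1()] (or steady-state) result.
#' @param fragment A single-row fragment record with `heavy_atoms` (and
#'   optionally `id`).
#' @param temperature_k Assay temperature, K.
#' @return A list with `fragment_id`, `kd_value` (M), `kd_uM`, `le`,
#'   `t_half_min` (NA for steady-state fits, which carry no rates).
#' @export
summarize_hit <- function(fit, fragment, temperature_k = 298.15) {
  stopifnot(inherits(fit, "spr_fit"))
  if (!isTRUE(fit$converged)) stop("fit did not converge", call. = FALSE)
  nh <- fragment$heavy_atoms
  le <- ligand_efficiency(fit$kd_value, nh, temperature_k)
  t_half_min <- if (!is.null(fit$params)) half_life(fit$params$kd) / 60
  else NA_real_
  list(fragment_id = if ("id" %in% names(fragment)) fragment$id else
    fit$fragment_id,
    kd_value = fit$kd_value, kd_uM = fit$kd_value * 1e6,
    le = le, t_half_min = t_half_min)
}
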