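# Synthetic screens and dose series with the statistical structure the
# downstream analysis assumes: per-sample Gaussian noise, optional baseline
# drift, DMSO bulk-refractive-index steps with a spot-dependent mismatch,
# interleaved buffer blanks and reference-ligand activity probes, and a
# linearly decaying surface-activity factor.

# Evaluate code under a fixed RNG seed without disturbing the caller's state.
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Measurement-noise model for synthetic sensorgrams
#'
#' @param sigma Per-sample Gaussian noise, RU (>= 0).
#' @param baseline_drift Linear baseline drift, RU/s.
#' @param bulk_shift Scale of the DMSO bulk refractive-index step during
#'   injection, RU. Per-cycle bulk steps are drawn uniformly in
#'   `[-bulk_shift, bulk_shift]` on the reference spot; protein spots see
#'   the same step inflated by a small spot-dependent mismatch, which is
#'   what solvent correction estimates and removes.
#' @param seed Integer seed; the same seed reproduces identical output.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(sigma = 0.3, baseline_drift = 0, bulk_shift = 0,
                        seed = NULL) {
  if (sigma < 0) stop("'sigma' must be >= 0", call. = FALSE)
  structure(list(sigma = sigma, baseline_drift = baseline_drift,
                 bulk_shift = bulk_shift, seed = seed),
            class = "noise_model")
}

.ARTIFACT_KINDS <- c("upward_drift", "carryover", "super_stoichiometry",
                     "slow_non11_dissociation")

#' Specification of an ill-behaviour artifact
#'
#' @param kind One of `"upward_drift"` (RU/s ramp during association),
#'   `"carryover"` (RU offset on the pre-injection baseline),
#'   `"super_stoichiometry"` (multiplicative scaling of the binding
#'   response), `"slow_non11_dissociation"` (adds a second, slower
#'   dissociating component of the given magnitude in RU).
#' @param magnitude Artifact magnitude; units depend on `kind`.
#' @return An object of class `artifact_spec`.
#' @export
artifact_spec <- function(kind, magnitude) {
  kind <- match.arg(kind, .ARTIFACT_KINDS)
  stopifnot(is.numeric(magnitude), length(magnitude) == 1L, is.finite(magnitude))
  structure(list(kind = kind, magnitude = magnitude), class = "artifact_spec")
}

#' Design of a single-concentration synthetic screen
#'
#' @param library A fragment table from [generate_library()] (or any data
#'   frame with columns `id` and `mw`).
#' @param screen_conc Screening concentration, M. Default 25 uM.
#' @param planted_binders Named list mapping fragment id to
#'   [kinetic_params()]; these fragments respond on the target spot.
#' @param offtarget_binders Named character vector mapping fragment id to an
#'   off-target spot (`"offtarget_CA"` or `"offtarget_GST"`).
#' @param buffer_every Insert a running-buffer blank after this many
#'   fragment injections. Default 6 (surfaces regenerated after six cycles).
#' @param reference_ligand_every Insert a reference-ligand activity probe
#'   every this many cycles. Default 20.
#' @param activity_decay_total Total fractional loss of surface activity
#'   across the run, applied linearly in cycle index. Default 0.15.
#' @param n_solvent_cycles DMSO solvent-calibration cycles at the start of
#'   the run. Default 8.
#' @param solvent_mismatch Named fractional excess of the bulk step on each
#'   protein spot relative to the reference spot.
#' @param reference_probe [kinetic_params()] of the reference-ligand probe.
#' @param reference_probe_conc Probe concentration, M. Default 20 uM.
#' @param offtarget_params [kinetic_params()] used for planted off-target
#'   binders.
#' @return An object of class `screen_design`.
#' @export
screen_design <- function(library,
                          screen_conc = 25e-6,
                          planted_binders = list(),
                          offtarget_binders = character(0),
                          buffer_every = 6,
                          reference_ligand_every = 20,
                          activity_decay_total = 0.15,
                          n_solvent_cycles = 8,
                          solvent_mismatch = c(target = 0.02,
                                               offtarget_CA = 0.015,
                                               offtarget_GST = 0.025),
                          reference_probe = kinetic_params(1.07e3, 5.8e-3, 60),
                          reference_probe_conc = 20e-6,
                          offtarget_params = kinetic_params(5e3, 2e-2, 30)) {
  stopifnot(is.data.frame(library), all(c("id", "mw") %in% names(library)))
  if (buffer_every < 1 || reference_ligand_every < 1)
    stop("'buffer_every' and 'reference_ligand_every' must be >= 1", call. = FALSE)
  if (activity_decay_total < 0 || activity_decay_total >= 1)
    stop("'activity_decay_total' must be in [0, 1)", call. = FALSE)
  bad <- setdiff(names(planted_binders), library$id)
  if (length(bad))
    stop("planted binders not in library: ", paste(bad, collapse = ", "), call. = FALSE)
  bad <- setdiff(names(offtarget_binders), library$id)
  if (length(bad))
    stop("off-target binders not in library: ", paste(bad, collapse = ", "), call. = FALSE)
  if (length(offtarget_binders) &&
      !all(offtarget_binders %in% c("offtarget_CA", "offtarget_GST")))
    stop("off-target binders must map to an off-target spot", call. = FALSE)
  structure(list(library = library, screen_conc = screen_conc,
                 planted_binders = planted_binders,
                 offtarget_binders = offtarget_binders,
                 buffer_every = buffer_every,
                 reference_ligand_every = reference_ligand_every,
                 activity_decay_total = activity_decay_total,
                 n_solvent_cycles = n_solvent_cycles,
                 solvent_mismatch = solvent_mismatch,
                 reference_probe = reference_probe,
                 reference_probe_conc = reference_probe_conc,
                 offtarget_params = offtarget_params),
            class = "screen_design")
}

#' Generate a synthetic fragment library
#'
#' Draws molecular weight, heavy-atom count, cLogP, TPSA, hydrogen-bond
#' donors/acceptors, rotatable bonds, ring count, solubility and a
#' deterministic pseudo-random fingerprint for `n` fragments. Default
#' distributions centre on a CNS-lead-like fragment library profile
#' (mean MW 250 Da, low cLogP and TPSA).
#'
#' @param n Number of fragments (>= 0).
#' @param seed Integer seed; the same seed gives an identical table.
#' @param profile A list of distribution parameters, see [library_profile()].
#' @return A data frame with one row per fragment; fingerprints are stored
#'   as hex strings (see [fp_from_hex()]).
#' @export
generate_library <- function(n, seed = 1L, profile = library_profile()) {
  stopifnot(n >= 0)
  cols <- c("id", "mw", "heavy_atoms", "clogp", "tpsa", "hbd", "hba",
            "rotatable_bonds", "rings", "solubility", "fingerprint")
  if (n == 0) {
    out <- data.frame(id = character(0), mw = numeric(0),
                      heavy_atoms = integer(0), clogp = numeric(0),
                      tpsa = numeric(0), hbd = integer(0), hba = integer(0),
                      rotatable_bonds = integer(0), rings = integer(0),
                      solubility = numeric(0), fingerprint = character(0),
                      stringsAsFactors = FALSE)
    return(out)
  }
  p <- profile
  .with_seed(seed, {
    mw <- pmin(pmax(stats::rnorm(n, p$mw_mean, p$mw_sd), p$mw_range[1]), p$mw_range[2])
    heavy_atoms <- pmax(8L, as.integer(round(mw / 13.4 + stats::rnorm(n, 0, 1))))
    clogp <- pmin(pmax(stats::rnorm(n, p$clogp_mean, p$clogp_sd),
                       p$clogp_range[1]), p$clogp_range[2])
    tpsa <- pmin(pmax(stats::rnorm(n, p$tpsa_mean, p$tpsa_sd), 0), p$tpsa_max)
    hbd <- stats::rbinom(n, p$hbd_size, p$hbd_p)
    hba <- stats::rbinom(n, p$hba_size, p$hba_p)
    rotb <- stats::rpois(n, p$rotb_lambda)
    rings <- 1L + stats::rbinom(n, p$rings_size, p$rings_p)
    solubility <- stats::rlnorm(n, p$sol_meanlog, p$sol_sdlog)
    nset <- pmin(p$fp_bits, 8L + stats::rpois(n, p$fp_set_mean))
    fps <- vapply(seq_len(n), function(i) {
      bits <- logical(p$fp_bits)
      bits[sample.int(p$fp_bits, nset[i])] <- TRUE
      fp_to_hex(bits)
    }, character(1))
    data.frame(id = sprintf("FRG%05d", seq_len(n)), mw = mw,
               heavy_atoms = heavy_atoms, clogp = clogp, tpsa = tpsa,
               hbd = hbd, hba = hba, rotatable_bonds = rotb, rings = rings,
               solubility = solubility, fingerprint = fps,
               stringsAsFactors = FALSE)
  })
}

#' Distribution parameters for [generate_library()]
#'
#' @param mw_mean,mw_sd,mw_range Molecular weight distribution, Da.
#' @param clogp_mean,clogp_sd,clogp_range Calculated logP distribution.
#' @param tpsa_mean,tpsa_sd,tpsa_max Topological polar surface area, A^2.
#' @param hbd_size,hbd_p,hba_size,hba_p Binomial parameters for
#'   hydrogen-bond donor/acceptor counts.
#' @param rotb_lambda Poisson mean of rotatable bonds.
#' @param rings_size,rings_p Binomial parameters for ring count above 1.
#' @param sol_meanlog,sol_sdlog Log-normal solubility parameters, uM.
#' @param fp_bits Fingerprint length in bits.
#' @param fp_set_mean Poisson mean of set bits above the minimum of 8.
#' @return A named list of parameters.
#' @export
library_profile <- function(mw_mean = 250, mw_sd = 40, mw_range = c(120, 350),
                            clogp_mean = 1.5, clogp_sd = 0.8,
                            clogp_range = c(-1, 3.5),
                            tpsa_mean = 55, tpsa_sd = 18, tpsa_max = 110,
                            hbd_size = 4, hbd_p = 0.35,
                            hba_size = 6, hba_p = 0.4,
                            rotb_lambda = 2,
                            rings_size = 2, rings_p = 0.45,
                            sol_meanlog = log(500), sol_sdlog = 0.8,
                            fp_bits = 256L, fp_set_mean = 10) {
  as.list(environment())
}

# Build the cycle schedule of a screen: solvent-calibration cycles first,
# then fragments with buffer blanks after every `buffer_every` fragments and
# a reference-ligand probe every `reference_ligand_every` cycles.
.screen_schedule <- function(design) {
  n_frag <- nrow(design$library)
  cap <- design$n_solvent_cycles + n_frag +
    ceiling(n_frag / design$buffer_every) +
    ceiling(2 * n_frag / design$reference_ligand_every) + 8L
  role <- character(cap); analyte <- character(cap); conc <- numeric(cap)
  k <- 0L
  emit <- function(r, a, cc) {
    k <<- k + 1L
    role[k] <<- r; analyte[k] <<- a; conc[k] <<- cc
  }
  for (i in seq_len(design$n_solvent_cycles))
    emit("solvent_calibration", "DMSO_cal", 0)
  # opening probe so activity is anchored at the start of screening
  since_probe <- design$reference_ligand_every - 1L
  since_buffer <- 0L
  for (i in seq_len(n_frag)) {
    if (since_probe >= design$reference_ligand_every - 1L) {
      emit("reference_ligand", "REF_PROBE", design$reference_probe_conc)
      since_probe <- 0L
    } else since_probe <- since_probe + 1L
    emit("fragment", design$library$id[i], design$screen_conc)
    since_probe <- since_probe + 1L
    since_buffer <- since_buffer + 1L
    if (since_buffer == design$buffer_every) {
      emit("buffer", "", 0)
      since_probe <- since_probe + 1L
      since_buffer <- 0L
    }
  }
  # closing probe so the activity series brackets the whole run
  emit("reference_ligand", "REF_PROBE", design$reference_probe_conc)
  data.frame(cycle_id = seq_len(k), role = role[seq_len(k)],
             analyte_id = analyte[seq_len(k)], concentration = conc[seq_len(k)],
             stringsAsFactors = FALSE)
}

#' Generate a complete synthetic single-concentration screen
#'
#' Produces one cycle per fragment, monitored on all four spots
#' (target, reference, and the two off-target promiscuity spots), with
#' buffer blanks, DMSO solvent-calibration cycles and reference-ligand
#' activity probes interleaved per the design. Planted binders follow the
#' closed-form 1:1 model scaled by a surface-activity factor that decays
#' linearly by `activity_decay_total` across the run; all other fragments
#' are pure noise.
#'
#' @param design A [screen_design()].
#' @param surface A [surface_model()].
#' @param protocol An [injection_protocol()].
#' @param noise A [noise_model()].
#' @return An object of class `spr_screen`: a shared time grid, a
#'   (time x trace) response matrix, and a per-trace metadata table.
#' @export
generate_screen <- function(design, surface = surface_model(55000),
                            protocol = injection_protocol(),
                            noise = noise_model()) {
  stopifnot(inherits(design, "screen_design"),
            inherits(surface, "surface_model"),
            inherits(protocol, "injection_protocol"),
            inherits(noise, "noise_model"))
  sched <- .screen_schedule(design)
  n_cyc <- nrow(sched)
  spots <- .SENSORGRAM_SPOTS
  n_spots <- length(spots)
  times <- protocol$sample_times
  nt <- length(times)
  t0 <- protocol$baseline_time
  t_stop <- t0 + protocol$contact_time
  inj <- times >= t0 & times <= t_stop

  # activity factor per cycle: 1 at the opening reference probe, decaying
  # linearly to 1 - activity_decay_total at the closing probe
  pr_cyc <- sched$cycle_id[sched$role == "reference_ligand"]
  c_first <- if (length(pr_cyc)) pr_cyc[1] else 1L
  c_last <- if (length(pr_cyc)) pr_cyc[length(pr_cyc)] else n_cyc
  f <- if (c_last > c_first)
    1 - design$activity_decay_total *
      pmax(0, sched$cycle_id - c_first) / (c_last - c_first)
  else rep(1, n_cyc)

  meta <- data.frame(
    cycle_id = rep(sched$cycle_id, each = n_spots),
    role = rep(sched$role, each = n_spots),
    analyte_id = rep(sched$analyte_id, each = n_spots),
    concentration = rep(sched$concentration, each = n_spots),
    spot = rep(spots, times = n_cyc),
    activity_factor = rep(f, each = n_spots),
    stringsAsFactors = FALSE)
  n_traces <- nrow(meta)

  .with_seed(noise$seed, {
    traces <- matrix(stats::rnorm(nt * n_traces, 0, noise$sigma), nt, n_traces)
    if (noise$baseline_drift != 0)
      traces <- traces + noise$baseline_drift * times

    # DMSO bulk steps during injection; solvent cycles span the range
    bulk <- numeric(n_cyc)
    is_sample <- sched$role %in% c("fragment", "dose_point")
    bulk[is_sample] <- stats::runif(sum(is_sample), -1, 1) * noise$bulk_shift
    is_cal <- sched$role == "solvent_calibration"
    if (any(is_cal))
      bulk[is_cal] <- seq(-1.5, 1.5, length.out = sum(is_cal)) * noise$bulk_shift
    mism <- c(target = 0, reference = 0, offtarget_CA = 0, offtarget_GST = 0)
    mm <- design$solvent_mismatch
    mism[names(mm)] <- mm
    bulk_trace <- bulk[meta$cycle_id] * (1 + mism[meta$spot])
    nz <- which(bulk_trace != 0)
    if (length(nz))
      traces[inj, nz] <- traces[inj, nz] +
        rep(bulk_trace[nz], each = sum(inj))

    col_of <- function(cycle, spot)
      (cycle - 1L) * n_spots + match(spot, spots)

    # reference-ligand probes on the target spot
    probe_sig <- model_response_1to1(times, design$reference_probe$ka,
                                     design$reference_probe$kd,
                                     design$reference_probe$rmax,
                                     design$reference_probe_conc, t0, t_stop)
    for (cyc in sched$cycle_id[sched$role == "reference_ligand"]) {
      j <- col_of(cyc, "target")
      traces[, j] <- traces[, j] + probe_sig * f[cyc]
    }

    # planted binders on the target spot
    for (fid in names(design$planted_binders)) {
      cyc <- sched$cycle_id[sched$role == "fragment" & sched$analyte_id == fid]
      pp <- design$planted_binders[[fid]]
      sig <- model_response_1to1(times, pp$ka, pp$kd, pp$rmax,
                                 design$screen_conc, t0, t_stop)
      for (cc in cyc) {
        j <- col_of(cc, "target")
        traces[, j] <- traces[, j] + sig * f[cc]
      }
    }

    # planted promiscuous binders on their off-target spot
    for (fid in names(design$offtarget_binders)) {
      cyc <- sched$cycle_id[sched$role == "fragment" & sched$analyte_id == fid]
      op <- design$offtarget_params
      sig <- model_response_1to1(times, op$ka, op$kd, op$rmax,
                                 design$screen_conc, t0, t_stop)
      for (cc in cyc) {
        j <- col_of(cc, design$offtarget_binders[[fid]])
        traces[, j] <- traces[, j] + sig
      }
    }

    structure(list(times = times, traces = traces, meta = meta,
                   protocol = protocol, t_inject = t0, t_stop = t_stop,
                   bulk = bulk),
              class = "spr_screen")
  })
}

#' @export
print.spr_screen <- function(x, ...) {
  tab <- table(x$meta$role[x$meta$spot == "target"])
  cat(sprintf("spr_screen: %d cycles x %d spots, %d samples/cycle\n",
              nrow(x$meta) / length(unique(x$meta$spot)),
              length(unique(x$meta$spot)), length(x$times)))
  cat("  cycles by role:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Extract one cycle/spot trace from a screen as a sensorgram
#'
#' @param screen An `spr_screen`.
#' @param cycle_id Cycle identifier.
#' @param spot Spot name.
#' @return A [sensorgram()].
#' @export
get_sensorgram <- function(screen, cycle_id, spot = "target") {
  stopifnot(inherits(screen, "spr_screen"))
  j <- which(screen$meta$cycle_id == cycle_id & screen$meta$spot == spot)
  if (length(j) != 1L)
    stop("no unique trace for cycle ", cycle_id, " spot ", spot, call. = FALSE)
  m <- screen$meta[j, ]
  sensorgram(screen$times, screen$traces[, j], cycle_id = m$cycle_id,
             role = m$role, analyte_id = m$analyte_id,
             concentration = m$concentration, spot = m$spot,
             t_inject = screen$t_inject, t_stop = screen$t_stop)
}

#' Generate a dose-response concentration series
#'
#' One cycle per concentration under the closed-form 1:1 model plus the
#' noise model. With `sigma = 0` the series is exactly the model, so a
#' round-trip fit recovers the generating parameters.
#'
#' @param params A [kinetic_params()].
#' @param concentrations Analyte concentrations, M (non-empty for a series;
#'   an empty vector returns an empty list).
#' @param protocol An [injection_protocol()].
#' @param noise A [noise_model()].
#' @param analyte_id Analyte identifier carried in the metadata.
#' @return A list of [sensorgram()]s, one per concentration, in input order.
#' @export
generate_dose_series <- function(params, concentrations,
                                 protocol = injection_protocol(),
                                 noise = noise_model(sigma = 0),
                                 analyte_id = "analyte") {
  stopifnot(inherits(params, "kinetic_params"),
            inherits(protocol, "injection_protocol"),
            inherits(noise, "noise_model"))
  if (length(concentrations) == 0) return(list())
  .with_seed(noise$seed, {
    lapply(seq_along(concentrations), function(i) {
      s <- simulate_cycle(params, concentrations[i], protocol,
                          cycle_id = i, role = "dose_point",
                          analyte_id = analyte_id)
      if (noise$sigma > 0)
        s$responses <- s$responses + stats::rnorm(length(s$responses), 0, noise$sigma)
      if (noise$baseline_drift != 0)
        s$responses <- s$responses + noise$baseline_drift * s$times
      s
    })
  })
}

#' Inject an ill-behaviour artifact into a sensorgram
#'
#' @param s A [sensorgram()] with injection timing metadata.
#' @param spec An [artifact_spec()].
#' @return The modified sensorgram.
#' @export
apply_artifact <- function(s, spec) {
  stopifnot(inherits(s, "sensorgram"), inherits(spec, "artifact_spec"))
  if (is.na(s$t_inject) || is.na(s$t_stop))
    stop("sensorgram lacks injection timing metadata", call. = FALSE)
  if (spec$magnitude == 0) return(s)
  t <- s$times
  assoc <- t >= s$t_inject & t <= s$t_stop
  pre <- t < s$t_inject
  post <- t > s$t_stop
  s$responses <- switch(spec$kind,
    upward_drift = {
      # ramp during the association phase only; dissociation untouched
      r <- s$responses
      r[assoc] <- r[assoc] + spec$magnitude * (t[assoc] - s$t_inject)
      r
    },
    carryover = {
      r <- s$responses
      r[pre] <- r[pre] + spec$magnitude
      r
    },
    super_stoichiometry = {
      r <- s$responses
      r[assoc | post] <- r[assoc | post] * spec$magnitude
      r
    },
    slow_non11_dissociation = {
      # mix a slower exponential (2e-3 s^-1) into the dissociation phase;
      # magnitude is the mixing fraction in [0, 1], continuous at t_stop
      if (spec$magnitude < 0 || spec$magnitude > 1)
        stop("slow_non11_dissociation magnitude is a mixing fraction in [0, 1]",
             call. = FALSE)
      r <- s$responses
      slow_kd <- 2e-3
      i_stop <- which(t <= s$t_stop)
      r_stop <- r[i_stop[length(i_stop)]]
      r[post] <- (1 - spec$magnitude) * r[post] +
        spec$magnitude * r_stop * exp(-slow_kd * (t[post] - s$t_stop))
      r
    })
  s
}
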