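# Readers and writers for the shared tabular formats (long sensorgram
# tables, plate/cycle maps, fragment tables, report tables) and the YAML
# run configuration. Simulated screens are written in exactly the formats
# the readers consume, so they are indistinguishable from imported runs.

.SG_COLUMNS <- c("cycle_id", "spot", "role", "analyte_id", "concentration_M",
                 "time_s", "response_RU")

#' Write sensorgrams as a long delimited table
#'
#' One row per time point with columns `cycle_id, spot, role, analyte_id,
#' concentration_M, time_s, response_RU`. Concentrations are stored in
#' molar units.
#'
#' @param x An `spr_screen` or a list of [sensorgram()]s.
#' @param path Output file (.csv).
#' @return `path`, invisibly.
#' @export
write_sensorgram_table <- function(x, path) {
  if (inherits(x, "spr_screen")) {
    nt <- length(x$times)
    dt <- data.table::data.table(
      cycle_id = rep(x$meta$cycle_id, each = nt),
      spot = rep(x$meta$spot, each = nt),
      role = rep(x$meta$role, each = nt),
      analyte_id = rep(x$meta$analyte_id, each = nt),
      concentration_M = rep(x$meta$concentration, each = nt),
      time_s = rep(x$times, times = nrow(x$meta)),
      response_RU = as.vector(x$traces))
  } else {
    stopifnot(all(vapply(x, inherits, logical(1), "sensorgram")))
    dt <- data.table::rbindlist(lapply(x, function(s)
      data.table::data.table(cycle_id = s$cycle_id, spot = s$spot,
                             role = s$role, analyte_id = s$analyte_id,
                             concentration_M = s$concentration,
                             time_s = s$times, response_RU = s$responses)))
  }
  data.table::fwrite(dt, path)
  invisible(path)
}

#' Read a long sensorgram table
#'
#' Strictly validates the header, the role/spot vocabularies and time
#' monotonicity within each (cycle, spot) trace; violations raise an error
#' naming the offending row or trace.
#'
#' @param path Input file from [write_sensorgram_table()].
#' @param protocol Optional [injection_protocol()]; when given, injection
#'   timing is attached to every sensorgram.
#' @return A list of [sensorgram()]s (row order within the file does not
#'   affect the grouped result).
#' @export
read_sensorgram_table <- function(path, protocol = NULL) {
  dt <- data.table::fread(path)
  missing_cols <- setdiff(.SG_COLUMNS, names(dt))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "), call. = FALSE)
  for (cc in c("cycle_id", "spot", "role", "analyte_id"))
    data.table::set(dt, j = cc, value = as.character(dt[[cc]]))
  bad <- which(!dt$role %in% .SENSORGRAM_ROLES)
  if (length(bad))
    stop("unknown role '", dt$role[bad[1]], "' at row ", bad[1], call. = FALSE)
  bad <- which(!dt$spot %in% .SENSORGRAM_SPOTS)
  if (length(bad))
    stop("unknown spot '", dt$spot[bad[1]], "' at row ", bad[1], call. = FALSE)
  bad <- which(dt$concentration_M < 0)
  if (length(bad))
    stop("negative concentration at row ", bad[1], call. = FALSE)
  t0 <- if (!is.null(protocol)) protocol$baseline_time else NA_real_
  ts <- if (!is.null(protocol)) protocol$baseline_time + protocol$contact_time
  else NA_real_
  data.table::setorder(dt, cycle_id, spot, time_s)
  groups <- split(dt, by = c("cycle_id", "spot"), sorted = TRUE)
  out <- lapply(groups, function(g) {
    if (any(diff(g$time_s) <= 0))
      stop("non-monotone time in cycle ", g$cycle_id[1], " spot ", g$spot[1],
           call. = FALSE)
    sensorgram(g$time_s, g$response_RU, cycle_id = g$cycle_id[1],
               role = g$role[1], analyte_id = g$analyte_id[1],
               concentration = g$concentration_M[1], spot = g$spot[1],
               t_inject = t0, t_stop = ts)
  })
  names(out) <- NULL
  out
}

#' Assemble sensorgrams sharing a time grid into a screen container
#'
#' @param sensorgrams List of [sensorgram()]s on one common grid; every
#'   cycle must carry the same set of spots (including `"reference"`).
#' @param protocol Optional [injection_protocol()] supplying injection
#'   timing when the sensorgrams carry none.
#' @return An `spr_screen`.
#' @export
screen_from_sensorgrams <- function(sensorgrams, protocol = NULL) {
  stopifnot(length(sensorgrams) >= 1,
            all(vapply(sensorgrams, inherits, logical(1), "sensorgram")))
  times <- sensorgrams[[1]]$times
  for (s in sensorgrams)
    if (length(s$times) != length(times) || any(s$times != times))
      stop("sensorgrams are not on a common time grid", call. = FALSE)
  meta <- data.frame(
    cycle_id = vapply(sensorgrams, function(s) as.character(s$cycle_id), character(1)),
    role = vapply(sensorgrams, `[[`, character(1), "role"),
    analyte_id = vapply(sensorgrams, `[[`, character(1), "analyte_id"),
    concentration = vapply(sensorgrams, `[[`, numeric(1), "concentration"),
    spot = vapply(sensorgrams, `[[`, character(1), "spot"),
    stringsAsFactors = FALSE)
  spots <- sort(unique(meta$spot))
  per_cycle <- table(meta$cycle_id)
  if (any(per_cycle != length(spots)))
    stop("every cycle must carry the same set of spots", call. = FALSE)
  spot_order <- intersect(.SENSORGRAM_SPOTS, spots)
  ids <- unique(meta$cycle_id)
  num <- suppressWarnings(as.numeric(ids))
  if (!anyNA(num)) ids <- ids[order(num)]  # restore run order for numeric ids
  o <- order(match(meta$cycle_id, ids), match(meta$spot, spot_order))
  meta <- meta[o, ]
  meta$activity_factor <- NA_real_
  traces <- vapply(sensorgrams[o], `[[`, numeric(length(times)), "responses")
  t0 <- sensorgrams[[1]]$t_inject
  ts <- sensorgrams[[1]]$t_stop
  if ((is.na(t0) || is.na(ts)) && !is.null(protocol)) {
    t0 <- protocol$baseline_time
    ts <- protocol$baseline_time + protocol$contact_time
  }
  if (is.na(t0) || is.na(ts))
    stop("injection timing unknown: supply a protocol", call. = FALSE)
  structure(list(times = times, traces = traces, meta = meta,
                 protocol = protocol, t_inject = t0, t_stop = ts),
            class = "spr_screen")
}

#' Write / read the plate (cycle) map of a screen
#'
#' Per-cycle metadata: `cycle_id, role, analyte_id, concentration_M`.
#'
#' @param screen An `spr_screen`.
#' @param path File path (.csv).
#' @return `path` (writer) or a data frame (reader).
#' @export
write_plate_map <- function(screen, path) {
  m <- screen$meta[screen$meta$spot == screen$meta$spot[1], ]
  data.table::fwrite(data.table::data.table(
    cycle_id = m$cycle_id, role = m$role, analyte_id = m$analyte_id,
    concentration_M = m$concentration), path)
  invisible(path)
}

#' @rdname write_plate_map
#' @export
read_plate_map <- function(path) {
  as.data.frame(data.table::fread(path, colClasses = list(
    character = c("cycle_id", "role", "analyte_id"))))
}

#' Write / read a fragment table
#'
#' Comma-separated with a header; fingerprints as hex strings.
#'
#' @param library Fragment table (see [generate_library()]).
#' @param path File path (.csv).
#' @return `path` (writer) or the fragment data frame (reader).
#' @export
write_fragment_table <- function(library, path) {
  data.table::fwrite(data.table::as.data.table(library), path)
  invisible(path)
}

#' @rdname write_fragment_table
#' @export
read_fragment_table <- function(path) {
  cc <- list(character = c("id", "fingerprint"))
  as.data.frame(data.table::fread(path, colClasses = cc))
}

#' Write the screen report files
#'
#' Writes a tab-separated hit table with stable column order (fragment id,
#' raw RU, corrected RU, %Rmax, QC flags, verdicts), an optional
#' tab-separated confirmation table, and a YAML run summary carrying
#' counts, both hit-rate conventions, thresholds and the activity-decay
#' endpoints.
#'
#' @param analysis A [process_screen()] result.
#' @param confirmations Optional data frame of confirmation results (one
#'   row per fragment).
#' @param outdir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_reports <- function(analysis, confirmations = NULL, outdir) {
  stopifnot(inherits(analysis, "screen_analysis"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cols <- c("fragment_id", "raw_level", "corrected_level", "percent_rmax",
            "qc_upward_drift", "qc_carryover", "qc_super_stoichiometry",
            "qc_non11_dissociation", "is_hit", "promiscuous")
  hit_path <- file.path(outdir, "hit_table.tsv")
  data.table::fwrite(data.table::as.data.table(analysis$records[cols]),
                     hit_path, sep = "\t")
  files <- c(hit_table = hit_path)
  if (!is.null(confirmations)) {
    conf_path <- file.path(outdir, "confirmation_table.tsv")
    data.table::fwrite(data.table::as.data.table(confirmations), conf_path,
                       sep = "\t")
    files <- c(files, confirmation_table = conf_path)
  }
  sum_path <- file.path(outdir, "run_summary.yaml")
  yaml::write_yaml(analysis$summary, sum_path)
  files <- c(files, run_summary = sum_path)
  invisible(files)
}

#' Default run configuration
#'
#' Every tunable threshold of the pipeline with its default, as one
#' serialisable list. A run is reproducible from its configuration plus the
#' seed.
#'
#' @return A nested named list.
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    n_fragments = 100L,
    screen_conc_M = 25e-6,
    surface = list(protein_mw = 55000, capture_level = 16000,
                   stoichiometry = 1, activity_fraction = 0.9),
    protocol = list(contact_time = 50, dissociation_time = 60,
                    baseline_time = 10, flow_rate = 30, sample_hz = 1),
    noise = list(sigma = 0.3, baseline_drift = 0, bulk_shift = 0),
    design = list(buffer_every = 6L, reference_ligand_every = 20L,
                  activity_decay_total = 0.15, n_solvent_cycles = 8L),
    qc = qc_thresholds(),
    confirmation = list(min_concentrations = 3L, min_percent_rmax = 10,
                        top_conc_M = 50e-6, n_dilutions = 6L,
                        dilution_factor = 2),
    library = list(tanimoto_cutoff = 0.85, solubility_min = 100)
  )
}

#' Write / read a run configuration (YAML)
#'
#' @param config A configuration list (see [default_run_config()]).
#' @param path File path (.yaml).
#' @return `path` (writer) or the configuration list (reader).
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  utils::modifyList(default_run_config(), cfg)
}

# Construct model objects from a configuration list.
.cfg_surface <- function(cfg) do.call(surface_model, cfg$surface)
.cfg_protocol <- function(cfg) do.call(injection_protocol, cfg$protocol)
.cfg_noise <- function(cfg)
  noise_model(cfg$noise$sigma, cfg$noise$baseline_drift,
              cfg$noise$bulk_shift, seed = cfg$seed)
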