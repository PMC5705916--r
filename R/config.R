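# Run configuration: key-value config files, validation, structured output.

.scenarios <- c("batch", "transfer", "fedbatch", "scan:affinity",
                "scan:excretion", "scan:inoculum", "critical-ratio")

# Scenario-level keys accepted in configs and --set overrides, with
# defaults. Parameter fields (K_A, R_A, ...) are additionally accepted
# verbatim; initial-state components use dotted keys init.Ec, init.G, ...
.config_defaults <- list(
  scenario = "batch",
  variant = "default",          # model variant
  duration = 300,               # batch duration, h
  grid_dt = 1,                  # output grid spacing, h
  affinity_ratio = 1,           # Rp:Ec NH4+ affinity ratio (sets K_A/K_AR)
  n_transfers = 8,
  dilution_fraction = 0.01,
  batch_duration = 300,
  carry_solutes = TRUE,
  pulse_increment = 0.005,      # mM per NH4+ pulse
  feed_duration = 96,           # h
  ratios = NULL,                # scan grid (affinity or inoculum scans)
  RA_values = NULL,             # excretion scan grid, fmol/cell
  criterion = "batch_net_growth",
  bounds = c(0.1, 10),
  tol = 0.05,
  rtol = 1e-8)

.default_init_by_scenario <- function(scenario) {
  if (scenario == "fedbatch") {
    culture_state(Ec = 1e7, Rp = 1e7, G = 25, C = 20)
  } else {
    default_inoculum()
  }
}

#' Load and validate a run configuration
#'
#' Accepts either a JSON document or a flat `key: value` / `key = value`
#' text file (one pair per line, `#` comments allowed). Recognised keys are
#' the scenario settings (`scenario`, `variant`, `duration`, `grid_dt`,
#' `affinity_ratio`, `n_transfers`, `dilution_fraction`, `batch_duration`,
#' `carry_solutes`, `pulse_increment`, `feed_duration`, `ratios`,
#' `RA_values`, `criterion`, `bounds`, `tol`, `rtol`), every parameter
#' field of [syn_params()] verbatim (e.g. `K_A`, `R_A`), and initial-state
#' components as dotted keys (`init.Ec`, `init.G`, ...). Unknown keys are
#' rejected; an empty file resolves to all defaults (300-h default-variant
#' batch at affinity ratio 1).
#'
#' If the config sets `affinity_ratio`, it is applied through
#' [set_affinity_ratio()] after any explicit `K_A`/`K_AR` overrides (an
#' explicit half-saturation override therefore loses to an explicit ratio;
#' set one or the other).
#'
#' @param path config file path.
#' @param overrides named list applied on top of the file (used by the CLI
#'   for `--set key=value`).
#' @return a `syn_run_config`: scenario settings, resolved `syn_params`,
#'   initial state, and the raw key-value map.
#' @export
load_config <- function(path = NULL, overrides = NULL) {
  kv <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path,
                                 call. = FALSE)
    txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
    kv <- if (grepl("^\\s*\\{", txt)) {
      jsonlite::fromJSON(txt, simplifyVector = TRUE)
    } else {
      .parse_flat_config(txt)
    }
  }
  if (!is.null(overrides)) kv <- modifyList(kv, overrides)
  .resolve_config(kv)
}

.parse_flat_config <- function(txt) {
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z_.][A-Za-z0-9_.]*)\\s*[:=]\\s*(.*)$",
                                ln))[[1]]
    if (length(m) != 3) stop("cannot parse config line: '", ln, "'",
                             call. = FALSE)
    kv[[m[2]]] <- .parse_config_value(trimws(m[3]))
  }
  kv
}

.parse_config_value <- function(v) {
  if (v %in% c("true", "TRUE", "True")) return(TRUE)
  if (v %in% c("false", "FALSE", "False")) return(FALSE)
  # comma-separated numeric lists for scan grids
  parts <- trimws(strsplit(v, ",", fixed = TRUE)[[1]])
  nums <- suppressWarnings(as.numeric(parts))
  if (length(nums) > 0 && !any(is.na(nums))) {
    return(if (length(nums) == 1) nums[[1]] else nums)
  }
  v
}

.resolve_config <- function(kv) {
  if (is.null(names(kv))) names(kv) <- character(length(kv))
  kv <- kv[nzchar(names(kv))]
  known_scenario <- names(.config_defaults)
  known_params <- names(.param_defaults)
  init_keys <- names(kv)[startsWith(names(kv), "init.")]
  unknown <- setdiff(names(kv), c(known_scenario, known_params, init_keys))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (k in init_keys) {
    comp <- sub("^init\\.", "", k)
    if (!comp %in% STATE_NAMES) {
      stop("unknown initial-state component in key '", k, "'", call. = FALSE)
    }
  }

  settings <- modifyList(.config_defaults,
                         kv[intersect(names(kv), known_scenario)])
  if (!settings$scenario %in% .scenarios) {
    stop("unknown scenario '", settings$scenario, "'; must be one of: ",
         paste(.scenarios, collapse = ", "), call. = FALSE)
  }
  if (!settings$variant %in% c("default", "communal")) {
    stop("variant must be 'default' or 'communal'", call. = FALSE)
  }

  params <- syn_params(overrides = kv[intersect(names(kv), known_params)])
  validate_params(params)
  ratio_explicit <- "affinity_ratio" %in% names(kv)
  if (ratio_explicit) {
    params <- set_affinity_ratio(params, settings$affinity_ratio)
  }

  init <- .default_init_by_scenario(settings$scenario)
  for (k in init_keys) {
    init[[sub("^init\\.", "", k)]] <- as.numeric(kv[[k]])
  }
  validate_state(init)

  structure(list(settings = settings, params = params, init = init,
                 raw = kv), class = "syn_run_config")
}

# Fully resolved key-value view of a config (defaults + overrides +
# provenance), written as the JSON sidecar next to every run's results so
# that a run can be reproduced from its own output.
.config_manifest <- function(config, extra = NULL) {
  c(list(settings = config$settings,
         params = config$params[names(.param_defaults)],
         param_provenance = as.list(attr(config$params, "provenance")),
         init = as.list(config$init),
         deterministic = "model has no random component; no seed applies"),
    extra)
}

#' Write a trajectory as CSV plus a JSON sidecar
#'
#' One row per time point, one column per state variable; the header names
#' carry units (`time_h`, `Ec_cells_per_ml`, ..., `G_mM`, ...).
#'
#' @param traj a `syn_trajectory`.
#' @param path output CSV path; the sidecar is written next to it as
#'   `<path>.meta.json`.
#' @param sidecar named list of run metadata to include.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path, sidecar = list()) {
  df <- as.data.frame(traj)
  names(df) <- c("time_h", "Ec_cells_per_ml", "Rp_cells_per_ml", "G_mM",
                 "A_mM", "C_mM", "F_mM", "E_mM", "H_mM")
  write.csv(df, path, row.names = FALSE)
  meta <- c(list(variant = traj$variant,
                 params = traj$params[names(.param_defaults)],
                 param_provenance = as.list(attr(traj$params, "provenance")),
                 integrator = traj$diagnostics,
                 deterministic = "model has no random component; no seed applies"),
            sidecar)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a scan table as CSV plus a JSON sidecar
#'
#' @param scan a `syn_scan_table`.
#' @param path output CSV path.
#' @param sidecar extra metadata for the sidecar JSON.
#' @return `path`, invisibly.
#' @export
write_scan_csv <- function(scan, path, sidecar = list()) {
  tab <- scan$table
  names(tab)[names(tab) == "Ec_final"] <- "Ec_final_cells_per_ml"
  names(tab)[names(tab) == "Rp_final"] <- "Rp_final_cells_per_ml"
  write.csv(tab, path, row.names = FALSE)
  meta <- c(list(scan_param = scan$scan_param, variant = scan$variant,
                 params = scan$params[names(.param_defaults)],
                 param_provenance = as.list(attr(scan$params, "provenance"))),
            sidecar)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a serial-transfer series as CSV plus a JSON sidecar
#'
#' The CSV holds the per-transfer summary (initial/final densities, final
#' % E. coli); full per-transfer trajectories are written alongside when
#' `full = TRUE`.
#'
#' @param series a `syn_transfer_series`.
#' @param path output CSV path for the summary.
#' @param full also write `<path stem>_transfer<k>.csv` trajectories.
#' @param sidecar extra metadata.
#' @return `path`, invisibly.
#' @export
write_transfer_csv <- function(series, path, full = FALSE, sidecar = list()) {
  s <- series$summary
  names(s) <- c("transfer", "Ec_initial_cells_per_ml",
                "Rp_initial_cells_per_ml", "Ec_final_cells_per_ml",
                "Rp_final_cells_per_ml", "pct_Ec_final")
  write.csv(s, path, row.names = FALSE)
  if (full) {
    stem <- sub("\\.csv$", "", path)
    for (k in seq_along(series$trajectories)) {
      write_trajectory_csv(series$trajectories[[k]],
                           sprintf("%s_transfer%02d.csv", stem, k))
    }
  }
  meta <- c(list(variant = series$variant,
                 protocol = series$protocol[c("batch_duration",
                                              "dilution_fraction",
                                              "n_transfers", "carry_solutes")],
                 params = series$params[names(.param_defaults)],
                 param_provenance = as.list(attr(series$params, "provenance"))),
            sidecar)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
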