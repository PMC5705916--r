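# Simulation drivers: single batch, serial transfer, pulsed fed-batch.

#' Default batch inoculum
#'
#' Standard starting condition: a 1% dilution of a stationary coculture of
#' total density 1e9 cells/ml containing 10% E. coli, inoculated into fresh
#' medium with 25 mM glucose. The stationary composition is the
#' experimentally observed one; the absolute total density is part of the
#' shipped calibration.
#'
#' @param total stationary total density before dilution, cells/ml.
#' @param pct_Ec E. coli fraction of the stationary coculture (0..1).
#' @param dilution dilution fraction at inoculation.
#' @param G glucose in fresh medium, mM.
#' @return a culture state vector.
#' @export
default_inoculum <- function(total = 1e9, pct_Ec = 0.10, dilution = 0.01,
                             G = 25) {
  culture_state(Ec = total * pct_Ec * dilution,
                Rp = total * (1 - pct_Ec) * dilution, G = G)
}

.new_trajectory <- function(times, states, variant, params, diagnostics,
                            clamp_floor = 0) {
  colnames(states) <- STATE_NAMES
  structure(list(times = times, states = states, variant = variant,
                 params = params, diagnostics = diagnostics),
            class = "syn_trajectory")
}

#' @export
print.syn_trajectory <- function(x, ...) {
  n <- length(x$times)
  fin <- x$states[n, ]
  cat(sprintf("<syn_trajectory> %s variant, %g h, %d time points\n",
              x$variant, x$times[n], n))
  cat(sprintf("  final: Ec=%.3g Rp=%.3g cells/ml | G=%.3g A=%.3g C=%.3g F=%.3g E=%.3g H=%.3g mM\n",
              fin[["Ec"]], fin[["Rp"]], fin[["G"]], fin[["A"]], fin[["C"]],
              fin[["F"]], fin[["E"]], fin[["H"]]))
  d <- x$diagnostics
  cat(sprintf("  integrator: %d steps, %d rejected, %d clamping events\n",
              d$steps, d$rejected, d$clamped))
  invisible(x)
}

#' @export
as.data.frame.syn_trajectory <- function(x, ...) {
  data.frame(time_h = x$times, x$states, check.names = FALSE)
}

#' Final state of a trajectory
#' @param traj a `syn_trajectory`.
#' @return named state vector at the last time point.
#' @export
final_state <- function(traj) {
  traj$states[nrow(traj$states), ]
}

#' Initial state of a trajectory
#' @param traj a `syn_trajectory`.
#' @return named state vector at the first time point.
#' @export
initial_state <- function(traj) {
  traj$states[1, ]
}

#' Simulate a single batch culture
#'
#' Integrates the chosen model variant from `init` for `duration` hours with
#' an adaptive embedded Runge-Kutta method (compiled), recording the state
#' on a regular output grid. The model is deterministic: no randomness
#' enters anywhere. States are clamped at zero (small integrator
#' undershoots) and clamping events are counted in the diagnostics.
#'
#' @param params `syn_params`.
#' @param init named initial state (see [culture_state()],
#'   [default_inoculum()]).
#' @param duration batch duration, h (> 0). The standard protocol is 300 h:
#'   glucose is typically exhausted by ~100 h, but slower-emerging trends
#'   need the longer window.
#' @param variant `"default"` or `"communal"`.
#' @param grid_dt output grid spacing, h (default 1 h; internal steps are
#'   adaptive and unrelated to this grid).
#' @param rtol relative tolerance of the step-size control.
#' @param atol_cells,atol_conc absolute tolerances for cell densities
#'   (cells/ml) and dissolved species (mM).
#' @param max_steps hard cap on internal steps before the integrator gives
#'   up with an error.
#' @return a `syn_trajectory`: times, state matrix, variant, parameters and
#'   integrator diagnostics.
#' @export
simulate_batch <- function(params, init = default_inoculum(), duration = 300,
                           variant = c("default", "communal"), grid_dt = 1,
                           rtol = 1e-8, atol_cells = 1e-2, atol_conc = 1e-12,
                           max_steps = 5e6) {
  variant <- match.arg(variant)
  if (!is.numeric(duration) || length(duration) != 1 || duration <= 0) {
    stop("duration must be a single value > 0", call. = FALSE)
  }
  validate_state(init)
  pvec <- .params_to_vector(params)
  times <- seq(0, duration, by = grid_dt)
  if (times[length(times)] < duration) times <- c(times, duration)

  res <- .integrate_cpp(as.numeric(init[STATE_NAMES]), pvec,
                        variant == "communal", times, rtol, atol_cells,
                        atol_conc, max_steps)
  if (!isTRUE(res$completed)) {
    stop("integration failed: ", res$message,
         sprintf(" [steps=%d rejected=%d]", as.integer(res$steps),
                 as.integer(res$rejected)), call. = FALSE)
  }
  .new_trajectory(times, res$states, variant, params,
                  list(steps = as.integer(res$steps),
                       rejected = as.integer(res$rejected),
                       clamped = as.integer(res$clamped),
                       rtol = rtol))
}

#' Serial-transfer protocol description
#'
#' @param batch_duration duration of each batch, h.
#' @param dilution_fraction fraction of the culture carried into fresh
#'   medium at each transfer (1% inoculum by default).
#' @param n_transfers number of batches simulated (>= 1).
#' @param fresh_medium state vector of the fresh medium (default 25 mM
#'   glucose, everything else zero, no cells).
#' @param carry_solutes if `TRUE` (default) dissolved species are carried
#'   over with the inoculum: `new = d * old_final + (1 - d) * fresh`,
#'   matching the physical transfer of a culture volume. If `FALSE`, each
#'   transfer resets solutes to the fresh medium (cells still diluted).
#' @return a `syn_transfer_protocol` list.
#' @export
transfer_protocol <- function(batch_duration = 300, dilution_fraction = 0.01,
                              n_transfers = 8,
                              fresh_medium = culture_state(G = 25),
                              carry_solutes = TRUE) {
  if (!(dilution_fraction > 0 && dilution_fraction <= 1)) {
    stop("dilution_fraction must be in (0, 1]", call. = FALSE)
  }
  if (batch_duration <= 0) stop("batch_duration must be > 0", call. = FALSE)
  if (n_transfers < 1) stop("n_transfers must be >= 1", call. = FALSE)
  validate_state(fresh_medium)
  structure(list(batch_duration = batch_duration,
                 dilution_fraction = dilution_fraction,
                 n_transfers = n_transfers, fresh_medium = fresh_medium,
                 carry_solutes = isTRUE(carry_solutes)),
            class = "syn_transfer_protocol")
}

#' Serially transfer a batch coculture
#'
#' Repeats [simulate_batch()] `n_transfers` times. After each batch, cells
#' are diluted by `dilution_fraction` into fresh medium; dissolved species
#' follow the carryover rule of the protocol. Declining per-transfer final
#' densities of both species are the signature of mutualism collapse.
#'
#' @param params `syn_params`.
#' @param init initial state of the first batch.
#' @param protocol a [transfer_protocol()].
#' @param variant `"default"` or `"communal"`.
#' @param ... passed on to [simulate_batch()] (tolerances, grid).
#' @return a `syn_transfer_series`: list of trajectories plus a per-transfer
#'   summary data frame (initial/final densities of each species and final
#'   % E. coli).
#' @export
serial_transfer <- function(params, init = default_inoculum(),
                            protocol = transfer_protocol(),
                            variant = c("default", "communal"), ...) {
  variant <- match.arg(variant)
  if (!inherits(protocol, "syn_transfer_protocol")) {
    stop("protocol must be created with transfer_protocol()", call. = FALSE)
  }
  trajs <- vector("list", protocol$n_transfers)
  state <- init
  rows <- vector("list", protocol$n_transfers)
  for (k in seq_len(protocol$n_transfers)) {
    traj <- tryCatch(
      simulate_batch(params, state, protocol$batch_duration, variant, ...),
      error = function(e) {
        stop("transfer ", k, ": ", conditionMessage(e), call. = FALSE)
      })
    trajs[[k]] <- traj
    fin <- final_state(traj)
    rows[[k]] <- data.frame(
      transfer = k, Ec_initial = state[["Ec"]], Rp_initial = state[["Rp"]],
      Ec_final = fin[["Ec"]], Rp_final = fin[["Rp"]],
      pct_Ec_final = 100 * fin[["Ec"]] / max(fin[["Ec"]] + fin[["Rp"]],
                                             .Machine$double.xmin))
    state <- .transfer_carryover(fin, protocol)
  }
  structure(list(trajectories = trajs, summary = do.call(rbind, rows),
                 protocol = protocol, variant = variant, params = params),
            class = "syn_transfer_series")
}

# Dilution bookkeeping between batches: exact scaling, no integration.
.transfer_carryover <- function(final, protocol) {
  d <- protocol$dilution_fraction
  fresh <- protocol$fresh_medium
  s <- final
  s[c("Ec", "Rp")] <- d * final[c("Ec", "Rp")]
  solutes <- setdiff(STATE_NAMES, c("Ec", "Rp"))
  if (protocol$carry_solutes) {
    s[solutes] <- d * final[solutes] + (1 - d) * fresh[solutes]
  } else {
    s[solutes] <- fresh[solutes]
  }
  s
}

#' @export
print.syn_transfer_series <- function(x, ...) {
  cat(sprintf("<syn_transfer_series> %s variant, %d transfers of %g h (%g%% inoculum)\n",
              x$variant, x$protocol$n_transfers, x$protocol$batch_duration,
              100 * x$protocol$dilution_fraction))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Pulsed-feed schedule for fed-batch simulation
#'
#' In-silico analog of the NH4+-limited competition assay: a small ammonium
#' pulse is added at fixed times (hourly for 96 h by default), each raising
#' the NH4+ concentration by ~5 uM, far below both default half-saturation
#' constants so that uptake stays affinity-limited.
#'
#' @param times pulse times, h (default every hour from 1 to `duration`).
#' @param increment concentration added per pulse, mM (default 0.005 mM).
#' @param duration total simulated duration, h.
#' @return a `syn_feed_schedule` list. Pulses target extracellular NH4+.
#' @export
feed_schedule <- function(times = NULL, increment = 0.005, duration = 96) {
  if (is.null(times)) times <- seq_len(floor(duration))
  if (duration <= 0) stop("duration must be > 0", call. = FALSE)
  if (length(times) > 0) {
    if (any(times < 0 | times > duration)) {
      stop("pulse times must lie within [0, duration]", call. = FALSE)
    }
    times <- sort(unique(times))
  }
  if (increment < 0) stop("increment must be >= 0", call. = FALSE)
  structure(list(times = as.numeric(times), increment = increment,
                 duration = duration), class = "syn_feed_schedule")
}

#' Simulate a pulsed fed-batch culture
#'
#' Integrates piecewise between pulse times; at each pulse the NH4+
#' concentration jumps by the schedule's increment and the integrator
#' restarts. Concentration increments, not volumes, are modeled. With an
#' empty schedule this reduces exactly to [simulate_batch()].
#'
#' Default initial condition for the competition-assay analog: 25 mM
#' glucose, 20 mM acetate (so each species has ample carbon), equal cell
#' densities and no ammonium, so growth of either species is limited by the
#' pulsed NH4+ it can capture.
#'
#' @param params `syn_params`.
#' @param init initial state.
#' @param feed a [feed_schedule()].
#' @param variant `"default"` or `"communal"`.
#' @param grid_dt output grid spacing, h.
#' @param ... tolerances passed to the integrator (as in
#'   [simulate_batch()]).
#' @return a `syn_trajectory` spanning the feed duration. Rows at pulse
#'   times report the post-pulse state.
#' @export
fed_batch <- function(params,
                      init = culture_state(Ec = 1e7, Rp = 1e7, G = 25, C = 20),
                      feed = feed_schedule(),
                      variant = c("default", "communal"), grid_dt = 1, ...) {
  variant <- match.arg(variant)
  if (!inherits(feed, "syn_feed_schedule")) {
    stop("feed must be created with feed_schedule()", call. = FALSE)
  }
  validate_state(init)
  if (length(feed$times) == 0) {
    return(simulate_batch(params, init, feed$duration, variant,
                          grid_dt = grid_dt, ...))
  }

  bounds <- sort(unique(c(0, feed$times[feed$times > 0 &
                                          feed$times < feed$duration],
                          feed$duration)))
  out_times <- sort(unique(c(seq(0, feed$duration, by = grid_dt),
                             feed$duration, bounds)))
  pvec <- .params_to_vector(params)
  dots <- list(...)
  rtol <- dots$rtol %||% 1e-8
  atol_cells <- dots$atol_cells %||% 1e-2
  atol_conc <- dots$atol_conc %||% 1e-12
  max_steps <- dots$max_steps %||% 5e6

  all_times <- c()
  all_states <- NULL
  diag <- list(steps = 0L, rejected = 0L, clamped = 0L)
  state <- init
  for (i in seq_len(length(bounds) - 1)) {
    t0 <- bounds[i]; t1 <- bounds[i + 1]
    if (t0 %in% feed$times) state[["A"]] <- state[["A"]] + feed$increment
    seg_times <- out_times[out_times >= t0 & out_times <= t1]
    if (length(seg_times) < 2) seg_times <- c(t0, t1)
    res <- .integrate_cpp(as.numeric(state[STATE_NAMES]), pvec,
                          variant == "communal", seg_times, rtol, atol_cells,
                          atol_conc, max_steps)
    if (!isTRUE(res$completed)) {
      stop("integration failed in feed segment [", t0, ", ", t1, "] h: ",
           res$message, call. = FALSE)
    }
    seg_states <- res$states
    colnames(seg_states) <- STATE_NAMES
    if (is.null(all_states)) {
      all_times <- seg_times
      all_states <- seg_states
    } else {
      all_times <- c(all_times, seg_times[-1])
      all_states <- rbind(all_states, seg_states[-1, , drop = FALSE])
    }
    diag$steps <- diag$steps + as.integer(res$steps)
    diag$rejected <- diag$rejected + as.integer(res$rejected)
    diag$clamped <- diag$clamped + as.integer(res$clamped)
    state <- setNames(seg_states[nrow(seg_states), ], STATE_NAMES)
  }
  # final pulse exactly at the end of the run, if scheduled
  if (feed$duration %in% feed$times) {
    state[["A"]] <- state[["A"]] + feed$increment
    all_states[nrow(all_states), "A"] <- state[["A"]]
  }
  diag$rtol <- rtol
  .new_trajectory(all_times, all_states, variant, params, diag)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
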