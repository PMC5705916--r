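# In-silico experiments: outcome classification, parameter scans,
# critical-ratio bisection, yield bookkeeping.

OUTCOME_LEVELS <- c("BOTH_GROW", "EC_FAILS", "RP_FAILS", "BOTH_FAIL",
                    "COLLAPSE_OVER_TRANSFERS")

#' Classify the population outcome of a simulation
#'
#' For a single batch trajectory: "net growth" of a species means its final
#' density strictly exceeds `(1 + growth_margin)` times its initial density
#' (equality counts as failure, a conservative convention). The margin
#' exists because the model has no cell death: a failing population never
#' literally declines, it merely stays within a few percent of its
#' starting density, which is what "no net growth" means on a log-scale
#' density plot. The default margin of 0.1 (10% over a 300-h batch) makes
#' the failure classes reachable; `growth_margin = 0` recovers the strict
#' convention. The four combinations map to `BOTH_GROW`, `EC_FAILS` (only
#' E. coli fails), `RP_FAILS`, `BOTH_FAIL`.
#'
#' For a serial-transfer series: `COLLAPSE_OVER_TRANSFERS` iff the
#' per-transfer final densities of both species are strictly decreasing
#' over the last `max(3, n_transfers - 1)` transfers and lose at least 20%
#' overall across that window (with `ec_only = TRUE`, only the E. coli
#' series needs to decline). The 20% floor distinguishes genuine
#' progressive collapse from the numerically monotone approach to a stable
#' per-transfer fixed point, whose per-step declines are fractions of a
#' percent. A non-collapsing series is classified by the net growth of its
#' final transfer.
#'
#' @param result a `syn_trajectory` or `syn_transfer_series`.
#' @param ec_only alternative collapse criterion: E. coli decline alone
#'   suffices.
#' @param growth_margin relative margin defining net growth (see above).
#' @return a `syn_outcome` list: `outcome` (one of the enumeration above),
#'   per-species net-growth booleans, final densities, and final % E. coli.
#' @export
classify_outcome <- function(result, ec_only = FALSE,
                             growth_margin = 0.1) {
  if (inherits(result, "syn_trajectory")) {
    if (nrow(result$states) < 2) stop("empty trajectory", call. = FALSE)
    ini <- initial_state(result)
    fin <- final_state(result)
    ec_grows <- fin[["Ec"]] > (1 + growth_margin) * ini[["Ec"]]
    rp_grows <- fin[["Rp"]] > (1 + growth_margin) * ini[["Rp"]]
    outcome <- if (ec_grows && rp_grows) "BOTH_GROW"
    else if (!ec_grows && rp_grows) "EC_FAILS"
    else if (ec_grows && !rp_grows) "RP_FAILS"
    else "BOTH_FAIL"
    return(structure(list(outcome = outcome, ec_grows = ec_grows,
                          rp_grows = rp_grows, Ec_final = fin[["Ec"]],
                          Rp_final = fin[["Rp"]],
                          pct_Ec_final = 100 * fin[["Ec"]] /
                            max(fin[["Ec"]] + fin[["Rp"]],
                                .Machine$double.xmin)),
                     class = "syn_outcome"))
  }
  if (inherits(result, "syn_transfer_series")) {
    s <- result$summary
    n <- nrow(s)
    if (n == 0) stop("empty transfer series", call. = FALSE)
    win <- min(n, max(3, n - 1))
    idx <- seq(n - win + 1, n)
    declining <- function(x) {
      all(diff(x) < 0) && x[length(x)] < 0.8 * x[1]
    }
    ec_dec <- declining(s$Ec_final[idx])
    rp_dec <- declining(s$Rp_final[idx])
    collapsed <- if (ec_only) ec_dec else (ec_dec && rp_dec)
    if (collapsed) {
      fin <- s[n, ]
      return(structure(list(outcome = "COLLAPSE_OVER_TRANSFERS",
                            ec_grows = FALSE, rp_grows = FALSE,
                            Ec_final = fin$Ec_final, Rp_final = fin$Rp_final,
                            pct_Ec_final = fin$pct_Ec_final),
                       class = "syn_outcome"))
    }
    return(classify_outcome(result$trajectories[[n]], growth_margin = growth_margin))
  }
  stop("result must be a syn_trajectory or syn_transfer_series",
       call. = FALSE)
}

#' @export
print.syn_outcome <- function(x, ...) {
  cat(sprintf("<syn_outcome> %s (Ec %s, Rp %s) Ec=%.3g Rp=%.3g cells/ml, %.1f%% Ec\n",
              x$outcome, if (x$ec_grows) "grows" else "fails",
              if (x$rp_grows) "grows" else "fails",
              x$Ec_final, x$Rp_final, x$pct_Ec_final))
  invisible(x)
}

.new_scan_table <- function(scan_param, grid, outcomes, params, variant,
                            extra = NULL) {
  tab <- data.frame(value = grid,
                    outcome = vapply(outcomes, function(o) o$outcome, ""),
                    Ec_final = vapply(outcomes, function(o) o$Ec_final, 0),
                    Rp_final = vapply(outcomes, function(o) o$Rp_final, 0),
                    pct_Ec_final = vapply(outcomes,
                                          function(o) o$pct_Ec_final, 0))
  names(tab)[1] <- scan_param
  if (!is.null(extra)) tab <- cbind(tab, extra)
  structure(list(scan_param = scan_param, table = tab, params = params,
                 variant = variant), class = "syn_scan_table")
}

#' @export
print.syn_scan_table <- function(x, ...) {
  cat(sprintf("<syn_scan_table> scan over %s (%s variant)\n", x$scan_param,
              x$variant))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Scan batch outcomes over the Rp:Ec ammonium affinity ratio
#'
#' One batch per grid point. The ratio is applied through
#' [set_affinity_ratio()]: half-saturation constants are only ever raised
#' from the shared default, so a ratio r > 1 weakens E. coli's affinity and
#' r < 1 weakens R. palustris's.
#'
#' @param params base `syn_params` (its `K_A`/`K_AR` are overwritten per
#'   grid point).
#' @param ratios strictly positive affinity ratios; log-spaced grids are
#'   the natural choice as the interesting range spans orders of magnitude.
#' @param duration batch duration, h.
#' @param variant `"default"` or `"communal"`.
#' @param init initial state for every batch.
#' @param ... integrator settings for [simulate_batch()].
#' @return a `syn_scan_table` with one outcome per ratio.
#' @export
affinity_ratio_scan <- function(params, ratios, duration = 300,
                                variant = c("default", "communal"),
                                init = default_inoculum(), ...) {
  variant <- match.arg(variant)
  if (any(!is.finite(ratios)) || any(ratios <= 0)) {
    stop("affinity ratios must be finite and > 0", call. = FALSE)
  }
  ratios <- sort(ratios)
  outcomes <- lapply(ratios, function(r) {
    p <- set_affinity_ratio(params, r)
    classify_outcome(simulate_batch(p, init, duration, variant, ...))
  })
  .new_scan_table("affinity_ratio", ratios, outcomes, params, variant)
}

#' Scan batch outcomes over the ammonium excretion level
#'
#' Explores whether higher per-cell NH4+ excretion (`R_A`) can rescue a
#' recipient with a crippled ammonium affinity: the scan is run at a fixed
#' Rp:Ec affinity ratio of 1000 (`K_A = 10`, `K_AR = 0.01` mM) by default.
#' Expected shape: recipient failure at low `R_A`, coexistence at
#' intermediate `R_A`, and producer failure at the highest `R_A` where
#' fast E. coli growth acidifies the culture.
#'
#' @param params base `syn_params`.
#' @param RA_values non-negative excretion levels, fmol per new cell.
#' @param duration batch duration, h.
#' @param ratio affinity ratio held fixed during the scan.
#' @param init initial state for every batch.
#' @param ... integrator settings.
#' @return a `syn_scan_table` with one outcome per `R_A`.
#' @export
excretion_scan <- function(params, RA_values, duration = 300, ratio = 1000,
                           init = default_inoculum(), ...) {
  if (any(!is.finite(RA_values)) || any(RA_values < 0)) {
    stop("R_A values must be finite and >= 0", call. = FALSE)
  }
  RA_values <- sort(RA_values)
  base <- set_affinity_ratio(params, ratio)
  outcomes <- lapply(RA_values, function(ra) {
    p <- base
    p$R_A <- ra
    classify_outcome(simulate_batch(p, init, duration, "default", ...))
  })
  .new_scan_table("R_A", RA_values, outcomes, base, "default")
}

#' Scan batch outcomes over the starting Rp:Ec cell-density ratio
#'
#' At a producer-biased affinity ratio (1000 by default), a relatively
#' denser E. coli inoculum improves the odds that any given E. coli cell
#' captures excreted NH4+. Ratios are achieved by diluting one species from
#' a shared reference density, never concentrating: at ratio 1 both start
#' at `ref_density`; at ratio > 1, E. coli is diluted; at ratio < 1,
#' R. palustris is diluted.
#'
#' @param params base `syn_params`.
#' @param rp_to_ec_ratios strictly positive starting-density ratios.
#' @param duration batch duration, h.
#' @param affinity_ratio_fixed affinity ratio held fixed during the scan.
#' @param ref_density reference inoculum density, cells/ml.
#' @param G glucose in the starting medium, mM.
#' @param ... integrator settings.
#' @return a `syn_scan_table` with one outcome per inoculum ratio.
#' @export
inoculum_ratio_scan <- function(params, rp_to_ec_ratios, duration = 300,
                                affinity_ratio_fixed = 1000,
                                ref_density = 2.7e6, G = 25, ...) {
  if (any(!is.finite(rp_to_ec_ratios)) || any(rp_to_ec_ratios <= 0)) {
    stop("inoculum ratios must be finite and > 0", call. = FALSE)
  }
  rp_to_ec_ratios <- sort(rp_to_ec_ratios)
  p <- set_affinity_ratio(params, affinity_ratio_fixed)
  outcomes <- lapply(rp_to_ec_ratios, function(r) {
    ec <- if (r >= 1) ref_density / r else ref_density
    rp <- if (r >= 1) ref_density else ref_density * r
    init <- culture_state(Ec = ec, Rp = rp, G = G)
    classify_outcome(simulate_batch(p, init, duration, "default", ...))
  })
  .new_scan_table("rp_to_ec_inoculum_ratio", rp_to_ec_ratios, outcomes, p,
                  "default")
}

#' Locate the affinity ratio at which the coculture outcome flips
#'
#' Bisection on the Rp:Ec ammonium affinity ratio. Two criteria:
#' `"batch_net_growth"` - success means `BOTH_GROW` in a single batch;
#' `"transfer_stability"` - success means a serial-transfer series does
#' not collapse. The criterion must flip between the two bounds (verified
#' by endpoint evaluation before bisecting); the returned value is the
#' midpoint of the final bracket of width <= `tol`.
#'
#' @param params base `syn_params`.
#' @param criterion `"batch_net_growth"` or `"transfer_stability"`.
#' @param bounds length-2 bracketing interval of affinity ratios.
#' @param tol bisection tolerance in ratio units (default 0.05).
#' @param duration batch duration, h.
#' @param protocol transfer protocol (transfer_stability criterion only).
#' @param init initial state.
#' @param variant model variant.
#' @param ... integrator settings.
#' @return the boundary ratio (numeric scalar) with attribute `"bracket"`,
#'   the final bracketing interval.
#' @export
find_critical_ratio <- function(params,
                                criterion = c("batch_net_growth",
                                              "transfer_stability"),
                                bounds = c(0.1, 10), tol = 0.05,
                                duration = 300,
                                protocol = transfer_protocol(),
                                init = default_inoculum(),
                                variant = c("default", "communal"), ...) {
  criterion <- match.arg(criterion)
  variant <- match.arg(variant)
  if (length(bounds) != 2 || any(!is.finite(bounds)) || any(bounds <= 0)) {
    stop("bounds must be two finite positive ratios", call. = FALSE)
  }
  bounds <- sort(bounds)

  success <- function(r) {
    p <- set_affinity_ratio(params, r)
    if (criterion == "batch_net_growth") {
      out <- classify_outcome(simulate_batch(p, init, duration, variant, ...))
      out$outcome == "BOTH_GROW"
    } else {
      out <- classify_outcome(serial_transfer(p, init, protocol, variant, ...))
      out$outcome != "COLLAPSE_OVER_TRANSFERS"
    }
  }

  lo <- bounds[1]; hi <- bounds[2]
  s_lo <- success(lo); s_hi <- success(hi)
  if (s_lo == s_hi) {
    stop("criterion does not flip across bounds [", lo, ", ", hi,
         "]: no bracket", call. = FALSE)
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (success(mid) == s_lo) lo <- mid else hi <- mid
  }
  structure((lo + hi) / 2, bracket = c(lo, hi), criterion = criterion)
}

#' Product yields of a completed trajectory
#'
#' Net accumulation of each product per glucose consumed, mol/mol:
#' consumable acids (C), formate (F), ethanol (E), hydrogen (H), and net
#' extracellular NH4+ (A; may be ~0 when consumed as fast as excreted).
#' Formate and ethanol are produced stoichiometrically and consumed by
#' nothing, so their yields equal `f_F` and `f_E` exactly whenever glucose
#' was consumed. For the communal variant, the table also reports total
#' fixed nitrogen and the corresponding N2 consumed (2 NH4+ per N2, the
#' nitrogenase stoichiometry).
#'
#' @param traj a `syn_trajectory`.
#' @return a `syn_yield_table`: named list of mol/mol yields plus `dG_mM`,
#'   the glucose consumed.
#' @export
compute_yields <- function(traj) {
  ini <- initial_state(traj)
  fin <- final_state(traj)
  dG <- ini[["G"]] - fin[["G"]]
  if (dG <= 0) {
    stop("no glucose consumed: yields undefined", call. = FALSE)
  }
  y <- list(C = (fin[["C"]] - ini[["C"]]) / dG,
            F = (fin[["F"]] - ini[["F"]]) / dG,
            E = (fin[["E"]] - ini[["E"]]) / dG,
            H = (fin[["H"]] - ini[["H"]]) / dG,
            A_net = (fin[["A"]] - ini[["A"]]) / dG,
            dG_mM = dG)
  if (traj$variant == "communal") {
    # all fixed N flows through the A pool: fixed = dA + dEc/Y_EA + dRp/Y_RA
    p <- traj$params
    fixedN <- (fin[["A"]] - ini[["A"]]) +
      (fin[["Ec"]] - ini[["Ec"]]) / p$Y_EA +
      (fin[["Rp"]] - ini[["Rp"]]) / p$Y_RA
    y$fixed_N_mM <- fixedN
    y$N2_consumed_mM <- fixedN / 2
  }
  structure(y, class = "syn_yield_table")
}

#' @export
print.syn_yield_table <- function(x, ...) {
  cat("<syn_yield_table> mol product per mol glucose consumed\n")
  for (nm in names(x)) cat(sprintf("  %-14s %.4g\n", nm, x[[nm]]))
  invisible(x)
}

#' Competitive index of E. coli from a fed-batch competition
#'
#' Fold-change of E. coli divided by fold-change of R. palustris over the
#' trajectory: `(Ec_final/Ec_initial) / (Rp_final/Rp_initial)`. A value of
#' 1 means both species were equally competitive for the limiting pulsed
#' NH4+; above 1, E. coli captured disproportionately more.
#'
#' @param traj a `syn_trajectory`, typically from [fed_batch()].
#' @return dimensionless index.
#' @export
competitive_index <- function(traj) {
  ini <- initial_state(traj)
  fin <- final_state(traj)
  if (ini[["Ec"]] <= 0 || ini[["Rp"]] <= 0) {
    stop("competitive index requires both species present initially",
         call. = FALSE)
  }
  (fin[["Ec"]] / ini[["Ec"]]) / (fin[["Rp"]] / ini[["Rp"]])
}
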