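# Parameter set: kinetic, stoichiometric and inhibition constants.
#
# Provenance: each field is flagged "paper" when its value is printed in the
# primary literature for this coculture, or "calibrated" when it comes from
# the shipped calibration (chosen once to satisfy three stated targets:
# E. coli/R. palustris maximum growth-rate ratio of 4.6, full glucose
# consumption by ~100 h, and stationary cocultures of ~10% E. coli).

.param_defaults <- list(
  mu_E_max  = 0.46,   # maximal E. coli specific growth rate, 1/h
  K_G       = 0.1,     # glucose half-saturation for E. coli, mM
  K_A       = 0.01,    # E. coli NH4+ half-saturation, mM
  K_AR      = 0.01,    # R. palustris NH4+ half-saturation, mM
  mu_R_max1 = 0.10,    # maximal R. palustris growth rate, N2 route, 1/h
  mu_R_max2 = 0.0152,  # additive growth boost on extracellular NH4+, 1/h
  K_C       = 0.3,     # consumable-organic-acid half-saturation, mM
  R_A       = 0.15,    # NH4+ excreted per new R. palustris cell, fmol/cell
  Y_EG      = 5e7,     # E. coli yield on glucose, cells/ml per mM
  Y_EA      = 2e9,     # E. coli yield on NH4+, cells/ml per mM
  Y_RC      = 3e7,     # R. palustris yield on organic acids, cells/ml per mM
  Y_RA      = 2.5e8,   # R. palustris yield on NH4+ (boost route), cells/ml per mM
  m_G       = 15,       # maintenance glucose turnover, fmol/cell/h
  f_C       = 1.2,     # mol consumable acids per mol glucose
  f_F       = 0.8,     # mol formate per mol glucose
  f_E       = 0.6,     # mol ethanol per mol glucose
  phi_H     = 2.0,    # H2 per unit N2-route growth flux, fmol/cell
  K_I       = 15,      # total acids (C+F) at half-maximal inhibition, mM
  n_I       = 6,       # Hill steepness of acid inhibition
  v_fix     = 0.4     # communal-variant fixation rate, fmol/cell/h
)

.param_provenance_default <- c(
  mu_E_max = "calibrated", K_G = "calibrated", K_A = "paper", K_AR = "paper",
  mu_R_max1 = "calibrated", mu_R_max2 = "paper", K_C = "calibrated",
  R_A = "paper", Y_EG = "calibrated", Y_EA = "calibrated", Y_RC = "calibrated",
  Y_RA = "calibrated", m_G = "calibrated", f_C = "calibrated",
  f_F = "calibrated", f_E = "calibrated", phi_H = "calibrated",
  K_I = "calibrated", n_I = "calibrated", v_fix = "calibrated"
)

# Fields that must be strictly positive (half-saturation constants).
.param_strictly_positive <- c("K_G", "K_A", "K_AR", "K_C", "K_I")

#' Construct a validated parameter set for the cross-feeding model
#'
#' Returns the full set of kinetic, stoichiometric and inhibition constants
#' used by both model variants. All values default to the shipped
#' calibration; any field may be overridden by name. Each field carries a
#' provenance flag, `"paper"` for values printed in the primary literature
#' on this coculture and `"calibrated"` for values fixed by the shipped
#' calibration (see the methods vignette).
#'
#' Units: growth rates in 1/h; half-saturation constants and inhibition
#' constant in mM; yields in cells/ml per mM; per-cell rates (`R_A`, `m_G`,
#' `phi_H`, `v_fix`) in fmol/cell (/h where a rate); stoichiometric
#' fractions (`f_C`, `f_F`, `f_E`) in mol per mol glucose, dimensionless.
#' The fixed conversion constant 1e-9 mM per (fmol/cell x cells/ml) is not
#' user-settable.
#'
#' @param ... named overrides of individual fields, e.g. `K_A = 0.015`.
#' @param overrides optional named list of overrides (merged after `...`).
#' @return An object of class `syn_params`: a named list of numeric fields
#'   with a `provenance` attribute (named character vector; overridden
#'   fields keep their provenance unless the override equals the default).
#' @examples
#' p <- syn_params(K_A = 0.015)
#' p$K_A
#' attr(p, "provenance")[["K_A"]]
#' @export
syn_params <- function(..., overrides = NULL) {
  user <- c(list(...), overrides)
  if (length(user) > 0 && (is.null(names(user)) || any(names(user) == ""))) {
    stop("all parameter overrides must be named", call. = FALSE)
  }
  unknown <- setdiff(names(user), names(.param_defaults))
  if (length(unknown) > 0) {
    stop("unknown parameter field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  p <- modifyList(.param_defaults, lapply(user, as.numeric))
  prov <- .param_provenance_default
  # An override away from the default is a user choice, flagged as such.
  for (nm in names(user)) {
    if (!isTRUE(all.equal(p[[nm]], .param_defaults[[nm]]))) {
      prov[[nm]] <- "override"
    }
  }
  structure(p, provenance = prov, class = "syn_params")
}

#' Validate a parameter set
#'
#' Checks the domain invariants: every field is a finite, non-negative
#' scalar; half-saturation constants are strictly positive; the fermentation
#' stoichiometry satisfies 0 < f_C + f_F + f_E <= 3.
#'
#' @param params a `syn_params` object (or bare named list with the same
#'   fields).
#' @return `params`, invisibly, if valid; otherwise an error naming the
#'   offending field.
#' @export
validate_params <- function(params) {
  missing <- setdiff(names(.param_defaults), names(params))
  if (length(missing) > 0) {
    stop("parameter set is missing field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (nm in names(.param_defaults)) {
    v <- params[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v)) {
      stop("parameter '", nm, "' must be a finite numeric scalar", call. = FALSE)
    }
    if (v < 0) {
      stop("parameter '", nm, "' must be non-negative (got ", v, ")",
           call. = FALSE)
    }
    if (nm %in% .param_strictly_positive && v <= 0) {
      stop("parameter '", nm, "' must be strictly positive", call. = FALSE)
    }
  }
  fsum <- params$f_C + params$f_F + params$f_E
  if (fsum <= 0 || fsum > 3) {
    stop("fermentation fractions must satisfy 0 < f_C + f_F + f_E <= 3 (got ",
         signif(fsum, 4), ")", call. = FALSE)
  }
  invisible(params)
}

#' @export
print.syn_params <- function(x, ...) {
  prov <- attr(x, "provenance")
  cat("<syn_params> cross-feeding model parameters\n")
  for (nm in names(.param_defaults)) {
    cat(sprintf("  %-10s %-12g [%s]\n", nm, x[[nm]], prov[[nm]]))
  }
  invisible(x)
}

#' Set the ammonium affinity ratio of a parameter set
#'
#' The producer:recipient (Rp:Ec) ammonium affinity ratio is defined as
#' `K_A / K_AR` (affinity is the inverse of the half-saturation constant).
#' Because ammonium transporters are already high-affinity, half-saturation
#' constants are only ever raised from the 0.01 mM default, never lowered:
#' a ratio r > 1 sets `K_A = r * 0.01` with `K_AR = 0.01`; a ratio r < 1
#' sets `K_AR = 0.01 / r` with `K_A = 0.01`.
#'
#' @param params base `syn_params`.
#' @param ratio strictly positive Rp:Ec affinity ratio.
#' @param K_default the default half-saturation both species share at ratio
#'   1, mM (0.01 mM unless exploring the sensitivity to this choice).
#' @return `params` with `K_A` and `K_AR` replaced.
#' @export
set_affinity_ratio <- function(params, ratio, K_default = 0.01) {
  if (!is.numeric(ratio) || length(ratio) != 1 || !is.finite(ratio) ||
      ratio <= 0) {
    stop("affinity ratio must be a single finite value > 0", call. = FALSE)
  }
  if (ratio >= 1) {
    params$K_A <- ratio * K_default
    params$K_AR <- K_default
  } else {
    params$K_A <- K_default
    params$K_AR <- K_default / ratio
  }
  prov <- attr(params, "provenance")
  prov[c("K_A", "K_AR")] <- if (ratio == 1) "paper" else "override"
  attr(params, "provenance") <- prov
  params
}

#' Rp:Ec ammonium affinity ratio of a parameter set
#'
#' @param params a `syn_params` object.
#' @return `K_A / K_AR`, dimensionless.
#' @export
affinity_ratio <- function(params) params$K_A / params$K_AR

# Flat numeric vector in the fixed order the compiled right-hand side
# expects. Validation happens here so every entry point to the integrator
# is covered.
.params_to_vector <- function(params) {
  validate_params(params)
  unlist(params[names(.param_defaults)])
}
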