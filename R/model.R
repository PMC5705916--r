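# Model core: state space and right-hand sides for both model variants.
#
# The coculture couples a glucose-fermenting E. coli population (Ec) to a
# phototrophic, N2-fixing R. palustris population (Rp). Ec converts glucose
# (G) into consumable organic acids (C; pooled acetate+lactate+succinate),
# formate (F) and ethanol (E); Rp consumes C and excretes NH4+ (A) in
# proportion to its N2-fueled growth, releasing H2 (H) as an obligate
# by-product of nitrogenase. Both species draw on the shared A pool, which
# is where interpartner competition enters.

#' Monod saturation fraction
#'
#' `s / (K + s)`: the fraction of the maximal rate realised at substrate
#' concentration `s` with half-saturation constant `K`. Strictly increasing
#' in `s`, 0 at `s = 0`, 1/2 at `s = K`, approaching 1 as `s` grows.
#'
#' @param s substrate concentration, mM (>= 0; vectorised).
#' @param K half-saturation constant, mM (> 0).
#' @return dimensionless fraction in `[0, 1)`.
#' @examples
#' monod(0.01, 0.01)  # 0.5 at half-saturation
#' @export
monod <- function(s, K) {
  if (!is.numeric(K) || any(!is.finite(K)) || any(K <= 0)) {
    stop("half-saturation constant K must be finite and > 0", call. = FALSE)
  }
  if (any(s < 0)) stop("substrate concentration must be >= 0", call. = FALSE)
  s / (K + s)
}

#' Growth inhibition by accumulated acids
#'
#' Consumable organic acids and formate acidify the medium once they
#' accumulate; growth and metabolism of both species are inhibited by the
#' decreasing Hill factor `1 / (1 + ((C + F) / K_I)^n_I)`. The factor is 1
#' with no acids, 1/2 at `C + F = K_I`, and falls steeply for `n_I > 1`.
#' Ethanol is excluded: it is not an acid.
#'
#' @param C consumable organic acids, mM.
#' @param F_ formate, mM.
#' @param params `syn_params` (uses `K_I`, `n_I`).
#' @return dimensionless factor in `(0, 1]`, applied multiplicatively to
#'   every growth and consumption rate of both species.
#' @export
acid_inhibition <- function(C, F_, params) {
  if (any(C < 0) || any(F_ < 0)) {
    stop("acid concentrations must be >= 0", call. = FALSE)
  }
  1 / (1 + ((C + F_) / params$K_I)^params$n_I)
}

#' Construct a culture state vector
#'
#' @param Ec E. coli density, cells/ml.
#' @param Rp R. palustris density, cells/ml.
#' @param G glucose, mM.
#' @param A extracellular NH4+, mM.
#' @param C consumable organic acids (acetate+lactate+succinate pool), mM.
#' @param F_ formate, mM.
#' @param E ethanol, mM.
#' @param H cumulative H2 (liquid-equivalent bookkeeping), mM.
#' @return named numeric vector with the canonical state layout. N2 is
#'   implicit and unlimited (headspace), never a state variable.
#' @examples
#' culture_state(Ec = 1e6, Rp = 9e6, G = 25)
#' @export
culture_state <- function(Ec = 0, Rp = 0, G = 0, A = 0, C = 0, F_ = 0,
                          E = 0, H = 0) {
  s <- c(Ec = Ec, Rp = Rp, G = G, A = A, C = C, F = F_, E = E, H = H)
  validate_state(s)
  s
}

#' Validate a culture state vector
#'
#' @param state named numeric vector with fields Ec, Rp, G, A, C, F, E, H.
#' @return `state`, invisibly, or an error.
#' @export
validate_state <- function(state) {
  missing <- setdiff(STATE_NAMES, names(state))
  if (length(missing) > 0) {
    stop("state is missing component(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  v <- state[STATE_NAMES]
  if (any(!is.finite(v))) stop("state components must be finite", call. = FALSE)
  if (any(v < 0)) {
    bad <- STATE_NAMES[v < 0]
    stop("state components must be >= 0: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(state)
}

#' Default-variant right-hand side (partial privatization)
#'
#' Time derivatives of the culture state under the default model variant,
#' in which R. palustris assimilates N2 directly (an intracellular route
#' that bypasses the extracellular NH4+ pool, enforcing partial
#' privatization) and additionally takes up extracellular NH4+ through a
#' second, Monod-limited growth route with its own half-saturation `K_AR`
#' and additive rate boost `mu_R_max2`.
#'
#' With `I` the acid-inhibition factor:
#' \deqn{\mu_E = \mu_{E,max}\, \frac{G}{K_G+G}\, \frac{A}{K_A+A}\, I}
#' glucose is consumed by growth (`mu_E / Y_EG`) plus a nitrogen-independent
#' maintenance term (`m_G` per cell), so a nitrogen-starved, non-growing
#' E. coli population still ferments glucose and feeds its partner;
#' R. palustris grows through the N2 route (`mu_R1`, fuelling NH4+
#' excretion `R_A` per new cell and H2 release) and the NH4+ route
#' (`mu_R2`, a sink on the shared pool).
#'
#' @param state named state vector (see [culture_state()]).
#' @param params `syn_params`.
#' @return named numeric vector of derivatives, one per state component,
#'   units per hour.
#' @seealso [rhs_communal()] for the communal-pool control variant.
#' @export
rhs_default <- function(state, params) {
  validate_state(state)
  Ec <- state[["Ec"]]; Rp <- state[["Rp"]]
  G <- state[["G"]]; A <- state[["A"]]; C <- state[["C"]]; F_ <- state[["F"]]

  I <- 1 / (1 + ((C + F_) / params$K_I)^params$n_I)
  mG <- G / (params$K_G + G)
  mC <- C / (params$K_C + C)

  mu_E <- params$mu_E_max * mG * (A / (params$K_A + A)) * I
  q_G <- mu_E / params$Y_EG + params$m_G * UNIT_CONV * mG * I
  mu_R1 <- params$mu_R_max1 * mC * I
  mu_R2 <- params$mu_R_max2 * mC * (A / (params$K_AR + A)) * I
  mu_R <- mu_R1 + mu_R2

  c(Ec = mu_E * Ec,
    Rp = mu_R * Rp,
    G  = -q_G * Ec,
    A  = params$R_A * UNIT_CONV * mu_R1 * Rp -
         (mu_E / params$Y_EA) * Ec - (mu_R2 / params$Y_RA) * Rp,
    C  = params$f_C * q_G * Ec - (mu_R / params$Y_RC) * Rp,
    F  = params$f_F * q_G * Ec,
    E  = params$f_E * q_G * Ec,
    H  = params$phi_H * UNIT_CONV * mu_R1 * Rp)
}

#' Communal-pool right-hand side (no direct N2 assimilation)
#'
#' Control variant in which the direct N2-to-biomass route is removed: all
#' fixed nitrogen passes through the extracellular NH4+ pool before either
#' species can assimilate it, mimicking extracellular generation of a
#' communally valuable nutrient. R. palustris growth then requires
#' extracellular NH4+ (`mu_R = (mu_R_max1 + mu_R_max2) * monod(C, K_C) *
#' monod(A, K_AR) * I`), and fixation is decoupled from growth: the pool
#' gains `v_fix` per cell (Monod-limited by acids, which fuel nitrogenase)
#' and loses the uptake of both species. H2 release tracks the fixation
#' flux. No nitrogen enters biomass except through `A`, so the fixed-N
#' bookkeeping `dA + dEc/Y_EA + dRp/Y_RA = v_fix * 1e-9 * monod(C, K_C) *
#' I * Rp` holds identically.
#'
#' @inheritParams rhs_default
#' @return named numeric vector of derivatives, units per hour.
#' @export
rhs_communal <- function(state, params) {
  validate_state(state)
  Ec <- state[["Ec"]]; Rp <- state[["Rp"]]
  G <- state[["G"]]; A <- state[["A"]]; C <- state[["C"]]; F_ <- state[["F"]]

  I <- 1 / (1 + ((C + F_) / params$K_I)^params$n_I)
  mG <- G / (params$K_G + G)
  mC <- C / (params$K_C + C)

  mu_E <- params$mu_E_max * mG * (A / (params$K_A + A)) * I
  q_G <- mu_E / params$Y_EG + params$m_G * UNIT_CONV * mG * I
  mu_R <- (params$mu_R_max1 + params$mu_R_max2) * mC *
    (A / (params$K_AR + A)) * I
  fix <- params$v_fix * UNIT_CONV * mC * I * Rp

  c(Ec = mu_E * Ec,
    Rp = mu_R * Rp,
    G  = -q_G * Ec,
    A  = fix - (mu_E / params$Y_EA) * Ec - (mu_R / params$Y_RA) * Rp,
    C  = params$f_C * q_G * Ec - (mu_R / params$Y_RC) * Rp,
    F  = params$f_F * q_G * Ec,
    E  = params$f_E * q_G * Ec,
    H  = params$phi_H * UNIT_CONV * mC * I * Rp)
}

#' Right-hand side for a named model variant
#'
#' @param state named state vector.
#' @param params `syn_params`.
#' @param variant `"default"` (partial privatization) or `"communal"`.
#' @return named derivative vector.
#' @export
crossfeed_rhs <- function(state, params, variant = c("default", "communal")) {
  variant <- match.arg(variant)
  if (variant == "default") rhs_default(state, params)
  else rhs_communal(state, params)
}
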