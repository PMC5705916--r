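# Independent integration oracle: classical fixed-step RK4 written in plain
# R on top of the exported (pure-R) right-hand sides. Deliberately shares
# nothing with the compiled adaptive integrator except the model
# definition's R reference implementation.

rk4_fixed <- function(params, init, duration, variant = "default",
                      dt = 1e-3) {
  f <- if (variant == "default") rhs_default else rhs_communal
  y <- init[c("Ec", "Rp", "G", "A", "C", "F", "E", "H")]
  n <- round(duration / dt)
  for (i in seq_len(n)) {
    k1 <- f(y, params)
    k2 <- f(pmax(y + dt / 2 * k1, 0), params)
    k3 <- f(pmax(y + dt / 2 * k2, 0), params)
    k4 <- f(pmax(y + dt * k3, 0), params)
    y <- pmax(y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4), 0)
  }
  y
}

# Trapezoidal quadrature of a sampled flux, for trajectory-level
# conservation checks that recompute an integral along the stored grid.
trapz <- function(t, v) {
  sum(diff(t) * (head(v, -1) + tail(v, -1)) / 2)
}

# Random non-degenerate culture states for property-style loops.
random_state <- function() {
  culture_state(Ec = 10^runif(1, 4, 9), Rp = 10^runif(1, 4, 9),
                G = runif(1, 0, 25), A = 10^runif(1, -6, 0),
                C = runif(1, 0, 20), F_ = runif(1, 0, 20),
                E = runif(1, 0, 15), H = runif(1, 0, 2))
}

# Random plausible parameter sets (positive, within broad physical ranges).
random_params <- function() {
  syn_params(
    mu_E_max = runif(1, 0.1, 0.6), mu_R_max1 = runif(1, 0.02, 0.15),
    mu_R_max2 = runif(1, 0, 0.05), K_G = 10^runif(1, -2, 0),
    K_A = 10^runif(1, -3, 0), K_AR = 10^runif(1, -3, 0),
    K_C = 10^runif(1, -2, 0.5), R_A = runif(1, 0, 1),
    Y_EG = 10^runif(1, 7, 8), Y_EA = 10^runif(1, 8.5, 9.5),
    Y_RC = 10^runif(1, 7, 8), Y_RA = 10^runif(1, 8, 9),
    m_G = runif(1, 0, 20), f_C = runif(1, 0.3, 1.5),
    f_F = runif(1, 0.1, 0.9), f_E = runif(1, 0.1, 0.6),
    phi_H = runif(1, 0, 3), K_I = runif(1, 10, 50), n_I = runif(1, 1, 8),
    v_fix = runif(1, 0, 1))
}
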