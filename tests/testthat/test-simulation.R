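test_that("a culture without cells stays exactly at its initial state", {
  p <- syn_params()
  init <- culture_state(G = 25, A = 0.5, C = 3)
  tr <- simulate_batch(p, init, duration = 50)
  expect_equal(nrow(tr$states), 51)
  for (j in seq_along(init)) {
    expect_true(all(tr$states[, j] == init[[j]]))
  }
})

test_that("standard 300-h batch grows both species and meets the calibration targets", {
  p <- syn_params()
  tr <- simulate_batch(p)
  ini <- initial_state(tr)
  fin <- final_state(tr)
  expect_gt(fin[["Ec"]], ini[["Ec"]])
  expect_gt(fin[["Rp"]], ini[["Rp"]])
  # full glucose consumption by roughly 100 h
  df <- as.data.frame(tr)
  t_exhaust <- df$time_h[which(df$G < 0.1)[1]]
  expect_lt(t_exhaust, 130)
  # stationary composition ~10% E. coli at ~1e9 cells/ml
  pct <- 100 * fin[["Ec"]] / (fin[["Ec"]] + fin[["Rp"]])
  expect_gt(pct, 8)
  expect_lt(pct, 13)
  expect_gt(fin[["Ec"]] + fin[["Rp"]], 5e8)
  expect_lt(fin[["Ec"]] + fin[["Rp"]], 2e9)
})

test_that("a strongly producer-biased affinity stops recipient growth but not the producer", {
  p <- set_affinity_ratio(syn_params(), 1000)
  tr <- simulate_batch(p)
  out <- classify_outcome(tr)
  expect_equal(out$outcome, "EC_FAILS")
  expect_gt(final_state(tr)[["Rp"]], 10 * initial_state(tr)[["Rp"]])
})

test_that("glucose consumed matches independent quadrature of the uptake flux", {
  p <- syn_params()
  for (ratio in c(1, 50)) {
    pp <- set_affinity_ratio(p, ratio)
    tr <- simulate_batch(pp, duration = 200)
    df <- as.data.frame(tr)
    I <- acid_inhibition(df$C, df$F, pp)
    mG <- monod(df$G, pp$K_G)
    mu_E <- pp$mu_E_max * mG * monod(df$A, pp$K_A) * I
    q_G <- mu_E / pp$Y_EG + pp$m_G * 1e-9 * mG * I
    dG_quad <- trapz(df$time_h, q_G * df$Ec)
    dG_int <- df$G[1] - df$G[nrow(df)]
    expect_lt(abs(dG_quad - dG_int) / dG_int, 0.005)
  }
})

test_that("halving integrator tolerances leaves final densities unchanged to 0.1%", {
  p <- syn_params()
  a <- final_state(simulate_batch(p, rtol = 1e-6))
  b <- final_state(simulate_batch(p, rtol = 5e-7))
  for (v in c("Ec", "Rp")) {
    expect_lt(abs(a[[v]] - b[[v]]) / b[[v]], 0.001)
  }
})

test_that("integrator failure surfaces as an error with diagnostics", {
  p <- syn_params()
  expect_error(simulate_batch(p, max_steps = 5), "step budget")
  expect_error(simulate_batch(p, duration = -1), "> 0")
})

test_that("transfer carryover bookkeeping is exact", {
  p <- syn_params()
  proto <- transfer_protocol(batch_duration = 40, n_transfers = 3,
                             dilution_fraction = 0.01)
  s <- serial_transfer(p, protocol = proto)
  for (k in 1:2) {
    fin <- final_state(s$trajectories[[k]])
    nxt <- initial_state(s$trajectories[[k + 1]])
    expect_identical(nxt[["Ec"]], 0.01 * fin[["Ec"]])
    expect_identical(nxt[["Rp"]], 0.01 * fin[["Rp"]])
    expect_identical(nxt[["G"]], 0.01 * fin[["G"]] + 0.99 * 25)
    for (v in c("A", "C", "F", "E", "H")) {
      expect_identical(nxt[[v]], 0.01 * fin[[v]])
    }
  }
  # fresh-medium-only alternative resets solutes
  proto2 <- transfer_protocol(batch_duration = 40, n_transfers = 2,
                              carry_solutes = FALSE)
  s2 <- serial_transfer(p, protocol = proto2)
  expect_identical(initial_state(s2$trajectories[[2]])[["F"]], 0)
  expect_identical(initial_state(s2$trajectories[[2]])[["G"]], 25)
})

test_that("no dilution into final-state medium continues the run exactly", {
  p <- syn_params()
  t1 <- simulate_batch(p, duration = 60)
  fin <- final_state(t1)
  proto <- transfer_protocol(batch_duration = 60, dilution_fraction = 1,
                             n_transfers = 2, fresh_medium = fin)
  s <- serial_transfer(p, protocol = proto)
  expect_equal(initial_state(s$trajectories[[2]]),
               final_state(s$trajectories[[1]]), tolerance = 1e-15)
})

test_that("equal affinities give steady per-transfer densities; strong bias collapses both", {
  p <- syn_params()
  st <- serial_transfer(p)$summary
  # approximately constant after the first transfer
  expect_lt(max(abs(st$Ec_final[3:8] / st$Ec_final[2] - 1)), 0.01)
  expect_lt(max(abs(st$Rp_final[3:8] / st$Rp_final[2] - 1)), 0.01)
  expect_equal(classify_outcome(serial_transfer(p))$outcome, "BOTH_GROW")

  co <- serial_transfer(set_affinity_ratio(p, 10))
  expect_equal(classify_outcome(co)$outcome, "COLLAPSE_OVER_TRANSFERS")
  # both species decline together: mutual starvation, not displacement
  expect_true(all(diff(co$summary$Ec_final[2:8]) < 0))
  expect_true(all(diff(co$summary$Rp_final[2:8]) < 0))
})

test_that("fed-batch with an empty schedule reduces to a plain batch", {
  p <- syn_params()
  init <- culture_state(Ec = 1e7, Rp = 1e7, G = 25, C = 20)
  feed0 <- feed_schedule(times = numeric(0), duration = 48)
  a <- fed_batch(p, init, feed0)
  b <- simulate_batch(p, init, duration = 48)
  expect_equal(a$states, b$states, tolerance = 1e-12)
})

test_that("without nitrogen input neither species grows in the communal control", {
  p <- syn_params(v_fix = 0, R_A = 0)
  init <- culture_state(Ec = 1e7, Rp = 1e7, G = 25, C = 20)
  tr <- fed_batch(p, init, feed_schedule(times = numeric(0), duration = 48),
                  variant = "communal")
  fin <- final_state(tr)
  expect_identical(fin[["Ec"]], 1e7)
  expect_identical(fin[["Rp"]], 1e7)
  expect_lt(fin[["G"]], 25)   # maintenance still runs
  expect_equal(competitive_index(tr), 1)
})

test_that("pulsed ammonium goes to whichever species has the higher affinity", {
  # AmtB deletion raises the half-saturation constant ~100-fold
  ci_ec_adv <- competitive_index(fed_batch(syn_params(K_AR = 1)))
  ci_equal <- competitive_index(fed_batch(syn_params()))
  ci_rp_adv <- competitive_index(fed_batch(syn_params(K_A = 1)))
  expect_gt(ci_ec_adv, ci_equal)
  expect_gt(ci_equal, ci_rp_adv)
  expect_gt(ci_ec_adv, 1)
  expect_lt(ci_rp_adv, 1)
})

test_that("pulses raise the ammonium pool at the scheduled times", {
  p <- syn_params(v_fix = 0, R_A = 0)
  init <- culture_state(Ec = 0, Rp = 0, G = 25, C = 20)  # no consumers
  tr <- fed_batch(p, init, feed_schedule(times = c(1, 2, 3), duration = 5,
                                         increment = 0.005))
  df <- as.data.frame(tr)
  expect_equal(df$A[df$time_h == 5], 0.015, tolerance = 1e-12)
  expect_equal(df$A[df$time_h == 0.0], 0)
})

test_that("protocol and schedule validation rejects impossible settings", {
  expect_error(transfer_protocol(dilution_fraction = 0), "dilution_fraction")
  expect_error(transfer_protocol(dilution_fraction = 1.5), "dilution_fraction")
  expect_error(transfer_protocol(n_transfers = 0), "n_transfers")
  expect_error(feed_schedule(times = c(-1, 5), duration = 10), "within")
  expect_error(feed_schedule(increment = -0.1), "increment")
})

test_that("a 15 mM ammonium supplement lets E. coli bloom and acid-arrests the producer", {
  p <- syn_params()
  sup <- simulate_batch(p, culture_state(Ec = 1e6, Rp = 9e6, G = 25, A = 15))
  ds <- as.data.frame(sup)
  # E. coli no longer waits on cross-fed nitrogen: a >100-fold bloom in
  # 48 h, with the acid pools filled far into the inhibitory regime
  expect_gt(ds$Ec[ds$time_h == 48], 100 * 1e6)
  expect_gt(ds$C[ds$time_h == 48] + ds$F[ds$time_h == 48], 2 * p$K_I)
  # the producer is arrested within the one-week experimental window,
  # despite ample acids and nitrogen (2.7x vs 101x unsupplemented)
  un <- as.data.frame(simulate_batch(p))
  fold_sup <- ds$Rp[ds$time_h == 168] / 9e6
  fold_un <- un$Rp[un$time_h == 168] / 9e6
  expect_lt(fold_sup, 5)
  expect_gt(fold_un, 50)
})
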