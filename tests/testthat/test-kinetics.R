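full_state <- function(...) {
  s <- c(no3 = 10, no2 = 0.5, n2o = 0.1, n2 = 0, fe2 = 4, fe3 = 0.5,
         c = 2, fe3_cell = 0.3)
  over <- c(...)
  s[names(over)] <- over
  s
}

test_that("derivatives respect the stoichiometric couplings and degenerate limits", {
  p0 <- kinetic_params(vmax_no3_fe = 0, k_chem = 0)
  d <- derivatives(full_state(), p0)
  expect_identical(unname(d["fe2"]), 0)   # no Fe-consuming pathway

  p_off <- kinetic_params(vmax_no3_c = 0, vmax_no3_fe = 0, vmax_no2_c = 0,
                          vmax_n2o_c = 0, k_chem = 0)
  expect_true(all(derivatives(full_state(), p_off) == 0))

  # chemodenitrification couples 4 Fe(II) per N2O at any state
  p_chem <- kinetic_params(vmax_no3_c = 0, vmax_no3_fe = 0, vmax_no2_c = 0,
                           k_chem = 0.02)
  set.seed(7)
  for (i in 1:10) {
    s <- full_state(no2 = runif(1, 0.01, 2), fe2 = runif(1, 0.01, 5))
    d <- derivatives(s, p_chem)
    expect_equal(unname(-d["fe2"] / d["n2o"]), 4, tolerance = 1e-12)
  }

  expect_error(derivatives(full_state(fe2 = -1), kinetic_params()),
               "negative state")
})

test_that("pseudo-first-order chemodenitrification matches the closed form within 1%", {
  # nitrite in large excess: fe2(t) ~ fe2_0 exp(-2 k no2_0 t)
  p <- kinetic_params(vmax_no3_c = 0, vmax_no3_fe = 0, vmax_no2_c = 0,
                      vmax_n2o_c = 0, k_chem = 0.001,
                      fe2_0 = 0.5, no3_0 = 0, no2_0 = 50, c0 = 0)
  tt <- seq(0, 20, by = 2)
  tr <- simulate_incubation(p, times = tt)
  expected <- p$fe2_0 * exp(-2 * p$k_chem * p$no2_0 * tt)
  expect_true(all(abs(tr$fe2 - expected) <= 0.01 * pmax(expected, 1e-12)))
})

test_that("the Fe-free setup leaves iron untouched and is carbon-limited", {
  p <- kinetic_params(fe2_0 = 0)
  tr <- simulate_incubation(p, times = seq(0, 240, by = 10))
  expect_true(all(tr$fe2 == 0))
  expect_true(all(tr$fe3 == 0))
  # nitrate consumption bounded by the carbon reserve at 2 e-meq per mM
  expect_lt(p$no3_0 - tr$no3[nrow(tr)], p$c0 / 2 + 1e-6)
  expect_gt(p$no3_0 - tr$no3[nrow(tr)], 0)
})

test_that("the default preset reproduces the narrated incubation shape", {
  p <- kinetic_params()
  tt <- seq(0, 240, by = 1)
  tr <- simulate_incubation(p, times = tt)

  # nitrite transient: unique interior maximum
  ipk <- which.max(tr$no2)
  expect_gt(ipk, 1)
  expect_lt(ipk, nrow(tr))
  expect_true(all(diff(tr$no2[1:ipk]) >= -1e-9))
  d_after <- diff(tr$no2[ipk:nrow(tr)])
  expect_true(all(d_after <= 1e-9))

  # >= 50% of the total Fe(II) loss happens by 48 h
  loss <- p$fe2_0 - tr$fe2
  expect_gte(loss[tt == 48] / loss[tt == 240], 0.5)

  # consumption rates below 1% of their maxima after 144 h
  r_fe <- -diff(tr$fe2); r_no3 <- -diff(tr$no3)
  expect_lt(max(r_fe[tt[-1] > 144]), 0.01 * max(r_fe))
  expect_lt(max(r_no3[tt[-1] > 144]), 0.01 * max(r_no3))

  # paired setups: Fe(II) amendment boosts nitrate consumption
  pc <- kinetic_params(fe2_0 = 0)
  trc <- simulate_incubation(pc, times = tt)
  expect_gt(p$no3_0 - tr$no3[nrow(tr)], pc$no3_0 - trc$no3[nrow(trc)])
})

test_that("conservation and monotonicity invariants hold across presets", {
  presets <- list(
    kinetic_params(),
    kinetic_params(vmax_no3_fe = 0.003, k_chem = 0.040),
    kinetic_params(vmax_no3_fe = 0.08, k_chem = 0.010, vmax_no3_c = 0.14,
                   vmax_no2_c = 0.028, K_enc = 1.5),
    kinetic_params(fe2_0 = 0)
  )
  atol <- 1e-10
  for (p in presets) {
    tr <- simulate_incubation(p, times = seq(0, 240, by = 8), atol = atol)
    expect_true(all(abs(tr$fe2 + tr$fe3 - p$fe2_0) <= 10 * max(1e-8, atol) +
                      1e-8 * p$fe2_0))
    n_tot <- tr$no3 + tr$no2 + 2 * tr$n2o + 2 * tr$n2
    expect_true(all(abs(n_tot - p$no3_0) <= 1e-6))
    expect_true(all(diff(tr$fe2) <= 1e-9))
    expect_true(all(diff(tr$no3) <= 1e-9))
    expect_true(all(diff(tr$fe3) >= -1e-9))
    expect_true(all(diff(tr$fe3_cell) >= -1e-9))
    expect_true(all(diff(tr$n2) >= -1e-9))
    expect_true(all(diff(tr$A) <= 1e-9))  # activity never recovers
  }
})

test_that("removing the inhibition term (K_enc = Inf) recovers the uninhibited model", {
  p_inf <- kinetic_params(K_enc = Inf)
  p_free <- kinetic_params(phi_biotic = 0, phi_abiotic = 0, K_enc = Inf)
  tt <- c(0, 24, 48, 96)
  tr1 <- simulate_incubation(p_inf, times = tt)
  tr2 <- simulate_incubation(p_free, times = tt)
  expect_equal(tr1$fe2, tr2$fe2, tolerance = 1e-8)
  expect_equal(tr1$no3, tr2$no3, tolerance = 1e-8)
})

test_that("simulation input validation rejects bad time grids", {
  expect_error(simulate_incubation(kinetic_params(), times = c(1, 2)),
               "start at 0")
  expect_error(simulate_incubation(kinetic_params(), times = c(0, 10, 10)),
               "increase strictly")
})
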