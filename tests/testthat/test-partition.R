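test_that("consumption summaries match direct arithmetic", {
  tc <- timecourse(endpoint_tc("s", "x", "NO3", 10, 8.92))
  cs <- consumed(tc, "NO3", 0, 240)
  expect_equal(cs$mean_consumed, 1.08)
  expect_identical(cs$sd_consumed, 0)
  expect_identical(cs$n_replicates, 3L)

  flat <- consumed(timecourse(endpoint_tc("s", "x", "NO3", 5, 5)), "NO3")
  expect_identical(flat$mean_consumed, 0)

  tc3 <- timecourse(endpoint_tc("s", "x", "NO3", 10, 10 - c(1.0, 1.1, 1.2)))
  cs3 <- consumed(tc3, "NO3", 0, 240)
  expect_equal(cs3$mean_consumed, 1.1)
  expect_equal(cs3$sd_consumed, 0.1)
  expect_equal(consumed(tc3, "NO3", sd_type = "population")$sd_consumed,
               sqrt(mean((c(1.0, 1.1, 1.2) - 1.1)^2)))

  # nearest-sample matching within 1 h; beyond that is an error
  expect_equal(consumed(tc, "NO3", 0.6, 239.4)$mean_consumed, 1.08)
  expect_error(consumed(tc, "NO3", 0, 200), "no sample within 1 h")
  expect_error(consumed(tc, "Fe2", 0, 240), "absent")
  # negative consumption retained, flagged
  up <- consumed(timecourse(endpoint_tc("s", "x", "N2O", 0.1, 0.5)), "N2O")
  expect_equal(up$mean_consumed, -0.4)
  expect_match(up$warnings, "negative consumption")
})

test_that("the partition reproduces both bounds of the reported mass balance", {
  # lower bound: 1.08 vs 0.67 mM nitrate, 3.80 mM Fe oxidized
  lo <- pair_from_consumption(1.08, 0.67, 3.80)
  est <- partition_fe(lo$with_fe, lo$without_fe)
  expect_equal(est$delta_no3, 0.41)
  expect_equal(est$enzymatic_fe, 0.82)
  expect_equal(est$total_fe_ox, 3.80)
  expect_equal(est$abiotic_fe, 2.98)
  expect_identical(est$frac_enzymatic_pct, 22L)
  expect_identical(est$frac_abiotic_pct, 78L)
  expect_identical(est$frac_no3_fe_driven_pct, 38L)
  expect_equal(est$frac_enzymatic, 0.82 / 3.80, tolerance = 1e-12)

  # upper bound: 1.61 vs 1.06 mM nitrate
  hi <- pair_from_consumption(1.61, 1.06, 3.80)
  est2 <- partition_fe(hi$with_fe, hi$without_fe)
  expect_equal(est2$delta_no3, 0.55)
  expect_equal(est2$enzymatic_fe, 1.10)
  expect_equal(est2$abiotic_fe, 2.70)
  expect_identical(est2$frac_enzymatic_pct, 29L)
  expect_identical(est2$frac_abiotic_pct, 71L)
  expect_identical(est2$frac_no3_fe_driven_pct, 34L)
  expect_length(est2$warnings, 0)
})

test_that("degenerate and invalid partitions behave as documented", {
  # identical nitrate consumption -> all Fe oxidation abiotic
  same <- pair_from_consumption(1.0, 1.0, 2.0)
  est <- partition_fe(same$with_fe, same$without_fe)
  expect_identical(est$delta_no3, 0)
  expect_identical(est$frac_enzymatic, 0)
  expect_identical(est$frac_abiotic, 1)

  # negative delta clipped with warning
  neg <- pair_from_consumption(0.5, 0.9, 2.0)
  est_n <- partition_fe(neg$with_fe, neg$without_fe)
  expect_identical(est_n$delta_no3, 0)
  expect_match(paste(est_n$warnings, collapse = ";"), "clipped")

  # enzymatic exceeding total Fe loss clips the abiotic share
  over <- pair_from_consumption(2.0, 0.5, 1.0)
  est_o <- partition_fe(over$with_fe, over$without_fe)
  expect_identical(est_o$abiotic_fe, 0)
  expect_identical(est_o$frac_enzymatic, 1)
  expect_match(paste(est_o$warnings, collapse = ";"), "clipped")

  # nothing to partition
  none <- pair_from_consumption(1.0, 0.5, 0)
  expect_error(partition_fe(none$with_fe, none$without_fe),
               "no Fe\\(II\\) oxidation")

  # strain pairing is strict
  other <- pair_from_consumption(1.0, 0.5, 2.0, strain = "E2")
  expect_error(partition_fe(same$with_fe, other$without_fe),
               "strain mismatch")
})

test_that("the partition is scale-equivariant and its fractions scale-invariant", {
  base <- pair_from_consumption(1.3, 0.8, 3.1)
  est <- partition_fe(base$with_fe, base$without_fe)
  for (cc in c(0.25, 4)) {
    scale_tc <- function(tc) {
      tc$value <- tc$value * cc
      timecourse(as.data.frame(tc))
    }
    est_c <- partition_fe(scale_tc(base$with_fe), scale_tc(base$without_fe))
    expect_equal(est_c$delta_no3, cc * est$delta_no3)
    expect_equal(est_c$enzymatic_fe, cc * est$enzymatic_fe)
    expect_equal(est_c$total_fe_ox, cc * est$total_fe_ox)
    expect_equal(est_c$abiotic_fe, cc * est$abiotic_fe)
    expect_equal(est_c$frac_enzymatic, est$frac_enzymatic)
    expect_equal(est_c$frac_no3_fe_driven, est$frac_no3_fe_driven)
  }
})

test_that("N2O consistency compares predicted and observed excess", {
  lo <- pair_from_consumption(1.08, 0.67, 3.80)
  est <- partition_fe(lo$with_fe, lo$without_fe)
  expect_equal(est$n2o_predicted_chem, 2.98 / 4)

  # absent N2O -> record unavailable, never an error
  rec0 <- n2o_consistency(est, lo$with_fe, lo$without_fe)
  expect_false(rec0$available)

  # observed excess equals prediction -> ratio 1, no flag
  add_n2o <- function(tc, id, strain, end) timecourse(rbind(
    as.data.frame(tc), endpoint_tc(id, strain, "N2O", 0, end)))
  wf <- add_n2o(lo$with_fe, "with_fe", "E1", 0.845)
  wo <- add_n2o(lo$without_fe, "without_fe", "E1", 0.100)
  rec <- n2o_consistency(est, wf, wo)
  expect_true(rec$available)
  expect_equal(rec$ratio, 1)
  expect_false(rec$flagged)

  # large mismatch is flagged
  wo_hi <- add_n2o(lo$without_fe, "without_fe", "E1", 0.60)
  expect_true(n2o_consistency(est, wf, wo_hi)$flagged)
})

test_that("end-to-end on noise-free simulator output the N2O budget closes", {
  pair <- make_paired_setups(kinetic_params(),
                             noise_model(sigma_rel = 0, sigma_abs = 0,
                                         n_replicates = 1))
  est <- partition_fe(pair$with_fe, pair$without_fe)
  rec <- n2o_consistency(est, pair$with_fe, pair$without_fe)
  expect_true(rec$available)
  # estimator error propagates: agreement well inside the default band
  expect_gt(rec$ratio, 0.9)
  expect_lt(rec$ratio, 1.1)
})

test_that("bootstrap CIs are degenerate without noise, seeded, and match enumeration", {
  lo <- pair_from_consumption(1.08, 0.67, 3.80)  # identical replicates
  ci0 <- bootstrap_uncertainty(lo$with_fe, lo$without_fe, B = 200, seed = 3)
  expect_equal(ci0$ci_upper - ci0$ci_lower, 0)

  # seeded determinism on heterogeneous replicates
  het <- list(
    with_fe = timecourse(rbind(
      endpoint_tc("with_fe", "E1", "NO3", 10, 10 - c(1.0, 1.2, 1.1)),
      endpoint_tc("with_fe", "E1", "Fe2", 4.5, 4.5 - c(3.7, 3.9, 3.8)))),
    without_fe = timecourse(
      endpoint_tc("without_fe", "E1", "NO3", 10, 10 - c(0.6, 0.7, 0.8))))
  a <- bootstrap_uncertainty(het$with_fe, het$without_fe, B = 500, seed = 11)
  b <- bootstrap_uncertainty(het$with_fe, het$without_fe, B = 500, seed = 11)
  expect_identical(a[c("ci_lower", "ci_upper")], b[c("ci_lower", "ci_upper")])
  c2 <- bootstrap_uncertainty(het$with_fe, het$without_fe, B = 500, seed = 12)
  expect_false(identical(a$fracs, c2$fracs))

  # two replicates: exhaustive mode equals a hand-rolled enumeration
  duo <- list(
    with_fe = timecourse(rbind(
      endpoint_tc("with_fe", "E1", "NO3", 10, 10 - c(1.0, 1.3),
                  n_replicates = 2),
      endpoint_tc("with_fe", "E1", "Fe2", 4.5, 4.5 - c(3.5, 4.0),
                  n_replicates = 2))),
    without_fe = timecourse(
      endpoint_tc("without_fe", "E1", "NO3", 10, 10 - c(0.6, 0.9),
                  n_replicates = 2)))
  got <- bootstrap_uncertainty(duo$with_fe, duo$without_fe, exhaustive = TRUE)
  no3w <- c(1.0, 1.3); few <- c(3.5, 4.0); no3o <- c(0.6, 0.9)
  combs <- expand.grid(a1 = 1:2, a2 = 1:2, b1 = 1:2, b2 = 1:2)
  fr <- apply(combs, 1, function(ix) {
    delta <- mean(no3w[ix[1:2]]) - mean(no3o[ix[3:4]])
    min(max(2 * max(delta, 0) / mean(few[ix[1:2]]), 0), 1)
  })
  expect_identical(length(got$fracs), length(fr))
  expect_equal(sort(got$fracs), sort(fr))
  expect_equal(got$ci_lower, unname(stats::quantile(fr, 0.025)))
  expect_equal(got$ci_upper, unname(stats::quantile(fr, 0.975)))

  # single replicate is rejected with advice
  solo <- pair_from_consumption(1.0, 0.6, 2.0, n_replicates = 1)
  expect_error(bootstrap_uncertainty(solo$with_fe, solo$without_fe),
               "noise-free")
})
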