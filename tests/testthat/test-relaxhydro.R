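test_that("exponential decay fitting recovers exact and noisy rates", {
  t <- seq(0.01, 1.0, length.out = 8)
  f <- fit_decay(t, 5 * exp(-2 * t))
  expect_true(f$ok)
  expect_equal(f$rate, 2, tolerance = 1e-8)
  expect_equal(f$i0, 5, tolerance = 1e-8)

  flat <- fit_decay(t, rep(3, 8))
  expect_false(flat$ok)

  set.seed(99)
  rates <- replicate(50, {
    y <- 4 * exp(-1.5 * t) * (1 + rnorm(8, 0, 0.02))
    fit_decay(t, y)$rate
  })
  expect_equal(mean(rates), 1.5, tolerance = 0.02)
})

test_that("the rotor model behaves physically and inverts consistently", {
  # R2 strictly increasing in tau_c
  r2s <- vapply(seq(1, 20, by = 0.5),
                function(tc) predict_rates(tc, 600)$r2, numeric(1))
  expect_true(all(diff(r2s) > 0))

  # fast-tumbling limit: inversion goes to zero with tau_c
  for (tc in c(0.2, 0.1, 0.05)) {
    r <- predict_rates(tc, 600)
    rt <- data.frame(residue = 1, r1 = r$r1, r1_err = 0,
                     r2 = r$r2, r2_err = 0, ok = TRUE)
    est <- suppressWarnings(tryCatch(
      estimate_tauc(rt, 600)$tau_c, error = function(e) 0))
    expect_lt(est, 0.6)
  }

  # tau_c 8.4 ns at 600 MHz sits near ratio 8 and round-trips within 5%
  r <- predict_rates(8.4, 600)
  expect_equal(r$r2 / r$r1, 8.0, tolerance = 0.05)
  rt <- data.frame(residue = 1, r1 = r$r1, r1_err = 0, r2 = r$r2,
                   r2_err = 0, ok = TRUE)
  expect_equal(estimate_tauc(rt, 600)$tau_c, 8.4, tolerance = 0.05)
})

test_that("the closed-form inversion evaluates known ratios", {
  mk <- function(ratio) data.frame(residue = 1, r1 = 1, r1_err = 0,
                                   r2 = ratio, r2_err = 0, ok = TRUE)
  expect_equal(estimate_tauc(mk(7 / 6), 600)$tau_c, 0, tolerance = 1e-9)
  expect_equal(estimate_tauc(mk(8.04), 600)$tau_c, 8.4, tolerance = 0.01)
  expect_equal(estimate_tauc(mk(2), 600)$tau_c, 2.9, tolerance = 0.02)
  expect_warning(estimate_tauc(rbind(mk(8), mk(1.1)), 600), "skipped")
})

test_that("round trip holds across the tau_c and field ranges", {
  for (field in c(500, 600, 700, 800))
    for (tc in c(3, 5, 8.4, 12, 15)) {
      r <- predict_rates(tc, field)
      rt <- data.frame(residue = 1, r1 = r$r1, r1_err = 0, r2 = r$r2,
                       r2_err = 0, ok = TRUE)
      expect_equal(estimate_tauc(rt, field)$tau_c, tc, tolerance = 0.05)
    }
})

test_that("filtering drops flexible termini and ratio outliers", {
  series <- gen_relaxation_series(noiseless_spec(seed = 3))
  rates <- filter_residues(fit_rate_table(series))
  flex <- rates$residue[rates$flexible]
  expect_equal(flex, 1:5)
  expect_true(all(!rates$pass_fine[rates$flexible]))
  expect_true(all(rates$pass_fine[!rates$flexible]))

  # all-identical ratios all pass
  rt <- data.frame(residue = 1:12, r1 = 1.5, r1_err = 0.01, r2 = 12,
                   r2_err = 0.05, ok = TRUE, flexible = FALSE)
  out <- filter_residues(rt)
  expect_true(all(out$pass_fine))

  # one extreme outlier is shed by the fine trim
  rt$r2[6] <- 36
  out2 <- filter_residues(rt)
  expect_false(out2$pass_fine[6])
  expect_true(all(out2$pass_fine[-6]))

  expect_error(filter_residues(rt[1:6, ]), "10")
})

test_that("Stokes-Einstein-Debye conversion has the right laws and value", {
  expect_equal(rh_from_tauc(8.4, 298.15, 8.90e-4), 2.10, tolerance = 0.005)
  expect_equal(rh_from_tauc(8.4 * 8) / rh_from_tauc(8.4), 2, tolerance = 1e-10)
  expect_equal(rh_from_tauc(1.05), 1.05, tolerance = 0.005)
  # monotone in tau_c and T, decreasing in eta
  expect_true(all(diff(vapply(1:10, rh_from_tauc, numeric(1))) > 0))
  expect_gt(rh_from_tauc(8.4, 310), rh_from_tauc(8.4, 280))
  expect_lt(rh_from_tauc(8.4, viscosity = 1.2e-3),
            rh_from_tauc(8.4, viscosity = 8.9e-4))
})

test_that("the noiseless pipeline reproduces the planted tumbling", {
  res <- relax_pipeline(gen_relaxation_series(noiseless_spec(seed = 1)))
  expect_equal(res$tauc$n_residues, 54L)
  expect_equal(res$tauc$tau_c, 8.4, tolerance = 0.02)
  expect_equal(res$rh_nm, 2.09, tolerance = 0.01)
})

test_that("the noisy pipeline stays inside the study's tolerance band", {
  tcs <- vapply(1:50, function(s) {
    sp <- synth_spec(seed = s)
    sp$noise$relax <- 0.03
    relax_pipeline(gen_relaxation_series(sp))$tauc$tau_c
  }, numeric(1))
  expect_lt(abs(mean(tcs) - 8.4), 0.7)
  expect_true(all(abs(tcs - 8.4) < 0.7))
})
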