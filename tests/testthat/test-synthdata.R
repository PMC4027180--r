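test_that("every generator is deterministic in (spec, seed)", {
  for (gen in list(gen_shift_table, gen_hsqc_pair, gen_relaxation_series,
                   gen_itc_thermogram, gen_titration_curve, gen_melting_pair,
                   gen_emsa_curve, gen_emission_pair, gen_promoter)) {
    a <- gen(synth_spec(seed = 11))
    b <- gen(synth_spec(seed = 11))
    attr(a, "truth") <- NULL; attr(b, "truth") <- NULL
    expect_identical(a, b)
  }
  # different seeds move peak positions but keep assignments
  p1 <- gen_hsqc_pair(synth_spec(seed = 1))
  p2 <- gen_hsqc_pair(synth_spec(seed = 2))
  expect_identical(p1$free$residue, p2$free$residue)
  expect_false(isTRUE(all.equal(p1$free$h, p2$free$h)))
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(123)
  before <- .Random.seed
  invisible(gen_shift_table(synth_spec(seed = 5)))
  invisible(gen_itc_thermogram(synth_spec(seed = 5)))
  expect_identical(.Random.seed, before)
})

test_that("spec validation enforces the documented invariants", {
  expect_error(synth_spec(topology = data.frame(element = "H", start = 70L,
                                                end = 80L), n_residues = 76),
               "topology|end")
  expect_error(synth_spec(topology = data.frame(
    element = c("H", "E"), start = c(5L, 10L), end = c(12L, 15L))),
    "non-overlapping")
  expect_error(synth_spec(tau_c = -1))
  expect_error(synth_spec(noise = modifyList(zero_noise, list(relax = -0.1))))
  expect_error(synth_spec(interface_residues = c(0L, 5L)))
})

test_that("degenerate experimental designs are refused", {
  expect_error(gen_relaxation_series(synth_spec(seed = 1),
                                     r1_delays = rep(0.1, 8)),
               "degenerate")
  expect_error(gen_itc_thermogram(synth_spec(seed = 1), n_inj = 5), "10")
})

test_that("zero-noise round trips recover every planted parameter", {
  spec <- noiseless_spec(seed = 42)

  expect_identical(csi_call(gen_shift_table(spec))$topology, "αβααββα")

  pair <- gen_hsqc_pair(spec)
  expect_setequal(classify_interface(pair$free, pair$bound)$interface,
                  spec$interface_residues)

  relax <- relax_pipeline(gen_relaxation_series(spec))
  expect_equal(relax$tauc$tau_c, spec$tau_c, tolerance = 0.02)

  sim <- gen_itc_thermogram(spec)
  fit <- fit_sequential(sim$thermogram, sim$design,
                        seq_params(1e-7, 1e-6, 5, -2))
  expect_equal(fit$params$kd1, spec$itc$kd1, tolerance = 0.01)
  expect_equal(fit$params$dh1, spec$itc$dh1, tolerance = 0.01)

  expect_equal(breakpoint_stoichiometry(gen_titration_curve(spec))$breakpoint,
               spec$stoich_break, tolerance = 1e-3)

  mp <- gen_melting_pair(spec)
  expect_equal(delta_tm(mp$free, mp$bound), spec$tm_bound - spec$tm_free,
               tolerance = 0.05)

  expect_equal(hill_fit(gen_emsa_curve(spec))$n, spec$hill_n,
               tolerance = 1e-3)
})

test_that("recovery error grows with the noise level", {
  levels <- c(0, 0.02, 0.08)
  err_break <- err_tm <- err_hill <- matrix(NA_real_, 20, 3)
  for (s in 1:20) for (l in 1:3) {
    sp <- synth_spec(seed = s,
                     noise = modifyList(zero_noise,
                                        list(curve = levels[l])))
    err_break[s, l] <-
      abs(breakpoint_stoichiometry(gen_titration_curve(sp))$breakpoint - 2)
    mp <- gen_melting_pair(sp)
    err_tm[s, l] <- abs(delta_tm(mp$free, mp$bound) - 10)
    err_hill[s, l] <- abs(hill_fit(gen_emsa_curve(sp))$n - 4.5)
  }
  for (e in list(err_break, err_tm, err_hill)) {
    m <- colMeans(e, na.rm = TRUE)
    expect_true(all(diff(m) >= -1e-8))
  }
})

test_that("the ITC generator reproduces the biphasic heat signature", {
  sim <- gen_itc_thermogram(noiseless_spec(seed = 3))
  h <- sim$thermogram$heat
  expect_gt(h[1], 0)
  expect_lt(h[length(h)], 0)
  # zero-enthalpy spec produces zero heats
  sp0 <- noiseless_spec(seed = 3, itc = list(kd1 = 40e-9, kd2 = 5e-6,
                                             dh1 = 0, dh2 = 0))
  expect_true(all(gen_itc_thermogram(sp0)$thermogram$heat == 0))
})

test_that("the synthetic promoter plants exactly the two operators", {
  prom <- gen_promoter(synth_spec(seed = 14))
  truth <- attr(prom, "truth")
  sites <- find_paired_sites(prom)
  expect_equal(nrow(sites), 2L)
  expect_equal(sites$first_start, unname(c(truth$site_a["start"],
                                           truth$site_b["start"])))
  expect_true(all(sites$span == 15L))
  # planted spans sit at the stated TSS coordinates
  off <- prom$tss_offset
  expect_equal(off + truth$site_a[["start"]] - 1L, -92L)
  expect_equal(off + truth$site_b[["start"]] - 1L, -28L)
  # the site A context is the direct-repeat 20-mer
  expect_true(grepl(site_a_20mer, prom$bases, fixed = TRUE))
  expect_true(direct_repeat_check(site_a_20mer)$is_repeat)

  none <- gen_promoter(synth_spec(seed = 14), plant_sites = FALSE)
  expect_equal(nrow(find_paired_sites(none)), 0L)
})

test_that("relaxation generator plants mobile termini and exact rates", {
  spec <- noiseless_spec(seed = 5)
  series <- gen_relaxation_series(spec)
  expect_length(series$residues, 59L)
  rates <- fit_rate_table(series)
  truth <- predict_rates(spec$tau_c, spec$field_1h)
  rigid <- rates[!rates$flexible, ]
  expect_equal(rigid$r1, rep(truth$r1, nrow(rigid)), tolerance = 1e-6)
  expect_equal(rigid$r2, rep(truth$r2, nrow(rigid)), tolerance = 1e-6)
  # flexible termini tumble effectively faster
  flex <- rates[rates$flexible, ]
  expect_true(all(flex$r2 / flex$r1 < min(rigid$r2 / rigid$r1)))
})
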