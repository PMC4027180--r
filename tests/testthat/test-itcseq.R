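# independent grid-search oracle over free protein concentration
oracle_species <- function(p_tot, d_tot, k1, k2, n_grid = 4e5) {
  p_grid <- seq(0, p_tot, length.out = n_grid)
  d <- d_tot / (1 + k1 * p_grid + k1 * k2 * p_grid^2)
  miss <- abs(p_grid + d * (k1 * p_grid + 2 * k1 * k2 * p_grid^2) - p_tot)
  i <- which.min(miss)
  p <- p_grid[i]
  d_i <- d_tot / (1 + k1 * p + k1 * k2 * p^2)
  list(d = d_i, pd = d_i * k1 * p, p2d = d_i * k1 * k2 * p^2, p_free = p)
}

test_that("species fractions honor limits and conserve mass", {
  s0 <- species_fractions(0, 1e-5, 1e7, 1e5)
  expect_equal(s0$d, 1e-5)
  expect_equal(s0$pd + s0$p2d, 0)

  # stoichiometric limit: huge K1, negligible K2, P = D
  s1 <- species_fractions(1e-5, 1e-5, 1e15, 1e-6)
  expect_equal(s1$pd, 1e-5, tolerance = 1e-4)

  set.seed(17)
  for (i in 1:200) {
    p_tot <- 10^runif(1, -7, -4); d_tot <- 10^runif(1, -7, -4)
    k1 <- 10^runif(1, 4, 9); k2 <- 10^runif(1, 3, 7)
    s <- species_fractions(p_tot, d_tot, k1, k2)
    expect_equal(s$d + s$pd + s$p2d, d_tot, tolerance = 1e-9)
    expect_equal(s$p_free + s$pd + 2 * s$p2d, p_tot, tolerance = 1e-9)
  }
})

test_that("species fractions agree with the grid-search oracle", {
  # the study-design condition, to 6 digits
  s <- species_fractions(20e-6, 10e-6, 1 / 40e-9, 1 / 5e-6)
  o <- oracle_species(20e-6, 10e-6, 1 / 40e-9, 1 / 5e-6, n_grid = 2e6)
  expect_equal(s$p_free, o$p_free, tolerance = 1e-5)
  expect_equal(s$pd, o$pd, tolerance = 1e-5)
  expect_equal(s$p2d, o$p2d, tolerance = 1e-5)

  set.seed(23)
  for (i in 1:200) {
    p_tot <- 10^runif(1, -6, -4); d_tot <- 10^runif(1, -6, -4)
    k1 <- 10^runif(1, 5, 8); k2 <- 10^runif(1, 4, 6)
    s <- species_fractions(p_tot, d_tot, k1, k2)
    o <- oracle_species(p_tot, d_tot, k1, k2)
    expect_equal(s$p_free, o$p_free, tolerance = 1e-4)
  }
})

test_that("simulated isotherms have the sequential-model signatures", {
  design <- itc_design()
  # zero enthalpies give zero heats
  h0 <- simulate_heats(seq_params(40e-9, 5e-6, 0, 0), design)
  expect_true(all(h0$heat == 0))

  # endothermic early, exothermic late, single zero crossing
  tg <- simulate_heats(seq_params(40e-9, 5e-6, 10, -5), design)
  expect_gt(tg$heat[1], 0)
  expect_lt(tg$heat[nrow(tg)], 0)
  expect_equal(sum(diff(sign(tg$heat)) != 0), 1L)

  # saturating pre-load: replace the cell with nearly saturated DNA
  sat <- itc_design(cell_conc = 1e-9, syringe_conc = 100e-6)
  tg2 <- simulate_heats(seq_params(40e-9, 5e-6, 10, -5), sat)
  expect_lt(max(abs(tg2$heat[-(1:3)])), abs(tg$heat[1]) / 100)

  # zero titrant
  tg3 <- simulate_heats(seq_params(40e-9, 5e-6, 10, -5),
                        itc_design(syringe_conc = 0))
  expect_true(all(tg3$heat == 0))
})

test_that("heats integrate back to the cumulative heat content", {
  design <- itc_design()
  params <- seq_params(40e-9, 5e-6, 10, -5)
  tg <- simulate_heats(params, design)
  v_cum <- cumsum(tg$volume)
  dil <- exp(-v_cum[length(v_cum)] / design$cell_volume)
  tot <- list(d_tot = design$cell_conc * dil,
              p_tot = design$syringe_conc * (1 - dil))
  sp <- species_fractions(tot$p_tot, tot$d_tot, 1 / params$kd1, 1 / params$kd2)
  q_final <- design$cell_volume *
    (sp$pd * params$dh1 + sp$p2d * (params$dh1 + params$dh2)) * 1000
  # displaced-volume correction adds O(dV/V0) per injection
  expect_equal(sum(tg$heat), q_final,
               tolerance = sum(tg$volume) / design$cell_volume)
})

test_that("a noiseless thermogram is refit to the planted constants", {
  sim <- gen_itc_thermogram(noiseless_spec(seed = 2))
  fit <- fit_sequential(sim$thermogram, sim$design,
                        seq_params(1e-7, 1e-6, 5, -2))
  expect_equal(fit$params$kd1, 40e-9, tolerance = 0.01)
  expect_equal(fit$params$dh1, 10, tolerance = 0.01)
  expect_equal(fit$params$kd2, 5e-6, tolerance = 0.01)
  expect_equal(fit$params$dh2, -5, tolerance = 0.01)

  # init at truth converges immediately with near-zero residual
  fit2 <- fit_sequential(sim$thermogram, sim$design,
                         seq_params(40e-9, 5e-6, 10, -5), n_start = 1)
  expect_lt(fit2$rss, 1e-18)
  expect_true(fit2$converged)
})

test_that("site-1 Kd recovery under heat noise is bounded", {
  lk <- vapply(1:50, function(s) {
    sp <- synth_spec(seed = s)
    sp$noise$itc <- 0.05
    sim <- gen_itc_thermogram(sp)
    f <- fit_sequential(sim$thermogram, sim$design,
                        seq_params(1e-7, 1e-6, 5, -2), seed = s)
    log(f$params$kd1 / 40e-9)
  }, numeric(1))
  # enthalpy-weighted isotherm at c = Dtot/Kd1 = 250 identifies Kd1 weakly;
  # bound set by this package's own simulation study
  expect_lte(median(abs(lk)), 0.7)
})

test_that("thermodynamic conversion matches its closed forms", {
  t0 <- thermo_convert(1, 5, 295.15)
  expect_equal(t0$dg_kcal, 0)
  expect_equal(t0$ds_cal, 5 / 295.15 * 1000)

  t1 <- thermo_convert(1 / 40e-9, 10, 295.15)
  expect_equal(t1$dg_kcal, -9.99, tolerance = 0.001)
  expect_equal(t1$ds_cal, 68, tolerance = 0.01)

  # dH = dG gives zero entropy
  k <- exp(-(-3) * 1000 / (1.98720 * 295.15))
  expect_equal(thermo_convert(k, -3, 295.15)$ds_cal, 0, tolerance = 1e-9)
})
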