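# Physical constants for the 15N amide spin pair (SI units).
# r_NH and the 15N CSA are the conventional fixed values; gyromagnetic
# ratios from CODATA.
.relax_const <- list(
  mu0 = 4 * pi * 1e-7,
  hbar = 1.054571817e-34,
  gamma_h = 2.6752218744e8,   # rad s^-1 T^-1
  gamma_n = -2.71261804e7,
  r_nh = 1.02e-10,            # m
  delta_sigma = -160e-6,      # 15N CSA
  kb = 1.380649e-23)

#' 15N frequency (MHz) for a given 1H field
#' @param field_1h Spectrometer 1H frequency in MHz.
#' @return 15N frequency in MHz (positive).
#' @export
nu_n_from_field <- function(field_1h) {
  field_1h * abs(.relax_const$gamma_n / .relax_const$gamma_h)
}

#' Rigid isotropic-rotor 15N R1 and R2
#'
#' Standard dipolar (N-H) + CSA expressions with the Lorentzian spectral
#' density J(w) = (2/5) tau_c / (1 + (w tau_c)^2); no internal motion or
#' exchange. Used both as the forward model of the synthetic generator and
#' as the reference the R2/R1 inversion approximates.
#'
#' @param tau_c Rotational correlation time in ns.
#' @param field_1h 1H frequency in MHz.
#' @return list(r1, r2) in s^-1.
#' @export
predict_rates <- function(tau_c, field_1h) {
  stopifnot(tau_c > 0, field_1h > 0)
  k <- .relax_const
  tc <- tau_c * 1e-9
  b0 <- field_1h * 1e6 * 2 * pi / k$gamma_h
  wh <- k$gamma_h * b0
  wn <- k$gamma_n * b0
  J <- function(w) 0.4 * tc / (1 + (w * tc)^2)
  d <- k$mu0 * k$hbar * k$gamma_h * k$gamma_n / (4 * pi * k$r_nh^3)
  c2 <- (k$delta_sigma * wn)^2 / 3
  r1 <- (d^2 / 4) * (J(wh - wn) + 3 * J(wn) + 6 * J(wh + wn)) + c2 * J(wn)
  r2 <- (d^2 / 8) * (4 * J(0) + J(wh - wn) + 3 * J(wn) + 6 * J(wh) +
                       6 * J(wh + wn)) +
        (c2 / 6) * (4 * J(0) + 3 * J(wn))
  list(r1 = r1, r2 = r2)
}

#' Fit a single-exponential decay I(t) = I0 exp(-R t)
#'
#' Levenberg-Marquardt on the raw intensities, started from the log-linear
#' regression slope. Non-decaying data are flagged rather than fit.
#'
#' @param delays Delay times (s), >= 4 points with >= 3 distinct values.
#' @param intensities Positive intensities (a.u.).
#' @return list(rate (s^-1), i0, error (asymptotic SE of rate), ok).
#' @export
fit_decay <- function(delays, intensities) {
  stopifnot(length(delays) == length(intensities), length(delays) >= 4L,
            length(unique(delays)) >= 3L)
  slope <- unname(stats::coef(stats::lm(log(pmax(intensities, 1e-12)) ~ delays))[2])
  if (!is.finite(slope) || slope >= 0)
    return(list(rate = NA_real_, i0 = NA_real_, error = NA_real_, ok = FALSE))
  fit <- try(minpack.lm::nlsLM(
    intensities ~ i0 * exp(-r * delays),
    start = list(i0 = max(intensities), r = -slope),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error"))
    return(list(rate = NA_real_, i0 = NA_real_, error = NA_real_, ok = FALSE))
  co <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit)))["r"], error = function(e) NA_real_)
  if (co["r"] <= 0)
    return(list(rate = NA_real_, i0 = NA_real_, error = NA_real_, ok = FALSE))
  list(rate = unname(co["r"]), i0 = unname(co["i0"]),
       error = unname(se), ok = TRUE)
}

#' Fit R1 and R2 decay series into a rate table
#'
#' @param series A relaxation series as produced by
#'   [gen_relaxation_series()]: list with `field_1h` and `residues`, each
#'   residue holding r1/r2 data.frames (delay, intensity) and a `flexible`
#'   flag.
#' @return data.frame residue, r1, r1_err, r2, r2_err, ok, flexible.
#' @export
fit_rate_table <- function(series) {
  rows <- lapply(series$residues, function(res) {
    f1 <- fit_decay(res$r1$delay, res$r1$intensity)
    f2 <- fit_decay(res$r2$delay, res$r2$intensity)
    data.frame(residue = res$residue,
               r1 = f1$rate, r1_err = f1$error,
               r2 = f2$rate, r2_err = f2$error,
               ok = f1$ok && f2$ok,
               flexible = isTRUE(res$flexible))
  })
  do.call(rbind, rows)
}

#' Coarse and fine residue filtering for tumbling analysis
#'
#' Coarse: drop fit failures, residues with relative rate error above
#' `max_rel_err`, and residues marked as flexible termini. Fine: iteratively
#' drop residues whose R2/R1 deviates from the current mean ratio by more
#' than `n_sd` standard deviations, until the passing set is stable.
#'
#' @param rates Rate table from [fit_rate_table()].
#' @param max_rel_err Coarse relative-error cut (default 0.2).
#' @param n_sd Fine trim width in SD (default 1).
#' @return Rate table with pass_coarse, pass_fine and ratio columns.
#' @export
filter_residues <- function(rates, max_rel_err = 0.2, n_sd = 1) {
  stopifnot(nrow(rates) >= 10L)
  rel1 <- ifelse(is.na(rates$r1_err), Inf, rates$r1_err / rates$r1)
  rel2 <- ifelse(is.na(rates$r2_err), Inf, rates$r2_err / rates$r2)
  # noiseless fits give ~0 error; treat NA error with ok fit as passing
  rel1[rates$ok & is.na(rates$r1_err)] <- 0
  rel2[rates$ok & is.na(rates$r2_err)] <- 0
  pass_coarse <- rates$ok & !rates$flexible &
    rel1 <= max_rel_err & rel2 <= max_rel_err
  ratio <- rates$r2 / rates$r1
  pass_fine <- pass_coarse
  # trim until the mean ratio of the passing set is stable (the 1-SD band
  # is re-evaluated against each new mean; pure Gaussian scatter stabilizes
  # after one pass, genuine outliers keep being shed)
  for (iter in 1:20) {
    mu <- mean(ratio[pass_fine]); s <- stats::sd(ratio[pass_fine])
    if (is.na(s) || s < .Machine$double.eps^0.5 * max(1, abs(mu))) break
    new_pass <- pass_fine & abs(ratio - mu) <= n_sd * s
    if (identical(new_pass, pass_fine) || sum(new_pass) < 5L) break
    mu_new <- mean(ratio[new_pass])
    pass_fine <- new_pass
    if (abs(mu_new - mu) < 1e-2 * abs(mu)) break
  }
  if (sum(pass_fine) < 5L) stop("fewer than 5 residues survive filtering")
  rates$ratio <- ratio
  rates$pass_coarse <- pass_coarse
  rates$pass_fine <- pass_fine
  rates
}

#' Rotational correlation time from R2/R1
#'
#' Per passing residue, tau_c = (1 / (4 pi nuN)) sqrt(6 R2/R1 - 7), the
#' standard closed-form inversion of the rotor model (valid for slow
#' tumbling; residues with R2/R1 below 7/6 are skipped with a warning).
#'
#' @param rates Filtered rate table ([filter_residues()]); if the pass_fine
#'   column is absent all rows are used.
#' @param field_1h 1H frequency in MHz.
#' @return list(tau_c (ns, mean), tau_c_sd, n_residues, per_residue).
#' @export
estimate_tauc <- function(rates, field_1h) {
  use <- if ("pass_fine" %in% names(rates)) rates$pass_fine else
    rep(TRUE, nrow(rates))
  r <- rates[use & rates$ok, , drop = FALSE]
  if (nrow(r) < 1L) stop("no residues available for tau_c estimation")
  ratio <- r$r2 / r$r1
  bad <- ratio < 7 / 6
  if (any(bad)) {
    warning(sum(bad), " residue(s) with R2/R1 < 7/6 skipped")
    r <- r[!bad, , drop = FALSE]; ratio <- ratio[!bad]
  }
  if (nrow(r) == 0L) stop("no residues with R2/R1 >= 7/6")
  nu_n <- nu_n_from_field(field_1h) * 1e6
  tc <- sqrt(6 * ratio - 7) / (4 * pi * nu_n) * 1e9
  list(tau_c = mean(tc), tau_c_sd = stats::sd(tc), n_residues = length(tc),
       per_residue = data.frame(residue = r$residue, tau_c = tc))
}

#' Hydrodynamic radius from the Stokes-Einstein-Debye relation
#'
#' rH = (3 kB T tau_c / (4 pi eta))^(1/3).
#'
#' @param tau_c Correlation time in ns.
#' @param temperature Kelvin (default 298.15).
#' @param viscosity Solvent viscosity in Pa s (default water at 25 C,
#'   8.90e-4).
#' @return Hydrodynamic radius in nm.
#' @export
rh_from_tauc <- function(tau_c, temperature = 298.15, viscosity = 8.90e-4) {
  stopifnot(tau_c > 0, temperature > 0, viscosity > 0)
  k <- .relax_const
  (3 * k$kb * temperature * (tau_c * 1e-9) / (4 * pi * viscosity))^(1/3) * 1e9
}

#' Full relaxation-to-hydrodynamics pipeline
#'
#' Fits all decays, applies coarse/fine filtering, inverts R2/R1 to tau_c
#' and converts to a hydrodynamic radius.
#'
#' @inheritParams fit_rate_table
#' @inheritParams rh_from_tauc
#' @return list(rates, tauc (as [estimate_tauc()]), rh_nm).
#' @export
relax_pipeline <- function(series, temperature = 298.15,
                           viscosity = 8.90e-4) {
  rates <- filter_residues(fit_rate_table(series))
  tc <- estimate_tauc(rates, series$field_1h)
  list(rates = rates, tauc = tc,
       rh_nm = rh_from_tauc(tc$tau_c, temperature, viscosity))
}
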