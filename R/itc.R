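#' Species fractions for sequential two-site binding
#'
#' DNA (D) carries two sequential protein (P) sites with stepwise
#' association constants K1 and K2 (M^-1). Solves the coupled mass balances
#'   Dtot = [D] (1 + K1 [P] + K1 K2 [P]^2)
#'   Ptot = [P] + [D] (K1 [P] + 2 K1 K2 [P]^2)
#' for free [P] in [0, Ptot] by bracketed root finding (relative tolerance
#' 1e-12), then recovers the species.
#'
#' @param p_tot,d_tot Total protein and DNA concentrations (M).
#' @param k1,k2 Stepwise association constants (M^-1).
#' @return list(d, pd, p2d, p_free) in M.
#' @export
species_fractions <- function(p_tot, d_tot, k1, k2) {
  stopifnot(p_tot >= 0, d_tot >= 0, k1 > 0, k2 > 0)
  if (p_tot == 0)
    return(list(d = d_tot, pd = 0, p2d = 0, p_free = 0))
  bound <- function(p) {
    d <- d_tot / (1 + k1 * p + k1 * k2 * p^2)
    d * (k1 * p + 2 * k1 * k2 * p^2)
  }
  f <- function(p) p + bound(p) - p_tot
  # f(0) = -Ptot < 0, f(Ptot) = bound(Ptot) >= 0: sign change guaranteed
  lo <- 0; hi <- p_tot
  if (f(hi) < 0) stop("species solver: no sign change in bracket")
  sol <- stats::uniroot(f, c(lo, hi), tol = .Machine$double.eps * p_tot)
  p <- sol$root
  # Newton polish to machine precision (f is smooth and monotone here)
  for (it in 1:5) {
    eps <- max(p, p_tot * 1e-6) * 1e-7
    fp <- (f(p + eps) - f(p - eps)) / (2 * eps)
    if (!is.finite(fp) || fp == 0) break
    step <- f(p) / fp
    p_new <- min(max(p - step, 0), p_tot)
    if (abs(p_new - p) <= .Machine$double.eps * max(p, 1e-300)) {
      p <- p_new; break
    }
    p <- p_new
  }
  d <- d_tot / (1 + k1 * p + k1 * k2 * p^2)
  list(d = d, pd = d * k1 * p, p2d = d * k1 * k2 * p^2, p_free = p)
}

#' Geometry of a titration experiment
#'
#' @param cell_volume Cell volume (L), default 200 uL.
#' @param cell_conc Macromolecule (DNA) concentration in the cell (M).
#' @param syringe_conc Titrant (protein) concentration in the syringe (M).
#' @param inj_volumes Vector of injection volumes (L).
#' @param temperature Kelvin (default 295.15, i.e. 22 C).
#' @return list used by [simulate_heats()] / [fit_sequential()].
#' @export
itc_design <- function(cell_volume = 200e-6, cell_conc = 10e-6,
                       syringe_conc = 100e-6,
                       inj_volumes = rep(2e-6, 20),
                       temperature = 295.15) {
  stopifnot(cell_volume > 0, cell_conc > 0, syringe_conc >= 0,
            all(inj_volumes > 0), length(inj_volumes) >= 5L)
  list(cell_volume = cell_volume, cell_conc = cell_conc,
       syringe_conc = syringe_conc, inj_volumes = inj_volumes,
       temperature = temperature)
}

#' Sequential-model binding parameters
#'
#' @param kd1,kd2 Stepwise dissociation constants (M).
#' @param dh1,dh2 Stepwise enthalpies (kcal/mol).
#' @param baseline Constant heat offset per injection (cal), default 0.
#' @return Parameter list.
#' @export
seq_params <- function(kd1, kd2, dh1, dh2, baseline = 0) {
  stopifnot(kd1 > 0, kd2 > 0)
  list(kd1 = kd1, kd2 = kd2, dh1 = dh1, dh2 = dh2, baseline = baseline)
}

# Total concentrations in the cell after cumulative injected volume v,
# continuous-perfusion convention: cell contents overflow and are replaced
# exponentially.
.itc_totals <- function(design, v_cum) {
  dil <- exp(-v_cum / design$cell_volume)
  list(d_tot = design$cell_conc * dil,
       p_tot = design$syringe_conc * (1 - dil))
}

#' Simulate per-injection heats for the sequential two-site model
#'
#' Cumulative cell heat content Q_i = V0 ([PD]_i dH1 + [P2D]_i (dH1 + dH2));
#' the measured injection heat applies the displaced-volume correction
#' q_i = Q_i - Q_{i-1} + (dV_i / V0) (Q_i + Q_{i-1}) / 2. Totals follow the
#' continuous-perfusion dilution convention.
#'
#' @param params [seq_params()].
#' @param design [itc_design()].
#' @return data.frame injection, volume (L), p_tot, d_tot (M), heat (cal),
#'   ratio (cumulative protein:DNA molar ratio in the cell).
#' @export
simulate_heats <- function(params, design) {
  k1 <- 1 / params$kd1; k2 <- 1 / params$kd2
  v0 <- design$cell_volume
  dh1 <- params$dh1 * 1000  # cal/mol
  dh2 <- params$dh2 * 1000
  v_cum <- 0
  q_prev <- 0
  n <- length(design$inj_volumes)
  out <- data.frame(injection = seq_len(n), volume = design$inj_volumes,
                    p_tot = NA_real_, d_tot = NA_real_, heat = NA_real_,
                    ratio = NA_real_)
  for (i in seq_len(n)) {
    dv <- design$inj_volumes[i]
    v_cum <- v_cum + dv
    tot <- .itc_totals(design, v_cum)
    sp <- species_fractions(tot$p_tot, tot$d_tot, k1, k2)
    q <- v0 * (sp$pd * dh1 + sp$p2d * (dh1 + dh2))
    out$heat[i] <- q - q_prev + (dv / v0) * (q + q_prev) / 2 + params$baseline
    out$p_tot[i] <- tot$p_tot; out$d_tot[i] <- tot$d_tot
    out$ratio[i] <- tot$p_tot / tot$d_tot
    q_prev <- q
  }
  out
}

#' Fit the sequential two-site model to a thermogram
#'
#' Least squares on the injection heats in log-Kd space (positivity) with
#' Levenberg-Marquardt, multi-started from `n_start` jittered copies of
#' `init` to guard against the shallow second-site direction.
#'
#' @param thermogram data.frame with columns injection, heat (cal), and the
#'   injection volumes in `volume` (L), e.g. from [simulate_heats()].
#' @param design [itc_design()] describing the experiment.
#' @param init [seq_params()] initial guess.
#' @param n_start Number of jittered starts (default 5).
#' @param fit_baseline Estimate a constant per-injection offset.
#' @param seed Seed for the jitter (default 1).
#' @return list(params, se (asymptotic), rss, residuals, converged).
#' @export
fit_sequential <- function(thermogram, design, init,
                           n_start = 5L, fit_baseline = FALSE, seed = 1L) {
  stopifnot(nrow(thermogram) >= 10L)
  obs <- thermogram$heat
  model_heats <- function(th) {
    p <- seq_params(exp(th[1]), exp(th[2]), th[3], th[4],
                    if (fit_baseline) th[5] else 0)
    simulate_heats(p, design)$heat
  }
  resid_fn <- function(th) {
    h <- try(model_heats(th), silent = TRUE)
    if (inherits(h, "try-error")) return(rep(1e6, length(obs)))
    obs - h
  }
  th0 <- c(log(init$kd1), log(init$kd2), init$dh1, init$dh2,
           if (fit_baseline) init$baseline)
  set.seed(seed)
  starts <- list(th0)
  for (s in seq_len(n_start - 1L)) {
    j <- th0
    j[1:2] <- j[1:2] + stats::rnorm(2, sd = 0.5)
    j[3:4] <- j[3:4] * (1 + stats::rnorm(2, sd = 0.2))
    starts[[s + 1L]] <- j
  }
  best <- NULL
  for (st in starts) {
    fit <- try(minpack.lm::nls.lm(
      par = st, fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 300, ftol = 1e-14,
                                           ptol = 1e-14)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss_raw)
      best <- list(fit = fit, rss_raw = rss)
  }
  if (is.null(best)) stop("sequential fit did not converge from any start")
  fit <- best$fit
  th <- fit$par
  se <- tryCatch({
    dof <- max(1L, length(obs) - length(th))
    sigma2 <- best$rss_raw / dof
    # hessian of the SSQ is ~2 J'J, so cov = sigma2 * 2 * H^-1
    sqrt(pmax(0, diag(2 * sigma2 * solve(fit$hessian))))
  }, error = function(e) rep(NA_real_, length(th)))
  pars <- seq_params(exp(th[1]), exp(th[2]), th[3], th[4],
                     if (fit_baseline) th[5] else 0)
  list(params = pars,
       se = list(log_kd1 = se[1], log_kd2 = se[2], dh1 = se[3], dh2 = se[4]),
       rss = best$rss_raw, residuals = fit$fvec,
       converged = fit$info %in% 1:4)
}

#' Binding free energy and entropy from K and dH
#'
#' dG = -R T ln K; dS = (dH - dG) / T with R = 1.98720 cal mol^-1 K^-1.
#'
#' @param k Association constant (M^-1).
#' @param dh Enthalpy (kcal/mol).
#' @param temperature Kelvin.
#' @return list(dg_kcal, ds_cal: cal mol^-1 K^-1).
#' @export
thermo_convert <- function(k, dh, temperature = 295.15) {
  stopifnot(k > 0, temperature > 0)
  r_gas <- 1.98720  # cal/(mol K)
  dg <- -r_gas * temperature * log(k) / 1000  # kcal/mol
  list(dg_kcal = dg, ds_cal = (dh - dg) / temperature * 1000)
}
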