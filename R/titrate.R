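#' Breakpoint stoichiometry of a titration curve
#'
#' Fits the continuous two-segment linear model
#' S(r) = a + b r + c max(r - x0, 0) by profiling x0 (golden-section search
#' on the residual sum of squares over the interior of the ratio range) with
#' closed-form linear coefficients at each candidate break. A break is
#' reported only when the slope change |c| is resolvable above the residual
#' noise.
#'
#' @param curve data.frame with columns ratio (protein:DNA, strictly
#'   increasing, >= 0) and signal.
#' @param min_points Minimum number of points (default 6).
#' @return list(breakpoint (x0, or NA if none), slope1 = b,
#'   slope2 = b + c, slope_change = c, rss).
#' @export
breakpoint_stoichiometry <- function(curve, min_points = 6L) {
  stopifnot(all(c("ratio", "signal") %in% names(curve)),
            nrow(curve) >= min_points,
            !is.unsorted(curve$ratio, strictly = TRUE), all(curve$ratio >= 0))
  r <- curve$ratio; s <- curve$signal
  fit_at <- function(x0) {
    X <- cbind(1, r, pmax(r - x0, 0))
    co <- stats::coef(stats::lm.fit(X, s))
    list(coef = co, rss = sum((s - X %*% co)^2))
  }
  rng <- range(r)
  # profile RSS over interior breaks; grid then local refinement
  grid <- seq(rng[1] + diff(rng) * 0.05, rng[2] - diff(rng) * 0.05,
              length.out = 101)
  rss <- vapply(grid, function(x) fit_at(x)$rss, numeric(1))
  x_best <- grid[which.min(rss)]
  opt <- stats::optimize(function(x) fit_at(x)$rss,
                         interval = c(max(rng[1], x_best - diff(rng) * 0.05),
                                      min(rng[2], x_best + diff(rng) * 0.05)),
                         tol = 1e-10)
  x0 <- opt$minimum
  f <- fit_at(x0)
  co <- f$coef
  # compare the slope change with the residual scale of a no-break line
  line_rss <- sum(stats::lm(s ~ r)$residuals^2)
  noise_sd <- sqrt(f$rss / max(1, length(s) - 4))
  slope_scale <- noise_sd / (diff(rng) / 4)
  has_break <- is.finite(co[3]) && abs(co[3]) > 3 * slope_scale &&
    (line_rss - f$rss) > 1e-12 * max(line_rss, 1)
  list(breakpoint = if (has_break) x0 else NA_real_,
       slope1 = unname(co[2]), slope2 = unname(co[2] + co[3]),
       slope_change = unname(co[3]), rss = f$rss)
}

#' Emission maximum of each spectrum in a titration series
#'
#' Parabolic interpolation through the grid maximum and its two neighbours;
#' a maximum on the grid edge is returned as-is with a warning.
#'
#' @param wavelength Increasing wavelength grid (nm).
#' @param intensity Intensity vector, or matrix with one column per
#'   spectrum.
#' @return Numeric vector of lambda_max (nm), one per spectrum.
#' @export
lambda_max <- function(wavelength, intensity) {
  if (is.null(dim(intensity))) intensity <- matrix(intensity, ncol = 1)
  stopifnot(length(wavelength) == nrow(intensity), length(wavelength) >= 5L,
            !is.unsorted(wavelength, strictly = TRUE))
  apply(intensity, 2, function(y) {
    i <- which.max(y)
    if (i == 1L || i == length(y) || stats::sd(y) == 0) {
      warning("spectrum maximum at grid edge or flat spectrum")
      return(wavelength[i])
    }
    # parabola through (x_{i-1},y_{i-1}), (x_i,y_i), (x_{i+1},y_{i+1})
    x <- wavelength[(i - 1):(i + 1)]; yy <- y[(i - 1):(i + 1)]
    denom <- (yy[1] - 2 * yy[2] + yy[3])
    if (denom == 0) return(wavelength[i])
    wavelength[i] + 0.5 * (x[2] - x[1]) * (yy[1] - yy[3]) / denom
  })
}

#' Melting temperature from an absorbance melting curve
#'
#' Tm is the temperature of the maximum of the smoothed derivative
#' dA260/dT (central differences, 3-point moving average), refined by
#' parabolic interpolation around the grid maximum.
#'
#' @param curve data.frame with columns temperature (C, strictly increasing,
#'   span >= 20 C) and a260.
#' @return Tm in degrees C.
#' @export
tm_from_melt <- function(curve) {
  stopifnot(all(c("temperature", "a260") %in% names(curve)),
            !is.unsorted(curve$temperature, strictly = TRUE),
            diff(range(curve$temperature)) >= 20)
  t <- curve$temperature; a <- curve$a260
  n <- length(t)
  if (stats::sd(a) == 0 || max(a) - min(a) < 1e-9 * max(abs(a), 1))
    stop("no melting transition detected (flat curve)")
  d <- (a[3:n] - a[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
  tc <- t[2:(n - 1)]
  sm <- as.numeric(stats::filter(d, rep(1 / 3, 3), sides = 2))
  na <- is.na(sm)
  sm[na] <- d[na]
  i <- which.max(sm)
  if (i > 1L && i < length(sm)) {
    denom <- sm[i - 1] - 2 * sm[i] + sm[i + 1]
    if (denom != 0)
      return(tc[i] + 0.5 * (tc[2] - tc[1]) * (sm[i - 1] - sm[i + 1]) / denom)
  }
  tc[i]
}

#' Melting-temperature shift of bound versus free duplex
#'
#' @param free,bound Melting curves as in [tm_from_melt()].
#' @return delta Tm = Tm(bound) - Tm(free), degrees C.
#' @export
delta_tm <- function(free, bound) {
  tm_from_melt(bound) - tm_from_melt(free)
}

#' Hill fit of a fraction-bound binding curve
#'
#' Fits f(c) = c^n / (K^n + c^n) by Levenberg-Marquardt, started from the
#' linearized Hill plot (logit f vs log c).
#'
#' @param curve data.frame with columns conc (uM, strictly increasing) and
#'   fraction (in [0, 1]).
#' @return list(k_half (uM), n, se (named), ci95 (2 x 2 matrix)).
#' @export
hill_fit <- function(curve) {
  stopifnot(all(c("conc", "fraction") %in% names(curve)),
            nrow(curve) >= 5L,
            !is.unsorted(curve$conc, strictly = TRUE))
  if (any(curve$fraction < 0 | curve$fraction > 1))
    stop("fractions must lie in [0, 1]")
  f <- curve$fraction; c_ <- curve$conc
  if (stats::sd(f) < 1e-12) stop("flat binding data, cannot fit")
  inner <- f > 1e-6 & f < 1 - 1e-6
  if (sum(inner) >= 2) {
    lf <- stats::lm(stats::qlogis(f[inner]) ~ log(c_[inner]))
    n0 <- max(0.2, unname(stats::coef(lf)[2]))
    k0 <- exp(-unname(stats::coef(lf)[1] / stats::coef(lf)[2]))
  } else {
    n0 <- 1; k0 <- stats::median(c_)
  }
  fit <- minpack.lm::nlsLM(
    f ~ c_^n / (k^n + c_^n),
    start = list(k = k0, n = n0),
    lower = c(k = 1e-6, n = 0.05),
    control = minpack.lm::nls.lm.control(maxiter = 300))
  co <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))),
                 error = function(e) c(k = NA_real_, n = NA_real_))
  ci <- cbind(lower = co - 1.96 * se, upper = co + 1.96 * se)
  list(k_half = unname(co["k"]), n = unname(co["n"]),
       se = se, ci95 = ci)
}
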