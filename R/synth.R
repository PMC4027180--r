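#' Specification of the synthetic study system
#'
#' One object holds every planted ground-truth parameter the generators
#' share: a 76-residue winged helix-turn-helix protein with an
#' alpha-beta-alpha-alpha-beta-beta-alpha topology, a 24-residue DNA-binding
#' face, 8.4 ns tumbling at 600 MHz, sequential two-site binding (site-1 Kd
#' 40 nM endothermic +10 kcal/mol; site-2 Kd 5 uM exothermic -5 kcal/mol),
#' a 2:1 protein:DNA titration breakpoint, duplex stabilization by 10 C,
#' Hill cooperativity 4.5, a 355 -> 350 nm tryptophan blue shift, and a
#' promoter with two TTAA-N7-TTAA operators at TSS spans (-92,-78) and
#' (-28,-14). Defaults mirror the characterized system; noise levels are
#' fractional/absolute per data type and may be zeroed for exact round
#' trips.
#'
#' @param seed Integer master seed; per-data-type sub-streams are derived
#'   deterministically from it.
#' @param n_residues Protein length.
#' @param topology data.frame(element in H/E/C, start, end), ordered,
#'   non-overlapping, within range. Only H/E segments need listing.
#' @param interface_residues Residue indices of the planted DNA-binding
#'   face.
#' @param tau_c Rotational correlation time (ns).
#' @param field_1h Spectrometer 1H frequency (MHz).
#' @param itc list(kd1, kd2 (M), dh1, dh2 (kcal/mol)).
#' @param stoich_break Protein:DNA molar ratio at the titration breakpoint.
#' @param tm_free,tm_bound Duplex melting midpoints (C).
#' @param hill_n,hill_k Hill coefficient and half-saturation (uM).
#' @param lambda_free,lambda_bound Emission maxima (nm).
#' @param noise Named list of noise levels (>= 0): shift_ca/shift_ha (ppm),
#'   peak_h/peak_n (ppm), peak_i (fractional), relax (fractional), itc
#'   (fraction of the largest heat), curve (fractional).
#' @return Validated list of class `synth_spec`.
#' @export
synth_spec <- function(seed = 1L,
                       n_residues = 76L,
                       topology = default_topology(),
                       interface_residues = default_interface(),
                       tau_c = 8.4, field_1h = 600,
                       itc = list(kd1 = 40e-9, kd2 = 5e-6,
                                  dh1 = 10, dh2 = -5),
                       stoich_break = 2.0,
                       tm_free = 55, tm_bound = 65,
                       hill_n = 4.5, hill_k = 12,
                       lambda_free = 355, lambda_bound = 350,
                       noise = list(shift_ca = 0.1, shift_ha = 0.01,
                                    peak_h = 0.005, peak_n = 0.025,
                                    peak_i = 0.05, relax = 0.02,
                                    itc = 0.02, curve = 0.01)) {
  seed <- as.integer(seed)
  stopifnot(n_residues >= 1L, tau_c > 0, field_1h > 0,
            itc$kd1 > 0, itc$kd2 > 0, stoich_break > 0,
            tm_free > 0, tm_bound > 0, hill_n > 0, hill_k > 0,
            all(unlist(noise) >= 0))
  if (nrow(topology) > 0) {
    stopifnot(all(topology$element %in% c("H", "E", "C")),
              all(topology$start >= 1L), all(topology$end <= n_residues),
              all(topology$start <= topology$end))
    if (nrow(topology) > 1) {
      o <- order(topology$start)
      if (!identical(o, seq_len(nrow(topology))) ||
          any(topology$start[-1] <= topology$end[-nrow(topology)]))
        stop("topology segments must be ordered and non-overlapping")
    }
  }
  if (length(interface_residues) > 0)
    stopifnot(all(interface_residues >= 1L),
              all(interface_residues <= n_residues))
  structure(list(seed = seed, n_residues = as.integer(n_residues),
                 topology = topology,
                 interface_residues = sort(unique(as.integer(interface_residues))),
                 tau_c = tau_c, field_1h = field_1h, itc = itc,
                 stoich_break = stoich_break,
                 tm_free = tm_free, tm_bound = tm_bound,
                 hill_n = hill_n, hill_k = hill_k,
                 lambda_free = lambda_free, lambda_bound = lambda_bound,
                 noise = noise),
            class = "synth_spec")
}

#' Default secondary-structure topology of the synthetic protein
#'
#' Helix/strand boundaries of the characterized fold: alpha1 8-18, beta1
#' 21-23, alpha2 24-31, alpha3 35-48, beta2 51-58, beta3 61-68, plus the
#' short C-terminal helical stretch 72-76.
#' @return data.frame(element, start, end).
#' @export
default_topology <- function() {
  data.frame(element = c("H", "E", "H", "H", "E", "E", "H"),
             start = c(8L, 21L, 24L, 35L, 51L, 61L, 72L),
             end = c(18L, 23L, 31L, 48L, 58L, 68L, 76L))
}

#' Default planted DNA-binding interface (24 residues)
#'
#' N-terminal stretch, helix alpha2, the alpha2-alpha3 loop, recognition
#' helix alpha3 and the beta-wing.
#' @return Integer residue vector.
#' @export
default_interface <- function() {
  c(9L, 10L, 11L, 24L, 25L, 26L, 28L, 29L, 33L, 34L,
    35L, 44L, 46L, 47L, 51L, 52L, 53L, 55L, 56L, 57L, 58L, 60L, 62L, 63L)
}

# deterministic per-data-type sub-seed below 2^31
.sub_seed <- function(spec, key) {
  h <- sum(utf8ToInt(key) * seq_along(utf8ToInt(key)))
  as.integer((abs(spec$seed) %% 1000003L) * 2017L + h * 131L + 7L) %% 2147483647L
}

# evaluate expr under a derived seed without disturbing the caller's stream
.with_subseed <- function(spec, key, expr) {
  had <- exists(".Random.seed", envir = globalenv())
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(.sub_seed(spec, key))
  force(expr)
}

# per-residue H/E/C labels from the topology
.labels_from_topology <- function(spec) {
  lab <- rep("C", spec$n_residues)
  tp <- spec$topology
  if (nrow(tp) > 0)
    for (i in seq_len(nrow(tp)))
      lab[tp$start[i]:tp$end[i]] <- tp$element[i]
  lab
}

# deterministic synthetic amino-acid sequence (no proline, so every residue
# has an amide)
.synth_sequence <- function(spec) {
  aas <- setdiff(random_coil_shifts()$aa, "P")
  .with_subseed(spec, "sequence",
                sample(aas, spec$n_residues, replace = TRUE))
}

#' Generate a backbone chemical-shift table
#'
#' Calpha/Halpha = residue random-coil value + secondary-structure offset
#' (helix: +2.5 / -0.25 ppm; strand: -2.0 / +0.35 ppm; coil: 0) + Gaussian
#' noise; amide N/HN are drawn around their coil values within physical
#' ranges.
#'
#' @param spec [synth_spec()].
#' @return data.frame residue, aa, ca, ha, n, hn (ppm).
#' @export
gen_shift_table <- function(spec) {
  lab <- .labels_from_topology(spec)
  aa <- .synth_sequence(spec)
  rc <- random_coil_shifts()
  idx <- match(aa, rc$aa)
  off_ca <- c(H = 2.5, E = -2.0, C = 0)[lab]
  off_ha <- c(H = -0.25, E = 0.35, C = 0)[lab]
  .with_subseed(spec, "shifts", {
    n <- spec$n_residues
    data.frame(residue = seq_len(n), aa = aa,
               ca = rc$ca[idx] + off_ca + stats::rnorm(n, 0, spec$noise$shift_ca),
               ha = rc$ha[idx] + off_ha + stats::rnorm(n, 0, spec$noise$shift_ha),
               n = rc$n[idx] + stats::rnorm(n, 0, 1.5),
               hn = rc$hn[idx] + stats::rnorm(n, 0, 0.25))
  })
}

#' Generate a free/bound HSQC peak-list pair
#'
#' Bound peaks of interface residues are displaced (combined perturbation
#' well above the global mean + SD) and attenuated; non-interface residues
#' move only by the noise level.
#'
#' @param spec [synth_spec()].
#' @return list(free, bound) peak-list data.frames (residue, aa, h, n,
#'   intensity) and `truth` (interface residues).
#' @export
gen_hsqc_pair <- function(spec) {
  aa <- .synth_sequence(spec)
  .with_subseed(spec, "hsqc", {
    n <- spec$n_residues
    h <- stats::runif(n, 7.5, 9.5)
    nn <- stats::runif(n, 106, 130)
    inten <- stats::runif(n, 0.8, 1.2)
    free <- data.frame(residue = seq_len(n), aa = aa, h = h, n = nn,
                       intensity = inten)
    is_if <- seq_len(n) %in% spec$interface_residues
    d_h <- ifelse(is_if,
                  sample(c(-1, 1), n, replace = TRUE) *
                    stats::runif(n, 0.10, 0.25), 0) +
      stats::rnorm(n, 0, spec$noise$peak_h)
    d_n <- ifelse(is_if,
                  sample(c(-1, 1), n, replace = TRUE) *
                    stats::runif(n, 0.5, 1.25), 0) +
      stats::rnorm(n, 0, spec$noise$peak_n)
    att <- ifelse(is_if, stats::runif(n, 0.25, 0.5), 1) *
      (1 + stats::rnorm(n, 0, spec$noise$peak_i))
    bound <- data.frame(residue = seq_len(n), aa = aa,
                        h = h + d_h, n = nn + d_n,
                        intensity = pmax(inten * att, 1e-6))
    list(free = free, bound = bound, truth = spec$interface_residues)
  })
}

#' Generate 15N relaxation decay series
#'
#' Rigid-core residues decay at the R1/R2 of the rigid isotropic rotor at
#' the spec's (tau_c, field); flexible terminal residues use a shorter
#' effective correlation time to emulate elevated mobility.
#'
#' @param spec [synth_spec()].
#' @param n_rigid Number of rigid residues (default 54).
#' @param n_flexible Flexible N-terminal residues (default 5).
#' @param r1_delays,r2_delays Delay vectors (s), >= 4 distinct values each.
#' @param tau_c_flexible Effective tau_c of flexible residues (ns).
#' @return list(field_1h, residues = list of per-residue series, truth).
#' @export
gen_relaxation_series <- function(spec, n_rigid = 54L, n_flexible = 5L,
                                  r1_delays = seq(0.02, 1.2, length.out = 8),
                                  r2_delays = seq(0.01, 0.17, length.out = 8),
                                  tau_c_flexible = 2.5) {
  if (length(unique(r1_delays)) < 4L || length(unique(r2_delays)) < 4L)
    stop("degenerate delay design: need >= 4 distinct delays per experiment")
  rigid <- predict_rates(spec$tau_c, spec$field_1h)
  flex <- predict_rates(tau_c_flexible, spec$field_1h)
  .with_subseed(spec, "relax", {
    make_res <- function(i, rates, flexible) {
      i0 <- stats::runif(1, 0.8, 1.2)
      mk <- function(delays, r) {
        y <- i0 * exp(-r * delays)
        data.frame(delay = delays,
                   intensity = y + stats::rnorm(length(y), 0,
                                                spec$noise$relax * i0))
      }
      list(residue = i, r1 = mk(r1_delays, rates$r1),
           r2 = mk(r2_delays, rates$r2), flexible = flexible)
    }
    residues <- c(
      lapply(seq_len(n_flexible), make_res, rates = flex, flexible = TRUE),
      lapply(n_flexible + seq_len(n_rigid), make_res, rates = rigid,
             flexible = FALSE))
    list(field_1h = spec$field_1h, residues = residues,
         truth = list(tau_c = spec$tau_c,
                      flexible = seq_len(n_flexible)))
  })
}

#' Generate an ITC thermogram under the sequential two-site model
#'
#' @param spec [synth_spec()].
#' @param cell_conc,syringe_conc Concentrations (M).
#' @param n_inj Number of injections (>= 10).
#' @param inj_vol Volume per injection (L).
#' @param cell_volume Cell volume (L).
#' @return list(design, thermogram (data.frame with noisy heats), truth).
#' @export
gen_itc_thermogram <- function(spec, cell_conc = 10e-6,
                               syringe_conc = 100e-6, n_inj = 20L,
                               inj_vol = 2e-6, cell_volume = 200e-6) {
  stopifnot(n_inj >= 10L)
  design <- itc_design(cell_volume = cell_volume, cell_conc = cell_conc,
                       syringe_conc = syringe_conc,
                       inj_volumes = rep(inj_vol, n_inj))
  params <- seq_params(spec$itc$kd1, spec$itc$kd2, spec$itc$dh1, spec$itc$dh2)
  tg <- simulate_heats(params, design)
  .with_subseed(spec, "itc", {
    scale <- max(abs(tg$heat), 1e-12)
    tg$heat <- tg$heat + stats::rnorm(nrow(tg), 0, spec$noise$itc * scale)
    list(design = design, thermogram = tg, truth = params)
  })
}

#' Generate a two-segment titration curve
#'
#' Linear signal rising to the stoichiometric breakpoint, then a much
#' shallower segment (binding-site saturation).
#'
#' @param spec [synth_spec()].
#' @param ratios Molar-ratio grid (default 12 points over 0-4).
#' @param slope1,slope2 Segment slopes.
#' @return data.frame ratio, signal.
#' @export
gen_titration_curve <- function(spec, ratios = seq(0, 4, length.out = 12),
                                slope1 = 1.0, slope2 = 0.05) {
  s <- slope1 * pmin(ratios, spec$stoich_break) +
    slope2 * pmax(ratios - spec$stoich_break, 0)
  .with_subseed(spec, "titration", {
    data.frame(ratio = ratios,
               signal = s + stats::rnorm(length(s), 0,
                                         spec$noise$curve * max(abs(s))))
  })
}

#' Generate paired free/bound duplex melting curves
#'
#' Two-state hyperchromic sigmoids centred at tm_free and tm_bound.
#'
#' @param spec [synth_spec()].
#' @param temperatures Temperature grid (C).
#' @param width Transition width (C).
#' @return list(free, bound) data.frames (temperature, a260).
#' @export
gen_melting_pair <- function(spec,
                             temperatures = seq(20, 80, by = 0.5),
                             width = 2.5) {
  sig <- function(tm)
    0.60 + 0.25 / (1 + exp(-(temperatures - tm) / width))
  .with_subseed(spec, "melt", {
    mk <- function(tm) data.frame(
      temperature = temperatures,
      a260 = sig(tm) + stats::rnorm(length(temperatures), 0,
                                    spec$noise$curve * 0.25))
    list(free = mk(spec$tm_free), bound = mk(spec$tm_bound))
  })
}

#' Generate a fraction-bound cooperativity curve
#'
#' Hill function f(c) = c^n / (K^n + c^n) evaluated at the EMSA protein
#' concentrations; noisy values are clipped back into [0, 1].
#'
#' @param spec [synth_spec()].
#' @param conc Protein concentrations (uM); default the gel-titration
#'   series 3.2-32.4 uM.
#' @return data.frame conc, fraction.
#' @export
gen_emsa_curve <- function(spec,
                           conc = c(3.2, 6.4, 9.6, 12.8, 16, 19.2,
                                    22.4, 25.8, 32.4)) {
  f <- conc^spec$hill_n / (spec$hill_k^spec$hill_n + conc^spec$hill_n)
  .with_subseed(spec, "emsa", {
    data.frame(conc = conc,
               fraction = pmin(1, pmax(0, f + stats::rnorm(
                 length(f), 0, spec$noise$curve))))
  })
}

#' Generate free/bound tryptophan emission spectra
#'
#' Gaussian emission bands at lambda_free (full amplitude) and lambda_bound
#' (quenched), for blue-shift analysis.
#'
#' @param spec [synth_spec()].
#' @param wavelength Grid (nm).
#' @param bandwidth Gaussian sigma (nm).
#' @return list(wavelength, free, bound) intensity vectors.
#' @export
gen_emission_pair <- function(spec, wavelength = seq(310, 420, by = 1),
                              bandwidth = 25) {
  band <- function(center, amp)
    amp * exp(-(wavelength - center)^2 / (2 * bandwidth^2))
  .with_subseed(spec, "emission", {
    ns <- function() stats::rnorm(length(wavelength), 0, spec$noise$curve)
    list(wavelength = wavelength,
         free = band(spec$lambda_free, 1.0) + ns(),
         bound = band(spec$lambda_bound, 0.6) + ns())
  })
}

#' Generate a promoter sequence with two planted operators
#'
#' Random background spanning TSS coordinates -120..+40 with the 15-nt
#' operator core TTAATAAAGTGTTAA planted at TSS spans (-92,-78) (site A,
#' inside the direct-repeat context AGTA...T) and (-28,-14) (site B). The
#' background is screened so that exactly the planted TTAA-N7-TTAA pairs
#' are present (or none, when `plant_sites = FALSE`).
#'
#' @param spec [synth_spec()].
#' @param plant_sites Plant the two operators (default TRUE).
#' @return `dna_sequence` with attribute `truth` (planted 1-based spans and
#'   TSS spans).
#' @export
gen_promoter <- function(spec, plant_sites = TRUE) {
  core <- "TTAATAAAGTGTTAA"              # site A 15-nt operator
  site_a_context <- "AGTATTAATAAAGTGTTAAT" # direct-repeat 20-mer
  tss_offset <- -120L
  len <- 160L
  to_index <- function(tss) tss - tss_offset + 1L   # negative coords only
  a_start <- to_index(-92L); b_start <- to_index(-28L)
  .with_subseed(spec, "promoter", {
    for (try_i in 1:200) {
      bg <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                  collapse = "")
      s <- bg
      if (plant_sites) {
        # site A with its 20-mer direct-repeat context (core at offset 5)
        substr(s, a_start - 4L, a_start + 15L) <- site_a_context
        substr(s, b_start, b_start + 14L) <- core
      }
      pairs <- find_paired_sites(s)
      ok <- if (plant_sites)
        nrow(pairs) == 2L &&
          all(pairs$first_start == c(a_start, b_start)) else
        nrow(pairs) == 0L
      if (ok) {
        out <- dna_sequence(s, name = "synthetic_promoter",
                            tss_offset = tss_offset)
        attr(out, "truth") <- list(
          planted = plant_sites,
          site_a = c(start = a_start, end = a_start + 14L),
          site_b = c(start = b_start, end = b_start + 14L),
          tss_spans = list(site_a = c(-92L, -78L), site_b = c(-28L, -14L)))
        return(out)
      }
    }
    stop("could not screen a background free of spurious operator pairs")
  })
}
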