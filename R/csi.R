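#' Random-coil chemical shift reference
#'
#' Residue-specific random-coil shifts (ppm) for Calpha and Halpha used by
#' the chemical shift index, after the Wishart random-coil compilation, plus
#' nominal amide 15N/1HN coil values used only by the synthetic generator.
#' One frozen table version; values in ppm at neutral pH.
#'
#' @return data.frame with columns aa, ca, ha, n, hn.
#' @export
random_coil_shifts <- function() {
  data.frame(
    aa = c("A","C","D","E","F","G","H","I","K","L",
           "M","N","P","Q","R","S","T","V","W","Y"),
    ca = c(52.5, 58.2, 54.2, 56.6, 57.7, 45.1, 55.0, 61.1, 56.2, 55.1,
           55.4, 53.1, 63.3, 55.7, 56.0, 58.3, 61.8, 62.2, 57.5, 57.9),
    ha = c(4.32, 4.55, 4.64, 4.35, 4.62, 3.96, 4.73, 4.17, 4.32, 4.34,
           4.48, 4.74, 4.42, 4.34, 4.34, 4.47, 4.35, 4.12, 4.66, 4.55),
    n  = c(123.8, 118.8, 120.4, 120.2, 120.3, 108.8, 118.2, 119.9, 120.4,
           121.8, 119.6, 118.7, NA, 119.8, 120.5, 115.7, 113.6, 119.2,
           121.3, 120.3),
    hn = c(8.24, 8.32, 8.34, 8.42, 8.30, 8.33, 8.42, 8.00, 8.29, 8.16,
           8.28, 8.40, NA, 8.32, 8.23, 8.31, 8.15, 8.03, 8.25, 8.12),
    stringsAsFactors = FALSE)
}

#' Secondary chemical shifts relative to random coil
#'
#' @param shifts data.frame with columns residue, aa, ca, ha (ppm); ca/ha may
#'   contain NA.
#' @param rc Random-coil reference table (default [random_coil_shifts()]).
#' @return data.frame residue, aa, dca, dha (observed minus coil; NA
#'   propagates).
#' @export
compute_deltas <- function(shifts, rc = random_coil_shifts()) {
  stopifnot(all(c("residue", "aa", "ca", "ha") %in% names(shifts)))
  unknown <- setdiff(unique(shifts$aa), rc$aa)
  if (length(unknown) > 0L)
    stop("unknown amino-acid code(s): ", paste(unknown, collapse = ", "))
  idx <- match(shifts$aa, rc$aa)
  data.frame(residue = shifts$residue, aa = shifts$aa,
             dca = shifts$ca - rc$ca[idx],
             dha = shifts$ha - rc$ha[idx])
}

#' Chemical shift index per nucleus
#'
#' Calpha: +1 above +0.7 ppm, -1 below -0.7 ppm; Halpha: -1 below -0.1 ppm,
#' +1 above +0.1 ppm; 0 otherwise (helix pattern is Calpha +1 with
#' Halpha -1). Thresholds follow the classical CSI method.
#'
#' @param deltas Output of [compute_deltas()].
#' @param ca_threshold,ha_threshold Index thresholds in ppm.
#' @return data.frame residue, idx_ca, idx_ha (NA shift gives index 0).
#' @export
csi_index <- function(deltas, ca_threshold = 0.7, ha_threshold = 0.1) {
  band <- function(x, thr) {
    i <- integer(length(x))
    i[!is.na(x) & x > thr] <- 1L
    i[!is.na(x) & x < -thr] <- -1L
    i
  }
  data.frame(residue = deltas$residue,
             idx_ca = band(deltas$dca, ca_threshold),
             idx_ha = band(deltas$dha, ha_threshold))
}

#' Call secondary structure from chemical shift indices
#'
#' Per-residue consensus: a residue is helix-consistent when idx_ca = +1 and
#' idx_ha = -1, strand-consistent for the opposite pattern. In the default
#' `"window"` mode the per-residue call is smoothed by majority over a
#' 3-residue window; `"strict"` requires the per-residue AND with no
#' smoothing. Runs shorter than `min_helix` (4) / `min_strand` (3) become
#' coil. The topology string concatenates segment labels (Greek alpha/beta).
#'
#' @param indices Output of [csi_index()].
#' @param mode "window" (3-residue majority) or "strict".
#' @param min_helix,min_strand Minimum run lengths.
#' @return list(labels = per-residue H/E/C data.frame, segments = data.frame
#'   (label, start, end), topology = character).
#' @export
call_secondary_structure <- function(indices, mode = c("window", "strict"),
                                     min_helix = 4L, min_strand = 3L) {
  mode <- match.arg(mode)
  stopifnot(nrow(indices) >= 1L)
  raw <- ifelse(indices$idx_ca == 1L & indices$idx_ha == -1L, "H",
         ifelse(indices$idx_ca == -1L & indices$idx_ha == 1L, "E", "C"))
  lab <- raw
  if (mode == "window" && length(raw) >= 3L) {
    for (i in seq_along(raw)) {
      win <- raw[max(1L, i - 1L):min(length(raw), i + 1L)]
      nh <- sum(win == "H"); ne <- sum(win == "E")
      lab[i] <- if (nh >= 2L) "H" else if (ne >= 2L) "E" else "C"
    }
  }
  # enforce minimum run lengths
  r <- rle(lab)
  keep_h <- r$values == "H" & r$lengths < min_helix
  keep_e <- r$values == "E" & r$lengths < min_strand
  r$values[keep_h | keep_e] <- "C"
  lab <- inverse.rle(r)
  r2 <- rle(lab)
  ends <- cumsum(r2$lengths); starts <- ends - r2$lengths + 1L
  seg_keep <- r2$values != "C"
  segments <- data.frame(label = r2$values[seg_keep],
                         start = indices$residue[starts[seg_keep]],
                         end = indices$residue[ends[seg_keep]])
  topo <- paste(ifelse(segments$label == "H", "α", "β"),
                collapse = "")
  list(labels = data.frame(residue = indices$residue, label = lab),
       segments = segments, topology = topo)
}

#' Full CSI pipeline from a shift table
#'
#' @param shifts Shift table (see [compute_deltas()]).
#' @inheritParams call_secondary_structure
#' @return As [call_secondary_structure()].
#' @export
csi_call <- function(shifts, mode = "window") {
  call_secondary_structure(csi_index(compute_deltas(shifts)), mode = mode)
}
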