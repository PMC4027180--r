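#' Molar extinction coefficient at 280 nm from composition
#'
#' Standard chromophore weights: 5500 (Trp), 1490 (Tyr) and 125 (cystine,
#' i.e. per disulfide bond) M^-1 cm^-1. One Trp, three Tyr and one disulfide
#' give 10 095 M^-1 cm^-1.
#'
#' @param n_trp,n_tyr,n_ss Non-negative counts of tryptophans, tyrosines and
#'   disulfide bonds.
#' @return Extinction coefficient in M^-1 cm^-1.
#' @export
extinction_coefficient <- function(n_trp, n_tyr, n_ss = 0) {
  stopifnot(n_trp >= 0, n_tyr >= 0, n_ss >= 0)
  5500 * n_trp + 1490 * n_tyr + 125 * n_ss
}
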