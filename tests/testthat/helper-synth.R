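# shared fixtures built in code

zero_noise <- list(shift_ca = 0, shift_ha = 0, peak_h = 0, peak_n = 0,
                   peak_i = 0, relax = 0, itc = 0, curve = 0)

noiseless_spec <- function(seed = 1L, ...) {
  synth_spec(seed = seed, noise = zero_noise, ...)
}

# printed probe sequences (top strand)
probe_a <- "GGAAACAGTATTAATAAAGTGTTAATCCTATTACCC"
probe_a_mut <- "GGAAACAGTATTAATAAAGTGCCGTTCCTATTACC"
site_a_20mer <- "AGTATTAATAAAGTGTTAAT"

# brute-force all-substrings motif oracle (independent of scan_motif)
oracle_scan <- function(bases, motif) {
  n <- nchar(bases); m <- nchar(motif)
  if (n < m) return(integer(0))
  which(vapply(seq_len(n - m + 1L),
               function(i) substr(bases, i, i + m - 1L) == motif,
               logical(1)))
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# minimal multi-MODEL PDB text from a list of coordinate data.frames
write_pdb_models <- function(models, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_along(models)) {
    writeLines(sprintf("MODEL     %4d", m), con)
    df <- models[[m]]
    for (i in seq_len(nrow(df))) {
      writeLines(sprintf(
        "ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
        i, substr(paste0(" ", df$atom[i]), 1, 4), df$resname[i],
        df$residue[i], df$x[i], df$y[i], df$z[i],
        substr(df$atom[i], 1, 1)), con)
    }
    writeLines(c("ENDMDL"), con)
  }
  writeLines("END", con)
}

random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

# backbone fragment built by sequential atom placement (NeRF) with ideal
# geometry and prescribed phi/psi; independent of the dihedral measurement
build_backbone <- function(n_res, phi, psi, omega = 180) {
  place <- function(a, b, c, bond, angle, torsion) {
    ang <- angle * pi / 180; tor <- torsion * pi / 180
    bc <- (c - b); bc <- bc / sqrt(sum(bc^2))
    ab <- (b - a)
    n <- c(ab[2] * bc[3] - ab[3] * bc[2], ab[3] * bc[1] - ab[1] * bc[3],
           ab[1] * bc[2] - ab[2] * bc[1])
    n <- n / sqrt(sum(n^2))
    m <- c(n[2] * bc[3] - n[3] * bc[2], n[3] * bc[1] - n[1] * bc[3],
           n[1] * bc[2] - n[2] * bc[1])
    d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(tor),
            bond * sin(ang) * sin(tor))
    c + d2[1] * bc + d2[2] * m + d2[3] * n
  }
  b_nc <- 1.329; b_cn <- 1.458; b_cc <- 1.525
  a_nca <- 121.7; a_cac <- 111.2; a_cn <- 116.2
  coords <- list(N1 = c(0, 0, 0), CA1 = c(b_cn, 0, 0),
                 C1 = c(b_cn - b_cc * cos(a_cac * pi / 180),
                        b_cc * sin(a_cac * pi / 180), 0))
  atoms <- data.frame(residue = 1L, atom = c("N", "CA", "C"),
                      x = NA_real_, y = NA_real_, z = NA_real_)
  atoms[1, 3:5] <- coords$N1; atoms[2, 3:5] <- coords$CA1
  atoms[3, 3:5] <- coords$C1
  prev <- list(n = coords$N1, ca = coords$CA1, c = coords$C1)
  for (r in 2:n_res) {
    n_new <- place(prev$n, prev$ca, prev$c, b_nc, a_cn, psi)
    ca_new <- place(prev$ca, prev$c, n_new, b_cn, a_nca, omega)
    c_new <- place(prev$c, n_new, ca_new, b_cc, a_cac, phi)
    atoms <- rbind(atoms,
                   data.frame(residue = r, atom = c("N", "CA", "C"),
                              x = c(n_new[1], ca_new[1], c_new[1]),
                              y = c(n_new[2], ca_new[2], c_new[2]),
                              z = c(n_new[3], ca_new[3], c_new[3])))
    prev <- list(n = n_new, ca = ca_new, c = c_new)
  }
  atoms$resname <- "ALA"
  atoms
}
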