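#' Read a FASTA file as a list of dna_sequence objects
#' @param path FASTA file.
#' @param tss_offset Optional TSS-relative coordinate of base 1 (applied to
#'   every record).
#' @return List of `dna_sequence`.
#' @export
read_fasta_dna <- function(path, tss_offset = NULL) {
  set <- Biostrings::readDNAStringSet(path)
  lapply(seq_along(set), function(i)
    dna_sequence(as.character(set[[i]]), name = names(set)[i],
                 tss_offset = tss_offset))
}

#' Write dna_sequence objects to FASTA
#' @param seqs List of `dna_sequence` (or one).
#' @param path Output file.
#' @export
write_fasta_dna <- function(seqs, path) {
  if (inherits(seqs, "dna_sequence")) seqs <- list(seqs)
  set <- Biostrings::DNAStringSet(vapply(seqs, `[[`, character(1), "bases"))
  names(set) <- vapply(seqs, `[[`, character(1), "name")
  Biostrings::writeXStringSet(set, path)
}

#' Write a shift table as an NMR-STAR assigned-chemical-shift loop
#'
#' Emits the minimal `_Atom_chem_shift` loop dialect (sequence code,
#' one-letter-expanded residue type, atom name, shift value). Only the
#' chemical-shift loop is written, not a full STAR entry.
#'
#' @param shifts data.frame residue, aa, ca, ha, n, hn (ppm; NA skipped).
#' @param path Output file.
#' @export
write_nmrstar_shifts <- function(shifts, path) {
  three <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE",
             G = "GLY", H = "HIS", I = "ILE", K = "LYS", L = "LEU",
             M = "MET", N = "ASN", P = "PRO", Q = "GLN", R = "ARG",
             S = "SER", T = "THR", V = "VAL", W = "TRP", Y = "TYR")
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("loop_",
               "   _Atom_chem_shift.ID",
               "   _Atom_chem_shift.Seq_ID",
               "   _Atom_chem_shift.Comp_ID",
               "   _Atom_chem_shift.Atom_ID",
               "   _Atom_chem_shift.Val"), con)
  id <- 0L
  atom_map <- c(ca = "CA", ha = "HA", n = "N", hn = "H")
  for (i in seq_len(nrow(shifts))) {
    for (col in names(atom_map)) {
      v <- shifts[[col]][i]
      if (is.na(v)) next
      id <- id + 1L
      writeLines(sprintf("   %d %d %s %s %.3f", id, shifts$residue[i],
                         three[[shifts$aa[i]]], atom_map[[col]], v), con)
    }
  }
  writeLines("stop_", con)
}

#' Read an NMR-STAR assigned-chemical-shift loop into a shift table
#'
#' Parses the `_Atom_chem_shift` loop of an NMR-STAR file (the deposited
#' chemical-shift dialect): tag lines define column order, data rows follow
#' until `stop_`. Atoms other than CA/HA/N/H are ignored.
#'
#' @param path NMR-STAR file containing one chemical-shift loop.
#' @return data.frame residue, aa, ca, ha, n, hn.
#' @export
read_nmrstar_shifts <- function(path) {
  lines <- readLines(path)
  tag_idx <- grep("^\\s*_Atom_chem_shift\\.", lines)
  if (length(tag_idx) == 0L) stop("no _Atom_chem_shift loop found")
  tags <- sub("^\\s*_Atom_chem_shift\\.", "", trimws(lines[tag_idx]))
  body_start <- max(tag_idx) + 1L
  stop_line <- grep("^\\s*stop_", lines)
  stop_line <- min(stop_line[stop_line >= body_start], length(lines) + 1L)
  rows <- lines[body_start:(stop_line - 1L)]
  rows <- trimws(rows)
  rows <- rows[nzchar(rows) & !startsWith(rows, "#")]
  if (length(rows) == 0L) stop("empty chemical-shift loop")
  mat <- do.call(rbind, strsplit(rows, "\\s+"))
  if (ncol(mat) < length(tags)) stop("malformed chemical-shift loop")
  col <- function(nm) mat[, match(nm, tags)]
  need <- c("Seq_ID", "Comp_ID", "Atom_ID", "Val")
  if (!all(need %in% tags)) stop("chemical-shift loop lacks required tags")
  one <- c(ALA = "A", CYS = "C", ASP = "D", GLU = "E", PHE = "F",
           GLY = "G", HIS = "H", ILE = "I", LYS = "K", LEU = "L",
           MET = "M", ASN = "N", PRO = "P", GLN = "Q", ARG = "R",
           SER = "S", THR = "T", VAL = "V", TRP = "W", TYR = "Y")
  df <- data.frame(residue = as.integer(col("Seq_ID")),
                   aa = unname(one[col("Comp_ID")]),
                   atom = col("Atom_ID"),
                   val = as.numeric(col("Val")))
  res <- sort(unique(df$residue))
  out <- data.frame(residue = res, aa = NA_character_, ca = NA_real_,
                    ha = NA_real_, n = NA_real_, hn = NA_real_)
  slot <- c(CA = "ca", HA = "ha", N = "n", H = "hn", HN = "hn")
  for (i in seq_len(nrow(df))) {
    r <- match(df$residue[i], res)
    out$aa[r] <- df$aa[i]
    s <- slot[df$atom[i]]
    if (!is.na(s)) out[[s]][r] <- df$val[i]
  }
  out
}

#' Read a peak-list CSV (residue, aa, h, n, intensity)
#' @param path CSV file with a header.
#' @return Peak-list data.frame.
#' @export
read_peaklist_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("residue", "h", "n", "intensity") %in% names(df)))
  df
}

#' Read a relaxation-decay CSV (residue, delay_s, intensity) per experiment
#'
#' @param r1_path,r2_path CSVs for the R1 and R2 experiments.
#' @param field_1h 1H frequency (MHz).
#' @param flexible Residues to mark as flexible termini (coarse filter).
#' @return Series list consumable by [fit_rate_table()].
#' @export
read_relaxation_csv <- function(r1_path, r2_path, field_1h,
                                flexible = integer(0)) {
  rd <- function(p) {
    df <- utils::read.csv(p, stringsAsFactors = FALSE)
    stopifnot(all(c("residue", "delay_s", "intensity") %in% names(df)))
    df
  }
  d1 <- rd(r1_path); d2 <- rd(r2_path)
  res <- sort(intersect(unique(d1$residue), unique(d2$residue)))
  residues <- lapply(res, function(r) {
    a <- d1[d1$residue == r, ]; b <- d2[d2$residue == r, ]
    list(residue = r,
         r1 = data.frame(delay = a$delay_s, intensity = a$intensity),
         r2 = data.frame(delay = b$delay_s, intensity = b$intensity),
         flexible = r %in% flexible)
  })
  list(field_1h = field_1h, residues = residues)
}

#' Read a thermogram CSV (inj_vol_uL, heat_ucal)
#'
#' @param path CSV file.
#' @param design [itc_design()] giving cell volume/concentrations.
#' @return data.frame injection, volume (L), heat (cal) merged with the
#'   design.
#' @export
read_thermogram_csv <- function(path, design) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("inj_vol_uL", "heat_ucal") %in% names(df)))
  data.frame(injection = seq_len(nrow(df)),
             volume = df$inj_vol_uL * 1e-6,
             heat = df$heat_ucal * 1e-6)
}
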