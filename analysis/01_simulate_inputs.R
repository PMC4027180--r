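#!/usr/bin/env Rscript
# Generate the full synthetic input bundle (the stand-in for the study's raw
# spectra, thermograms and gels) and write it to disk in the standard
# formats the downstream steps read. Ground-truth parameters go to a JSON
# sidecar so every later step can be checked against what was planted.

suppressMessages(library(wingbind))

seed <- 7L
outdir <- "results/synth"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
spec <- synth_spec(seed = seed)

# promoter + probe sequences
prom <- gen_promoter(spec)
write_fasta_dna(prom, file.path(outdir, "promoter.fasta"))

# backbone shifts as an NMR-STAR chemical-shift loop
write_nmrstar_shifts(gen_shift_table(spec),
                     file.path(outdir, "shifts.str"))

# free/bound HSQC peak lists
pair <- gen_hsqc_pair(spec)
write.csv(pair$free, file.path(outdir, "hsqc_free.csv"), row.names = FALSE)
write.csv(pair$bound, file.path(outdir, "hsqc_bound.csv"), row.names = FALSE)

# relaxation decay series
series <- gen_relaxation_series(spec)
flat <- function(which) do.call(rbind, lapply(series$residues, function(r)
  data.frame(residue = r$residue, delay_s = r[[which]]$delay,
             intensity = r[[which]]$intensity)))
write.csv(flat("r1"), file.path(outdir, "relax_r1.csv"), row.names = FALSE)
write.csv(flat("r2"), file.path(outdir, "relax_r2.csv"), row.names = FALSE)

# ITC thermogram
sim <- gen_itc_thermogram(spec)
write.csv(data.frame(inj_vol_uL = sim$thermogram$volume * 1e6,
                     heat_ucal = sim$thermogram$heat * 1e6),
          file.path(outdir, "itc.csv"), row.names = FALSE)

# titration-style curves
write.csv(gen_titration_curve(spec), file.path(outdir, "cd_titration.csv"),
          row.names = FALSE)
mp <- gen_melting_pair(spec)
write.csv(mp$free, file.path(outdir, "melt_free.csv"), row.names = FALSE)
write.csv(mp$bound, file.path(outdir, "melt_bound.csv"), row.names = FALSE)
write.csv(gen_emsa_curve(spec), file.path(outdir, "emsa.csv"),
          row.names = FALSE)
em <- gen_emission_pair(spec)
write.csv(data.frame(wavelength = em$wavelength, free = em$free,
                     bound = em$bound),
          file.path(outdir, "emission.csv"), row.names = FALSE)

truth <- list(seed = seed,
              tau_c_ns = spec$tau_c, field_1h_MHz = spec$field_1h,
              itc = spec$itc, stoich_break = spec$stoich_break,
              tm_free = spec$tm_free, tm_bound = spec$tm_bound,
              hill_n = spec$hill_n, hill_k_uM = spec$hill_k,
              interface_residues = spec$interface_residues,
              topology = spec$topology,
              promoter_sites = attr(prom, "truth"))
jsonlite::write_json(truth, file.path(outdir, "ground_truth.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("synthetic bundle written to", outdir, "\n")
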