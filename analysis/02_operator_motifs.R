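#!/usr/bin/env Rscript
# Operator-motif architecture: scan the printed gel-shift probes and the
# synthetic promoter for TTAA cores, pair them at the 7-nt spacer, and do
# the TSS coordinate arithmetic for the classic spans.

suppressMessages(library(wingbind))
dir.create("results", showWarnings = FALSE)

probe_a <- dna_sequence("GGAAACAGTATTAATAAAGTGTTAATCCTATTACCC", "probe_A")
probe_a_mut <- dna_sequence("GGAAACAGTATTAATAAAGTGCCGTTCCTATTACC",
                            "probe_A_mut")

cat("probe A':  ", nrow(scan_motif(probe_a)), "TTAA hits,",
    nrow(find_paired_sites(probe_a)), "paired site(s)\n")
cat("probe A'*: ", nrow(scan_motif(probe_a_mut)), "TTAA hit(s),",
    nrow(find_paired_sites(probe_a_mut)), "paired site(s)\n")

pairs <- find_paired_sites(probe_a)
cat("paired site span:", pairs$span, "nt, spacer:", pairs$spacer,
    "nt, center-to-center:", pairs$center_distance, "bp\n")

rep_check <- direct_repeat_check(probe_a$bases)
cat("direct repeat:", rep_check$is_repeat, "(", rep_check$unit1, "/",
    rep_check$unit2, ",", rep_check$mismatches, "mismatches )\n")

cat("TSS spans: (-120,+17) =", tss_span_length(-120, 17), "bp;",
    "(-92,-78) =", tss_span_length(-92, -78), "nt;",
    "(-28,-14) =", tss_span_length(-28, -14), "nt\n")

prom <- read_fasta_dna("results/synth/promoter.fasta",
                       tss_offset = -120L)[[1]]
sites <- find_paired_sites(prom)
sites$tss_start <- sites$first_start + prom$tss_offset - 1L
sites$tss_end <- sites$second_end + prom$tss_offset - 1L
write.table(sites, "results/motif_sites.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("promoter scan:", nrow(sites), "paired sites; table in",
    "results/motif_sites.tsv\n")
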