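#!/usr/bin/env Rscript
# Step 1 — simulate a germline V gene and a set of mutated clones.
#
# Generates a 98-codon germline (Kabat-style FR/CDR map), mutates four
# clones with CDR2-weighted rates and a transversion-leaning proposal (the
# mutation landscape observed in the anti-LeY heavy chains), and writes
# FASTA, the planted-mutation ground truth, the region map and a manifest.

suppressPackageStartupMessages(library(somaticRS))

outdir <- "results/sim"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(seed = 20140812L, n_clones = 4L,
                  per_region_rate = c(FR1 = 0.02, CDR1 = 0.02, FR2 = 0.01,
                                      CDR2 = 0.10, FR3 = 0.03),
                  titv_ratio = 0.5)
sim <- simulate_clone_set(cfg)

write_fasta_sequences(
  stats::setNames(sim$germline$nucleotides, sim$germline$id),
  file.path(outdir, "germline.fasta"))
write_fasta_sequences(sim$clones, file.path(outdir, "clones.fasta"))
write.table(sim$truth, file.path(outdir, "truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write_region_map(sim$germline$regions, file.path(outdir, "regions.tsv"))

manifest <- list(seed = cfg$seed, n_clones = cfg$n_clones,
                 per_region_rate = as.list(cfg$per_region_rate),
                 titv_ratio = cfg$titv_ratio,
                 stop_codon_policy = cfg$stop_codon_policy,
                 n_codons = nchar(sim$germline$nucleotides) %/% 3L,
                 package_version = as.character(packageVersion("somaticRS")))
jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                     auto_unbox = TRUE, pretty = TRUE)

cat(sprintf("germline: %d nt; clones: %d; planted mutations: %d (%d CDR2)\n",
            nchar(sim$germline$nucleotides), length(sim$clones),
            nrow(sim$truth), sum(sim$truth$region == "CDR2")))
cat("outputs in", outdir, "\n")
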