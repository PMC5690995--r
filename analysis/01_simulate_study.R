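#!/usr/bin/env Rscript

# Stage 1: generate the synthetic commissioning study.
#
# One ground-truth compensator model (rho = 7.8 g/cm^3, MSF = 0.1 cm^-1)
# produces everything the two commissioning workflows consume: the
# slab-attenuation table over 9 (depth, field size) conditions with 0.5%
# ion-chamber repeatability noise, and 7 compensator-modulated fields
# measured on a 7 mm diode array. Re-running with the same seed rewrites
# byte-identical files.

suppressPackageStartupMessages(library(compcomm))

out_dir <- "results/study"
truth <- beam_model(rho = 7.8, msf = 0.1)
plan <- plan_spec() # 7 fields, 25 cm, 7 mm diodes, 5 mm calc grid

study <- simulate_study(
  out_dir, truth,
  plan = plan,
  noise = noise_spec(relative_sd = 0.005, seed = 20260930),
  kappa_jitter = 0.02 # small per-condition beam-quality spread
)

cat("ground truth:\n")
print(truth)
cat(sprintf("slab records: %d (%d conditions)\n", nrow(study$slabs),
            nrow(unique(study$slabs[c("depth_cm", "field_size_cm")]))))
cat(sprintf("fields: %d, measured grid %s\n", length(study$fields),
            paste(dim(study$fields[[1]]$measured$values), collapse = " x ")))
cat(sprintf("study written to %s\n", out_dir))
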