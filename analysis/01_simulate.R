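#!/usr/bin/env Rscript
# Generate the synthetic study: six species x ten replicates of compound
# concentrations (moment-matched lognormal around the reference means), Ct
# records coupled to compound levels (GLUD1-Glu at r = 0.90), and an HPLC
# standard series. All downstream drivers read these files.

suppressPackageStartupMessages(library(umamikit))

seed <- 42
outdir <- "results/sim"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

cfg <- generator_config(seed = seed)
compounds <- generate_compound_table(cfg)
write_concentration_table(compounds, file.path(outdir, "compounds.csv"))

sim <- generate_expression_and_compounds(cfg)
write.csv(sim$ct, file.path(outdir, "ct.csv"), row.names = FALSE)
write.csv(sim$latent, file.path(outdir, "latent.csv"), row.names = FALSE)
write_concentration_table(sim$compounds,
                          file.path(outdir, "coupled_compounds.csv"))

standards <- generate_hplc_standards(slope = 120, intercept = 4,
                                     noise_sd = 8, seed = seed)
write.csv(standards, file.path(outdir, "standards.csv"), row.names = FALSE)

cat("simulated", nrow(compounds), "replicate concentration rows,",
    nrow(sim$ct), "Ct records,", nrow(standards), "calibration standards\n")
cat("outputs under", outdir, "\n")
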