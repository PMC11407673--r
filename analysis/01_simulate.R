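#!/usr/bin/env Rscript
# Stage 1: generate the synthetic camera-trap study.
#
# Simulates 204 stations x 3 years of montane camera-trap survey under the
# single-season occupancy model (tree cover, elevation, distance to water
# and terrain ruggedness driving habitat use; effort driving detection)
# and writes the raw tables every later stage consumes: records,
# deployments and site covariates. About 59,700 trap-nights in total.

library(camoccu)

dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = 42)
study <- simulate_study(cfg)

write_records(study$records, "results/data/records.csv")
write_deployments(study$deployments, "results/data/deployments.csv")
write_covariates(study$covariates, "results/data/site_covariates.csv")

cat(sprintf("simulated %d stations x %d years -> %d stacked sites\n",
            cfg$n_stations, cfg$years_per_station, nrow(study$covariates)))
cat(sprintf("%d detection records, %d deployments\n",
            nrow(study$records), nrow(study$deployments)))
cat(sprintf("true habitat-use mean %.3f, occupied sites %d\n",
            mean(study$truth$psi), sum(study$truth$z)))
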