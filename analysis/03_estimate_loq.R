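#!/usr/bin/env Rscript
# Estimate LOD/LOQ from ten fixed-point pseudo-blank measurements: ten
# spectra of the same 0.3 ug/cm^2 spot (shared baseline, independent scan
# noise), predicted through the calibration of step 02, sd * {3.3, 10}.
# The LOQ is then recorded as the model's calibration floor.

suppressPackageStartupMessages(library(ftirclean))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1
dir.create("results", showWarnings = FALSE)
if (!file.exists("results/pls_model.json")) {
  stop("run analysis/02_calibrate_model.R first")
}

model <- read_pls_model("results/pls_model.json")
reps <- generate_pseudo_blank_replicates(
  0.3, 10, default_api_signature(), instrument_profile(),
  seed = seed * 1000 + 3
)
pred <- predict(model, reps$spectra)$density
res <- loq_from_replicates(pred, note = "simulated fixed point, 16-scan spectra")
print(res)

model <- apply_calibration_floor(model, res)
write_pls_model(model, "results/pls_model.json")
writeLines(
  c("statistic\tvalue",
    sprintf("n_replicates\t%d", res$n),
    sprintf("replicate_sd\t%.6f", res$sd),
    sprintf("lod\t%.6f", res$lod),
    sprintf("loq\t%.6f", res$loq)),
  "results/loq.tsv"
)
cat(sprintf(
  "LOQ %.3f ug/cm^2 recorded as the calibration floor (training range starts at %.2f).\n",
  res$loq, model$training_range[1]
))
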