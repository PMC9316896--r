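#!/usr/bin/env Rscript
# Fit the PLS surface-residue calibration on a simulated calibration set
# (levels 0.6-3.0 ug/cm^2, 5 replicates each) restricted to the
# 1200.20-1259.84 cm^-1 model window, with the component count chosen by
# level-blocked cross-validation. Writes the serialized model and the CV
# error profile.

suppressPackageStartupMessages(library(ftirclean))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1
dir.create("results", showWarnings = FALSE)

instrument <- instrument_profile()
signature <- default_api_signature()
prep <- preprocess_spec(spectral_windows(c(1200.20, 1259.84)))
levels <- c(0.6, 1.2, 1.8, 2.4, 3.0)

cs <- generate_calibration_set(levels, 5, signature, instrument,
                               seed = seed * 1000 + 1)
cal <- build_calibration_set(cs, prep)
cv <- choose_components_cv(cal, 4, folds = 5, seed = seed * 1000 + 2)
model <- fit_pls(cal, cv$n_components)
write_pls_model(model, "results/pls_model.json")

fitted <- predict(model, cs$spectra)$density
rmsec <- sqrt(mean((fitted - cs$density)^2))
cv_tab <- data.frame(components = seq_along(cv$rmse),
                     cv_rmse = round(cv$rmse, 5))
write.csv(cv_tab, "results/pls_cv_rmse.csv", row.names = FALSE)
print(cv_tab, row.names = FALSE)
cat(sprintf(
  "\nChose %d component(s); CV RMSE %.4f ug/cm^2, training RMSE %.4f.\nModel written to results/pls_model.json\n",
  model$n_components, min(cv$rmse), rmsec
))
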