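#!/usr/bin/env Rscript
# How many measurement points does one hard-to-clean location need?
# Margin of error MOE(n) = t_{n-1} * sd / sqrt(n) at 99.73% confidence
# with sd 0.3 ug/cm^2 (50% RSD of the 0.6 visual limit), and the method
# capability CpK = (RAL - mean) / (3 * MOE(n)).

suppressPackageStartupMessages(library(ftirclean))
dir.create("results", showWarnings = FALSE)

params <- moe_params(mean = 0.6, sd = 0.3, confidence = 0.9973, ral = 1)
curve <- capability_curve(params, 30)
curve$moe <- round(curve$moe, 4)
curve$lower <- round(curve$lower, 4)
curve$upper <- round(curve$upper, 4)
curve$cpk <- round(curve$cpk, 4)
write.table(curve, "results/capability_curve.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
print(utils::head(curve, 10), row.names = FALSE)

iv <- mean_interval(params, 10)
cat(sprintf(
  "\nAt n = 10 the mean interval is %.3f-%.3f ug/cm^2 (MOE %.3f).\n",
  iv$lower, iv$upper, iv$moe
))
cmp <- compare_reported_sample_sizes(params)
print(cmp, row.names = FALSE)
writeLines(attr(cmp, "note"), "results/sample_size_note.txt")
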