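#!/usr/bin/env Rscript
# Simulate residue-bearing coupons at the visual cleanliness limit and
# characterize their spot-to-spot variability. Printer deposition is
# regular; hand deposition is clustered and lands in the 27-53% RSD band
# that motivates the 50% RSD planning assumption.

suppressPackageStartupMessages(library(ftirclean))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1
dir.create("results", showWarnings = FALSE)

rows <- list()
for (mode in c("printer", "by-hand")) {
  for (k in 1:3) {
    cp <- generate_coupon(0.6, deposition_profile(mode = mode),
                          seed = seed * 100 + k)
    d <- sample_spots_random(cp, 500, seed = seed * 100 + 50 + k)
    rows[[length(rows) + 1]] <- data.frame(
      mode = mode, coupon = k,
      droplets = length(cp$mass),
      mean_density = round(coupon_mean_density(cp), 4),
      spot_mean = round(mean(d), 4),
      spot_rsd_pct = round(percent_rsd(d), 1)
    )
  }
}
tab <- do.call(rbind, rows)
write.csv(tab, "results/coupon_variability.csv", row.names = FALSE)
print(tab, row.names = FALSE)
cat(sprintf(
  "\nHand-deposited coupons show %0.f-%0.f%% spot RSD (500 spots each);\nthe printed coupons stay near %0.f%%. Tables in results/coupon_variability.csv\n",
  min(tab$spot_rsd_pct[tab$mode == "by-hand"]),
  max(tab$spot_rsd_pct[tab$mode == "by-hand"]),
  mean(tab$spot_rsd_pct[tab$mode == "printer"])
))
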