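#!/usr/bin/env Rscript
# Calibrate the line-profile width estimator on rendered membranes with
# known widths: double-Gaussian peak-distance recovery at resolvable
# widths, and the single-Gaussian FWHM overestimate below the resolution
# limit. Writes results/width_calibration.csv.

library(mitomorph)

cfg <- sim_config()
px <- cfg$pixel_size_nm
set.seed(2)

measure_one <- function(w, L) {
  ang <- runif(1, 0, 180)
  patch <- render_membrane_object(L, w, ang, cfg, patch_size_px = 77)
  noisy <- matrix(rpois(length(patch), patch + cfg$background), nrow(patch)) +
    rnorm(length(patch), 0, cfg$noise_model$gaussian_read_sigma)
  ctr_um <- (nrow(noisy) - 1) / 2 * px / 1000
  obj <- list(id = 1L, centroid_um = c(x = ctr_um, y = ctr_um),
              angle_deg = ang, major_um = L, pixel_size_nm = px, n_px = 1L)
  pr <- extract_profile(noisy, obj, L / 2, L = L)
  fit_width(pr, count_peaks(pr))
}

rows <- list()
for (w in c(80, 120, 150, 200, 300)) {
  fits <- replicate(50, measure_one(w, if (w < 100) 0.5 else 1.0),
                    simplify = FALSE)
  models <- vapply(fits, function(f) f$model, character(1))
  widths <- vapply(fits, function(f) f$width_nm, numeric(1))
  ok <- models %in% c("single", "double")
  rows[[length(rows) + 1]] <- data.frame(
    true_width_nm = w, n = 50, n_accepted = sum(ok),
    frac_double = mean(models == "double"),
    mean_width_nm = mean(widths[ok]),
    bias_nm = mean(widths[ok]) - w)
  cat(sprintf("w = %3d nm: %2d accepted, mean %5.1f nm (bias %+5.1f), %2.0f%% double\n",
              w, sum(ok), mean(widths[ok]), mean(widths[ok]) - w,
              100 * mean(models == "double")))
}
tab <- do.call(rbind, rows)
write.csv(tab, "results/width_calibration.csv", row.names = FALSE)
cat("Note the single-Gaussian FWHM overestimate at 80 nm: unresolved",
    "membrane pairs read wider than their true diameter.\n")
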