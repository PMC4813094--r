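#!/usr/bin/env Rscript
# Gridded posterior prevalence for every year-season, WHO severity
# classification, population-weighted wasted-children counts by zone, and the
# dry-minus-wet seasonal difference surface.

source("analysis/_common.R")

state <- readRDS(res_path("fit_model1.rds"))
region <- study_region()
covs <- lapply(c(rainfall = "rainfall", evi = "evi",
                 temperature = "temperature", dist_water = "dist_water",
                 urban = "urban"),
               function(nm) read_grid_csv(res_path(paste0("covariate_", nm,
                                                          ".csv"))))
pop <- read_grid_csv(res_path("population.csv"))

which_ys <- expand.grid(year = YEARS, season = WM_SEASONS,
                        stringsAsFactors = FALSE)
prev <- predict_prevalence(state$fit, region, covs, which_ys,
                           seed = MASTER_SEED + 6)
cat(sprintf("predicted %d pixels per surface (%d masked)\n",
            prev$n_predicted, prev$n_masked))
for (key in names(prev$surfaces)) {
  write_grid_csv(prev$surfaces[[key]]$mean,
                 res_path(paste0("prevalence_", key, ".csv")))
}

risk <- wasted_children_counts(prev, pop, region)
utils::write.csv(as.data.frame(risk), res_path("risk.csv"), row.names = FALSE)
writeLines(utils::capture.output(
  print(format_risk_table(risk), row.names = FALSE)),
  res_path("risk_formatted.txt"))

by_class <- tapply(risk$wasted, risk$who_class, sum)
cat("wasted children by WHO class (all year-seasons):\n")
print(round(by_class))

dw <- dry_wet_difference(prev)
write_grid_csv(dw, res_path("dry_wet_difference.csv"))
cat(sprintf("dry-wet prevalence difference: %.4f to %.4f\n",
            min(dw$values, na.rm = TRUE), max(dw$values, na.rm = TRUE)))
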