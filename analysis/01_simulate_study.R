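#!/usr/bin/env Rscript
# Simulate the synthetic study: region, covariate surfaces, cluster survey
# records and the under-five population grid. Writes everything later stages
# consume under results/analysis/.

source("analysis/_common.R")

region <- study_region()
covs <- simulate_covariate_surfaces(region, seed = MASTER_SEED)
locs <- sample_cluster_locations(region, N_CLUSTERS, seed = MASTER_SEED + 1)
truth <- study_truth()
obs <- simulate_wasting_data(region, locs, covs, truth, years = YEARS,
                             seed = MASTER_SEED + 2)
pop <- simulate_population_grid(region, TOTAL_UNDER5, seed = MASTER_SEED + 3)

write_clusters_csv(obs, res_path("clusters.csv"),
                   metadata = list(seed = MASTER_SEED))
write_zones_geojson(region, res_path("zones.geojson"))
for (nm in names(covs)) {
  write_grid_csv(covs[[nm]], res_path(paste0("covariate_", nm, ".csv")))
}
write_grid_csv(pop, res_path("population.csv"))

t1 <- summarize_table1(transform(obs, region = zone_of(region, x_km, y_km)))
utils::write.csv(t1, res_path("zone_summary.csv"), row.names = FALSE)

cat(sprintf("simulated %d clusters, %s children, pooled prevalence %.2f%%\n",
            nrow(obs), format(sum(obs$n_examined), big.mark = ","),
            100 * sum(obs$n_wasted) / sum(obs$n_examined)))
cat("zone summary written to", res_path("zone_summary.csv"), "\n")
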