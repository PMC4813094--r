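#!/usr/bin/env Rscript
# De-clustered 10% hold-out, then the model-1 (year-season dynamics) Laplace
# fit on the training data. Saves the fit object for the mapping and
# validation stages.

source("analysis/_common.R")

obs <- read_clusters_csv(res_path("clusters.csv"))
sel <- jsonlite::fromJSON(res_path("selection.json"))

split <- spatiotemporal_holdout(obs, fraction = 0.10, seed = MASTER_SEED + 4)
cat(sprintf("hold-out: %d test / %d train clusters over %d strata\n",
            split$meta$n_test, nrow(split$train), split$meta$n_strata))

region <- study_region()
mesh <- build_mesh(region, MESH_EDGE, MESH_BUFFER)
cfg <- model_config(mesh = mesh, covariates = sel$chosen, model = 1)
fit <- laplace_fit(split$train, cfg,
                   optimizer_config = list(maxit = 150, restarts = 2),
                   seed = MASTER_SEED + 5)

print(fit)
utils::write.csv(fit$fixed_effects, res_path("fixed_effects.csv"),
                 row.names = FALSE)
saveRDS(list(fit = fit, split = split), res_path("fit_model1.rds"))
cat(sprintf("estimated spatial range %.0f km, field SD %.2f (log-odds)\n",
            sqrt(8) / fit$psi_natural$kappa[1],
            1 / (2 * sqrt(pi) * fit$psi_natural$kappa[1] *
                   fit$psi_natural$tau[1])))
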