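#!/usr/bin/env Rscript
# Predictive performance on the de-clustered 10% hold-out: RMSE, mean error,
# mean absolute error and the correlation between predicted and observed
# cluster proportions.

source("analysis/_common.R")

state <- readRDS(res_path("fit_model1.rds"))
val <- validate_fit(state$fit, state$split$test)
print(val)
jsonlite::write_json(
  list(rmse = val$rmse, me = val$me, mae = val$mae,
       correlation = val$correlation, n_test = val$n,
       split = state$split$meta),
  res_path("validation.json"), auto_unbox = TRUE, digits = NA)
cat("written to", res_path("validation.json"), "\n")
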