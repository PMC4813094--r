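#!/usr/bin/env Rscript
# Extended-BIC best-subset selection of the environmental covariates for the
# binomial GLM (exhaustive over the 2^5 subsets, gamma = 1).

source("analysis/_common.R")

obs <- read_clusters_csv(res_path("clusters.csv"))
sel <- select_best_subset(obs, CANDIDATES, gamma = 1)

utils::write.csv(sel$table[order(sel$table$ebic), ],
                 res_path("selection_table.csv"), row.names = FALSE)
jsonlite::write_json(
  list(chosen = sel$chosen, gamma = sel$gamma,
       chosen_ebic = sel$chosen_score,
       coefficients = as.list(sel$chosen_fit$coefficients)),
  res_path("selection.json"), auto_unbox = TRUE, digits = NA)

cat("subsets scored:", nrow(sel$table), "\n")
cat("chosen covariates:", paste(sel$chosen, collapse = ", "),
    sprintf("(EBIC %.1f)\n", sel$chosen_score))
cat("full table in", res_path("selection_table.csv"), "\n")
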