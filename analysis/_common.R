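# Shared study configuration for the numbered analysis scripts.
# Every script can be run from the repository root:
#   Rscript analysis/01_simulate_study.R
# Later scripts read the artifacts earlier ones wrote under results/.

library(wastemap)

RESULTS_DIR <- "results/analysis"
dir.create(RESULTS_DIR, showWarnings = FALSE, recursive = TRUE)

MASTER_SEED <- 20160201

# Desk-scale synthetic study emulating the survey structure: a 300 x 300 km
# three-zone region, ~1,066 clusters over 2007-2010, the five covariate
# surfaces, and a 1.5M-child under-five population.
study_region <- function() make_study_region(300, 300, 10)

study_truth <- function() true_parameters()

N_CLUSTERS <- 1066
YEARS <- 2007:2010
CANDIDATES <- c("rainfall", "evi", "temperature", "dist_water", "urban")
MESH_EDGE <- 60
MESH_BUFFER <- 80
TOTAL_UNDER5 <- 1.5e6

res_path <- function(...) file.path(RESULTS_DIR, ...)
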