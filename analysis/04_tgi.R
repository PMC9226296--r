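#!/usr/bin/env Rscript
# Stage 4: temporal grading index and feature assembly.
#
# For each patient and property, regresses the deviation of the patient's
# windowed property course from the control norm on that norm, per region;
# the slope is the TGI. Slopes are concatenated across regions and
# properties into the patient feature matrix. A simulated VAS target,
# linearly coupled to three TGI features plus noise, is written alongside
# so the prediction stage has a known ground truth.
#
# Inputs:  scratch/properties/, results/qc_report.tsv, results/meta.tsv
# Outputs: results/tgi_features.tsv, results/vas_target.tsv,
#          results/tgi_summary.tsv

suppressPackageStartupMessages(library(tgindex))

seed <- 20260923L
cfg <- default_config(seed = seed)
qc <- utils::read.delim("results/qc_report.tsv")
meta <- utils::read.delim("results/meta.tsv")
keep <- qc$subject_id[qc$include]
groups <- meta$group[match(keep, meta$subject_id)]
patients <- keep[groups == "CBP"]

read_pm <- function(stem, prop) {
  m <- read_roi_table(file.path("scratch/properties", paste0(stem, "_", prop, ".tsv")),
                      tr = cfg$tr)
  property_matrix(m$data, property = prop, subject_id = stem)
}

tgi_sets <- lapply(stats::setNames(cfg$metrics, cfg$metrics), function(prop) {
  norm <- read_pm("HC_mean", prop)
  lapply(patients, function(id) tgi_subject(read_pm(id, prop), norm))
})

features <- combine_features(tgi_sets, standardize = FALSE)
utils::write.table(data.frame(subject_id = rownames(features), features,
                              check.names = FALSE),
                   "results/tgi_features.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)

summ <- do.call(rbind, lapply(names(tgi_sets), function(prop) {
  k <- do.call(rbind, lapply(tgi_sets[[prop]], `[[`, "k"))
  data.frame(property = prop, mean_tgi = mean(k), sd_tgi = stats::sd(k),
             frac_negative = mean(k < 0))
}))
utils::write.table(summ, "results/tgi_summary.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
message("TGI summary by property:")
print(summ)

# ground-truth VAS: sparse linear coupling to three standardized TGI
# features, sd-0.5 noise, clipped to the 0-10 scale
Z <- standardize_features(features)
set.seed(derive_seed(seed, "vas_truth"))
active <- sample(ncol(Z), 3)
weights <- numeric(ncol(Z)); weights[active] <- c(1.2, -1.0, 0.8)
vas <- simulate_vas(Z, weights, intercept = 5, noise_sd = 0.5,
                    seed = derive_seed(seed, "vas_draw"))
utils::write.table(data.frame(subject_id = patients, vas = vas,
                              stringsAsFactors = FALSE),
                   "results/vas_target.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
writeLines(c("active features and weights:",
             sprintf("  %s  %+0.2f", colnames(Z)[active], weights[active])),
           "results/vas_ground_truth.txt")
message("active VAS features: ", paste(colnames(Z)[active], collapse = ", "))
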