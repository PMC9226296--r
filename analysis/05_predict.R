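#!/usr/bin/env Rscript
# Stage 5: pain-intensity prediction from TGI features.
#
# Runs 5-fold cross-validation repeated ten times for each model family
# (linear SVR, lasso, elastic net) on each feature set (per-property TGI and
# the combined set), with per-fold standardization, inner-CV grid search,
# and the training-set bias adjustment. Reports mean +/- sd of the
# repeat-level MSEs, one row per model x feature combination.
#
# Inputs:  results/tgi_features.tsv, results/vas_target.tsv
# Outputs: results/prediction_mse.tsv, results/top_weights.tsv

suppressPackageStartupMessages(library(tgindex))

seed <- 20260923L
feat <- utils::read.delim("results/tgi_features.tsv", check.names = FALSE)
X_all <- as.matrix(feat[, -1]); rownames(X_all) <- feat$subject_id
vas <- utils::read.delim("results/vas_target.tsv")
y <- vas$vas[match(feat$subject_id, vas$subject_id)]

prop_of <- sub(":.*", "", colnames(X_all))
feature_sets <- c(lapply(stats::setNames(unique(prop_of), unique(prop_of)),
                         function(p) X_all[, prop_of == p, drop = FALSE]),
                  list(combined = X_all))
families <- c("svr_linear", "lasso", "elastic_net")

rows <- list(); weights_acc <- NULL
for (fs in names(feature_sets)) {
  for (fam in families) {
    cv <- repeated_kfold(feature_sets[[fs]], y, fam, k = 5, repeats = 10,
                         seed = derive_seed(seed, paste(fam, fs)))
    rows[[length(rows) + 1L]] <- data.frame(
      features = fs, model = fam,
      mean_mse = cv$summary$mean_mse, sd_mse = cv$summary$sd_mse)
    message(sprintf("%-9s x %-11s MSE = %.3f +/- %.3f",
                    fs, fam, cv$summary$mean_mse, cv$summary$sd_mse))
    if (fs == "combined" && fam == "lasso")
      weights_acc <- sort(cv$mean_abs_weight, decreasing = TRUE)
  }
}
tab <- do.call(rbind, rows)
utils::write.table(tab, "results/prediction_mse.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

top <- data.frame(feature = names(weights_acc)[1:20],
                  mean_abs_weight = weights_acc[1:20])
utils::write.table(top, "results/top_weights.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
message("top combined-lasso features:")
print(utils::head(top, 5), row.names = FALSE)
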