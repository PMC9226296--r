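#!/usr/bin/env Rscript
# Stage 6: group statistics.
#
# (a) demographics: group differences in age and BDI (two-sample t), gender
#     (chi-square);
# (b) TGI vs BDI: Pearson association per property (does depression explain
#     the deviation index?);
# (c) windowed property group comparison in the regions that carried the
#     most prediction weight: covariate-adjusted (age, gender, BDI)
#     two-sample test per region on the window-mean property, BH-corrected
#     across regions within each property.
#
# Inputs:  results/*, scratch/properties/
# Outputs: results/demographics.tsv, results/tgi_bdi.tsv,
#          results/group_differences.tsv

suppressPackageStartupMessages(library(tgindex))

cfg <- default_config()
meta <- utils::read.delim("results/meta.tsv")
qc <- utils::read.delim("results/qc_report.tsv")
keep <- qc$subject_id[qc$include]
meta <- meta[match(keep, meta$subject_id), ]

# (a) demographics
demo <- rbind(
  { r <- covaried_group_test(meta$age, meta$group)
    data.frame(variable = "age", statistic = r$statistic, p = r$p) },
  { r <- covaried_group_test(meta$bdi, meta$group)
    data.frame(variable = "bdi", statistic = r$statistic, p = r$p) },
  { tab <- table(meta$group, meta$gender)
    r <- chi_square_2x2(tab)
    data.frame(variable = "gender", statistic = r$statistic, p = r$p) })
utils::write.table(demo, "results/demographics.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
message("demographics:"); print(demo, row.names = FALSE)

# (b) TGI-BDI association per property
feat <- utils::read.delim("results/tgi_features.tsv", check.names = FALSE)
X <- as.matrix(feat[, -1])
bdi <- meta$bdi[match(feat$subject_id, meta$subject_id)]
prop_of <- sub(":.*", "", colnames(X))
tgi_bdi <- do.call(rbind, lapply(unique(prop_of), function(p) {
  r <- pearson_association(rowMeans(X[, prop_of == p, drop = FALSE]), bdi)
  data.frame(property = p, r = r$estimate, p = r$p)
}))
utils::write.table(tgi_bdi, "results/tgi_bdi.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
message("TGI-BDI association:"); print(tgi_bdi, row.names = FALSE)

# (c) covariate-adjusted group comparison of window-mean properties in the
# twenty highest-weight regions, BH within property
topw <- utils::read.delim("results/top_weights.tsv")
top_regions <- unique(sub(".*:", "", topw$feature))
cov <- data.frame(age = meta$age, gender = meta$gender, bdi = meta$bdi)
rows <- list()
for (prop in cfg$metrics) {
  vals <- t(vapply(keep, function(id) {
    m <- read_roi_table(file.path("scratch/properties",
                                  paste0(id, "_", prop, ".tsv")), tr = cfg$tr)
    colMeans(m$data)
  }, numeric(ncol(X) / length(cfg$metrics))))
  regions <- intersect(top_regions, colnames(vals))
  res <- lapply(regions, function(rg)
    covaried_group_test(vals[, rg], meta$group, cov))
  p_adj <- fdr_correct(vapply(res, `[[`, numeric(1), "p"), q = 0.05)
  rows[[prop]] <- data.frame(
    property = prop, region = regions,
    t = vapply(res, `[[`, numeric(1), "statistic"),
    p = vapply(res, `[[`, numeric(1), "p"),
    q = p_adj$q_values, significant = p_adj$reject)
}
gd <- do.call(rbind, rows)
utils::write.table(gd, "results/group_differences.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
message(sprintf("group differences: %d/%d region-property tests significant at q < 0.05",
                sum(gd$significant), nrow(gd)))
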