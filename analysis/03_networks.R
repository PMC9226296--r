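#!/usr/bin/env Rscript
# Stage 3: sliding-window networks and dynamic property matrices.
#
# For every included subject, builds the stack of windowed
# Pearson-correlation networks (50-TR windows, 1-TR step, negatives and the
# diagonal zeroed -> 191 windows at T = 240), computes nodal degree,
# clustering coefficient, and participation coefficient per window, and
# writes the t x n property matrices. The control norm is computed
# metric-after-averaging from the window-wise mean control network.
#
# Inputs:  scratch/processed/, results/qc_report.tsv, results/partition.tsv
# Outputs: scratch/properties/, results/network_summary.tsv

suppressPackageStartupMessages(library(tgindex))

cfg <- default_config()
qc <- utils::read.delim("results/qc_report.tsv")
meta <- utils::read.delim("results/meta.tsv")
partition <- read_partition_table("results/partition.tsv")
keep <- qc$subject_id[qc$include]
dir.create("scratch/properties", showWarnings = FALSE, recursive = TRUE)

subjects <- lapply(keep, function(id)
  read_roi_table(file.path("scratch/processed", paste0(id, ".tsv")),
                 tr = cfg$tr, subject_id = id))
groups <- meta$group[match(keep, meta$subject_id)]

T <- nrow(subjects[[1]]$data)
spec <- sliding_window_indices(T, cfg$window_length, cfg$window_step, tr = cfg$tr)
message(sprintf("T = %d -> %d windows of %d TRs", T, length(spec$starts),
                spec$length))

stacks <- lapply(subjects, build_dfc_stack, spec = spec)
hc_stacks <- stacks[groups == "HC"]

summ <- list()
for (prop in cfg$metrics) {
  norm <- norm_property(hc_stacks, prop, partition, cfg$degree_mode)
  write_roi_table(norm$data,
                  file.path("scratch/properties", paste0("HC_mean_", prop, ".tsv")))
  for (i in seq_along(stacks)) {
    pm <- dynamic_property_matrix(stacks[[i]], prop, partition, cfg$degree_mode)
    write_roi_table(pm$data,
                    file.path("scratch/properties",
                              paste0(keep[i], "_", prop, ".tsv")))
    summ[[length(summ) + 1L]] <- data.frame(
      subject_id = keep[i], group = groups[i], property = prop,
      mean = mean(pm$data), sd = stats::sd(pm$data))
  }
}
summ <- do.call(rbind, summ)
utils::write.table(summ, "results/network_summary.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

agg <- stats::aggregate(mean ~ group + property, summ, mean)
message("group-mean property levels:")
print(agg)
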