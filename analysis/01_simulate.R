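#!/usr/bin/env Rscript
# Stage 1: generate the synthetic cohort.
#
# Emulates the target cohort design: two groups (29 controls, 30 chronic back pain
# patients), parcellated BOLD series at TR = 2.5 s with 245 volumes, a
# 9-module region partition, six-parameter motion traces, and demographic
# metadata. The analysis runs at 60 regions (not the atlas's 274) to keep
# the demonstration light; every downstream stage is size-agnostic.
#
# Outputs: scratch/cohort/ (per-subject time-series + motion TSVs),
#          results/meta.tsv, results/partition.tsv,
#          results/manifest_simulate.txt

suppressPackageStartupMessages(library(tgindex))

seed <- 20260923L
n_regions <- 60L
cfg <- default_config(seed = seed)

dir.create("scratch/cohort", recursive = TRUE, showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)

message("simulating cohort: 29 HC + 30 CBP, ", n_regions,
        " regions, T = 245, TR = 2.5 s, covariance shift 0.5")
co <- simulate_cohort_timeseries(n_hc = 29, n_cbp = 30,
                                 n_regions = n_regions, T = 245, tr = cfg$tr,
                                 n_states = 4, dwell_mean = 30,
                                 cbp_shift = 0.5, seed = seed)

for (ts in co$subjects)
  write_roi_table(ts, file.path("scratch/cohort", paste0(ts$subject_id, ".tsv")))

# motion traces: mostly clean scans plus three deliberately bad ones so the
# QC stage has something to catch (a 3 mm spike, a high-FD walk, heavy
# rotation)
ids <- co$meta$subject_id
for (i in seq_along(ids)) {
  m <- simulate_motion_trace(245, base_sd = 0.01, n_spikes = 0,
                             seed = derive_seed(seed, "motion", i))
  if (i == 3L) m <- simulate_motion_trace(245, base_sd = 0.01, n_spikes = 1,
                                          spike_amp = 3,
                                          seed = derive_seed(seed, "motion", i))
  if (i == 17L) m <- simulate_motion_trace(245, base_sd = 0.06,
                                           seed = derive_seed(seed, "motion", i))
  if (i == 40L) m[, 5] <- m[, 5] + seq(0, 2.5, length.out = 245)
  write_roi_table(m, file.path("scratch/cohort", paste0(ids[i], "_motion.tsv")))
}

utils::write.table(co$meta, "results/meta.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
write_partition_table(co$partition, "results/partition.tsv")
write_manifest(cfg, character(0), "results/manifest_simulate.txt")
message("wrote ", length(ids), " subjects to scratch/cohort/")
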