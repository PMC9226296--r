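#!/usr/bin/env Rscript
# Stage 2: motion-based exclusion, length standardization, band-pass.
#
# Applies the motion-exclusion rule (any |translation| > 2 mm, any
# |rotation| > 2 deg, or mean framewise displacement > 0.2 mm), truncates
# every run to 240 volumes (drop trailing volumes to 245, then the first
# 5), and band-passes 0.01-0.1 Hz.
#
# Inputs:  scratch/cohort/, results/meta.tsv
# Outputs: scratch/processed/, results/qc_report.tsv

suppressPackageStartupMessages(library(tgindex))

cfg <- default_config()
meta <- utils::read.delim("results/meta.tsv")
dir.create("scratch/processed", showWarnings = FALSE, recursive = TRUE)

rows <- lapply(meta$subject_id, function(id) {
  motion <- as.matrix(utils::read.delim(
    file.path("scratch/cohort", paste0(id, "_motion.tsv"))))
  dec <- motion_qc(motion, cfg$trans_thresh, cfg$rot_thresh, cfg$fd_thresh,
                   cfg$head_radius)
  if (dec$include) {
    ts <- read_roi_table(file.path("scratch/cohort", paste0(id, ".tsv")),
                         tr = cfg$tr, subject_id = id)
    ts <- preprocess_subject(ts, cfg)
    write_roi_table(ts, file.path("scratch/processed", paste0(id, ".tsv")))
  }
  data.frame(subject_id = id, include = dec$include,
             reasons = paste(dec$reasons, collapse = ";"),
             max_trans = dec$max_trans, max_rot = dec$max_rot,
             mean_fd = dec$mean_fd)
})
report <- do.call(rbind, rows)
utils::write.table(report, "results/qc_report.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)

message(sprintf("QC: %d/%d subjects pass; excluded: %s",
                sum(report$include), nrow(report),
                paste(report$subject_id[!report$include], collapse = ", ")))
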