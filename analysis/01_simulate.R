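#!/usr/bin/env Rscript
# Generate the synthetic study: an annotation matrix over 24 task
# conditions (12 ontological features, 8 cognitive / 4 perceptual-motor),
# network-structured ground-truth encoding weights over 1000 regions in 7
# resting-state networks, and session-level activation maps (8 tasks with
# four sessions, the rest two) for 3 subjects. Everything downstream reads
# this study; the ground truth makes recovery checkable.

source("analysis/common.R")

study <- load_study()
ds <- study$data

message(sprintf("tasks: %d (four-session: %d), features: %d, regions: %d",
                length(ds$tasks), sum(ds$session_counts == 4),
                ncol(study$features$values), ncol(ds$maps[[1]])))
message(sprintf("session rows per subject: %d", nrow(ds$maps[[1]])))
message(sprintf("subjects: %s", paste(names(ds$maps), collapse = ", ")))

out <- results_dir("study")
write_study(study, out)

# between-session reliability at the generated noise level
nc <- noise_ceiling(ds, names(ds$maps)[1])
message(sprintf("mean noise ceiling (subject 1): %.3f",
                mean(nc$ceiling, na.rm = TRUE)))
write_tsv(nc, file.path(out, "noise_ceiling_sub01.tsv"))
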