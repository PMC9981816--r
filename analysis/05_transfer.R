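#!/usr/bin/env Rscript
# Between-subject generalization: train each subject's model on all tasks,
# predict every task map, and score two-way classification on every other
# subject (and on the source itself, computed identically).

source("analysis/common.R")

study <- load_study()
ds <- study$data
subjects <- names(ds$maps)
out <- results_dir("transfer")

fits <- lapply(seq_along(subjects), function(i)
  fit_full(ds, subjects[i], study$features, seed = STUDY_SEED + 31L * i))
names(fits) <- subjects

tr <- transfer_evaluate(fits, ds, study$features)
write_tsv(tr$accuracy, file.path(out, "transfer_accuracy.tsv"),
          rownames_as = "source")
write_tsv(tr$mean_r, file.path(out, "transfer_mean_r.tsv"),
          rownames_as = "source")

ts <- transfer_summary(tr)
write_tsv(ts, file.path(out, "transfer_summary.tsv"))
message(sprintf("self-transfer accuracy:  M = %.3f", mean(ts$self)))
message(sprintf("cross-subject accuracy:  M = %.3f", mean(ts$cross)))
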