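#!/usr/bin/env Rscript
# Fit region-wise encoding models with leave-two-out nested CV for each
# subject and feature set (All / Cognitive / Perceptual-Motor), then compare
# the feature sets with a repeated-measures ANOVA and Bonferroni-corrected
# paired t-tests. Writes per-subject metric tables and the per-split detail
# for the All models (used by 03-04).

source("analysis/common.R")

study <- load_study()
ds <- study$data
subjects <- names(ds$maps)
out <- results_dir("fits")

sets <- c("All", "Cognitive", "PerceptualMotor")
subject_rows <- list()
for (set in sets) {
  fm <- subset_features(study$features, set)
  for (i in seq_along(subjects)) {
    cv <- run_subject_cv(ds, subjects[i], fm, seed = STUDY_SEED + 17L * i)
    agg <- aggregate_metrics(cv, noise_ceiling(ds, subjects[i]))
    subject_rows[[paste(set, i)]] <- cbind(feature_set = set, agg$subject)
    if (set == "All") {
      write_tsv(cv$splits,
                file.path(out, sprintf("splits_all_%s.tsv", subjects[i])))
      write_tsv(agg$task,
                file.path(out, sprintf("task_metrics_all_%s.tsv", subjects[i])))
    }
    message(sprintf("%s / %s: accuracy %.3f, map r %.3f, R2 %.3f",
                    set, subjects[i], agg$subject$accuracy,
                    agg$subject$mean_r, agg$subject$mean_r2))
  }
}
subj_tab <- do.call(rbind, subject_rows)
write_tsv(subj_tab, file.path(out, "subject_metrics.tsv"))

acc <- matrix(subj_tab$accuracy, ncol = length(sets),
              dimnames = list(NULL, sets))
cmp <- compare_feature_sets(acc)
message(sprintf("feature-set ANOVA: F(%d, %d) = %.2f, p = %.3g",
                cmp$anova$df1, cmp$anova$df2, cmp$anova$F, cmp$anova$p))
print(cmp$pairwise)
write_tsv(cmp$pairwise, file.path(out, "feature_set_ttests.tsv"))
write_tsv(cmp$anova, file.path(out, "feature_set_anova.tsv"))
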