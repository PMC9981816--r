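#!/usr/bin/env Rscript
# Hierarchical structure of the ontological features from classifier
# generalization errors: aggregate all subjects' split-level assignments
# into a task confusion matrix, project it into cognitive space through the
# feature matrix, build a 1-correlation RDM over features, and cluster it
# with UPGMA. Also clusters regions by coefficient similarity.

source("analysis/common.R")

study <- load_study()
ds <- study$data
subjects <- names(ds$maps)
out <- results_dir("structure")

cvs <- lapply(seq_along(subjects), function(i)
  run_subject_cv(ds, subjects[i], study$features,
                 seed = STUDY_SEED + 17L * i))
conf <- build_confusion(cvs)
message(sprintf("confusion total %d (= 2 x %d splits x %d subjects); %.1f%% on-diagonal",
                sum(conf), nrow(cvs[[1]]$splits), length(subjects),
                100 * sum(diag(conf)) / sum(conf)))
write_tsv(conf, file.path(out, "confusion.tsv"), rownames_as = "task")

proj <- project_to_cognitive(conf, study$features)
rdm <- feature_rdm(proj)
write_tsv(rdm, file.path(out, "feature_rdm.tsv"), rownames_as = "feature")

up <- upgma_cluster(rdm)
writeLines(up$newick, file.path(out, "feature_tree.nwk"))
message("feature dendrogram heights: ",
        paste(round(up$height, 3), collapse = ", "))

# region clustering on subject-averaged coefficients (full fits)
fits <- lapply(seq_along(subjects), function(i)
  fit_full(ds, subjects[i], study$features, seed = STUDY_SEED + 31L * i))
wbar <- Reduce(`+`, lapply(fits, `[[`, "weights")) / length(fits)
region_rdm <- 1 - cor(wbar)
region_up <- upgma_cluster(region_rdm)
k7 <- cutree(region_up$hclust, k = 7)
ut <- upper.tri(diag(length(k7)))
agree <- mean((outer(k7, k7, `==`) ==
               outer(ds$network_labels, ds$network_labels, `==`))[ut])
message(sprintf("region 7-cluster vs network-label pair agreement: %.3f", agree))
write_tsv(data.frame(region = colnames(wbar), cluster = k7,
                     network = ds$network_labels),
          file.path(out, "region_clusters.tsv"))
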