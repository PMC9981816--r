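# Shared study configuration for the numbered analysis scripts. Every
# script regenerates the same seeded synthetic study through the package,
# so the steps can be run independently and in any order.

library(cogem)

STUDY_SEED <- 20260926L

study_config <- function() {
  synthetic_config(n_tasks = 24, n_features = 12, n_cognitive = 8,
                   n_regions = 1000, n_networks = 7, n_subjects = 3,
                   n_four_session_tasks = 8, seed = STUDY_SEED)
}

load_study <- function() generate_study(study_config())

results_dir <- function(...) {
  d <- file.path("results", ...)
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  d
}

write_tsv <- function(x, path, rownames_as = NULL) {
  if (!is.null(rownames_as)) {
    x <- data.frame(rn = rownames(x), x, check.names = FALSE)
    names(x)[1] <- rownames_as
  }
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("wrote ", path)
}
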