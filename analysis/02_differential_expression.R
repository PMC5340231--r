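#!/usr/bin/env Rscript
# Stage 2: per-dataset differential expression.
#
# Patient cohorts: per-gene OLS of log2 expression on outcome status with
# MYCN amplification as a fixed effect (y ~ status + MYCN). Cell lines:
# Gaussian mixed model with a per-line random intercept
# (y ~ hypoxia + MYCN + growth pattern + (1 | line)); the single-line
# experiment falls back to fixed-effects OLS. Genes pass the DEG filter
# when q < 0.01 and their log2 fold change lies in the top or bottom 10%
# of the tested universe.

suppressMessages(library(nbhypoxia))

data_dir <- "results/data"
out_dir <- "results/deg"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
truth <- jsonlite::read_json(file.path(data_dir, "ground_truth.json"),
                             simplifyVector = TRUE)

for (nm in c("c1", "c2", "cl1", "cl2")) {
  type <- if (nm %in% c("c1", "c2")) "cohort" else "cellline"
  ds <- read_expression_dataset(
    file.path(data_dir, paste0(nm, "_expression.tsv")),
    file.path(data_dir, paste0(nm, "_annotations.tsv")),
    dataset_id = nm)
  de <- suppressWarnings(differential_expression(ds, type = type))
  write_deg_table(de$degs, file.path(out_dir, paste0("deg_", nm, ".tsv")))
  writeLines(sort(unique(de$fits$gene)),
             file.path(out_dir, paste0("universe_", nm, ".txt")))
  n_deg <- nrow(de$degs$records)
  n_hit <- sum(truth$planted_genes %in% de$degs$records$gene)
  message(sprintf(
    "%s (%s): %d DEGs of %d genes tested; %d/%d planted genes recovered",
    nm, type, n_deg, de$degs$universe_size, n_hit,
    length(truth$planted_genes)))
}

message("stage 2 complete: DEG tables in ", out_dir)
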