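#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs.
#
# Emulates the structure of the source data: two clinically annotated
# patient cohorts (expression + overall survival + MYCN/stage/age), one
# single-line hypoxia experiment with technical replicates, one 11-line
# hypoxia panel, a triplicate qPCR plate for the candidate genes, and
# matched gene/peak BED fixtures for promoter annotation. The same 25
# planted genes carry the prognostic signal in the cohorts and the hypoxia
# response in the cell lines; ground truth is saved for later stages.

suppressMessages(library(nbhypoxia))

master_seed <- 1
data_dir <- "results/data"
dir.create(data_dir, recursive = TRUE, showWarnings = FALSE)

n_genes <- 2000; n_planted <- 25

message("simulating patient cohorts (n = 600 each, ", n_genes, " genes)...")
c1 <- simulate_patient_cohort(cohort_sim_config(
  n_patients = 600, n_genes = n_genes, n_prognostic = n_planted,
  n_mycn_genes = n_planted, seed = derive_seed(master_seed, "acc_c1")))
c2 <- simulate_patient_cohort(cohort_sim_config(
  n_patients = 600, n_genes = n_genes, n_prognostic = n_planted,
  n_mycn_genes = n_planted, seed = derive_seed(master_seed, "acc_c2")))

message("simulating cell-line experiments...")
cl1 <- simulate_cellline_experiment(cellline_sim_config(
  n_lines = 1, n_replicates_per_condition = 6, n_genes = n_genes,
  n_hypoxia_responsive = n_planted, line_sd = 0, noise_sd = 0.2,
  seed = derive_seed(master_seed, "acc_cl1")))
cl2 <- simulate_cellline_experiment(cellline_sim_config(
  n_lines = 11, n_replicates_per_condition = 1, n_genes = n_genes,
  n_hypoxia_responsive = n_planted,
  seed = derive_seed(master_seed, "acc_cl2")))

for (nm in c("c1", "c2", "cl1", "cl2")) {
  sim <- list(c1 = c1, c2 = c2, cl1 = cl1, cl2 = cl2)[[nm]]
  write_expression_dataset(sim$dataset,
                           file.path(data_dir, paste0(nm, "_expression.tsv")),
                           file.path(data_dir, paste0(nm, "_annotations.tsv")))
}

message("simulating qPCR plate and peak fixtures...")
write_ct_table(simulate_qpcr_plate(
  qpcr_sim_config(seed = derive_seed(master_seed, "acc_qpcr"))),
  file.path(data_dir, "qpcr_ct.csv"))
# peaks placed in the promoters of the first 10 planted genes
simulate_peak_fixtures(n_genes, flagged = seq_len(10), promoter_window = 2000,
                       seed = derive_seed(master_seed, "acc_peaks"),
                       dir = data_dir,
                       gene_names = sprintf("g%04d", seq_len(n_genes)))

jsonlite::write_json(
  list(master_seed = master_seed,
       planted_genes = c1$truth$prognostic_genes,
       mycn_genes = c1$truth$mycn_genes,
       true_cutpoints = as.list(c1$truth$true_cutpoints)),
  file.path(data_dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)

message("stage 1 complete: inputs in ", data_dir)
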