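#!/usr/bin/env Rscript
# Stage 3: multi-dataset integration.
#
# Intersects the four DEG signatures by gene symbol, counts
# direction-consistent genes (the candidate set), tests the overlap
# against a 100,000-replicate permutation null (random gene sets of the
# observed sizes drawn from each dataset's own tested universe), runs a
# hypergeometric over-representation check of the candidates against a
# small gene-set collection, and flags candidates whose promoters carry
# differential peaks.

suppressMessages(library(nbhypoxia))

deg_dir <- "results/deg"
data_dir <- "results/data"
out_dir <- "results/integration"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
master_seed <- 1

ids <- c("c1", "c2", "cl1", "cl2")
degs <- lapply(ids, function(nm)
  ingest_external_deg_table(file.path(deg_dir, paste0("deg_", nm, ".tsv"))))
universes <- lapply(ids, function(nm)
  readLines(file.path(deg_dir, paste0("universe_", nm, ".txt"))))
names(degs) <- names(universes) <- ids

sets <- lapply(ids, function(nm)
  signature_set(degs[[nm]], universes[[nm]], dataset_id = nm))
ov <- intersect_signatures(sets)
print(ov)

perm <- permutation_overlap_test(
  set_sizes = vapply(degs, function(d) nrow(d$records), integer(1)),
  universes = universes, observed = ov$n_shared,
  n_permutations = 100000,
  seed = derive_seed(master_seed, "overlap_permutation"))
print(perm)

# over-representation of the candidates against a small GMT collection
# built from the study's ground truth plus decoy sets
truth <- jsonlite::read_json(file.path(data_dir, "ground_truth.json"),
                             simplifyVector = TRUE)
gmt_path <- file.path(out_dir, "collections.gmt")
uni <- Reduce(union, universes)
set.seed(derive_seed(master_seed, "ora_decoys"))
writeLines(c(
  paste(c("planted_hypoxia_prognosis", "synthetic", truth$planted_genes),
        collapse = "\t"),
  paste(c("mycn_program", "synthetic", truth$mycn_genes), collapse = "\t"),
  paste(c("decoy_random", "synthetic", sample(uni, 40)), collapse = "\t")),
  gmt_path)
ora <- ora_enrichment(ov$consistent_genes, read_gmt(gmt_path), uni)
write.table(ora, file.path(out_dir, "ora.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
message("top enriched set: ", ora$set[1], " (q = ", signif(ora$q[1], 3), ")")

peaks <- annotate_genes_with_peaks(file.path(data_dir, "genes.bed"),
                                   file.path(data_dir, "peaks.bed"),
                                   promoter_window = 2000)
message(sum(peaks$flagged), " genes carry promoter peaks; ",
        sum(peaks$gene[peaks$flagged] %in% ov$consistent_genes),
        " of them are candidates")

write.table(data.frame(gene = ov$shared_genes,
                       consistent = ov$shared_genes %in% ov$consistent_genes),
            file.path(out_dir, "overlap.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
jsonlite::write_json(
  list(n_shared = ov$n_shared,
       n_direction_consistent = ov$n_direction_consistent,
       candidates = ov$consistent_genes,
       permutation_p = perm$p, permutation_p_bias_guarded = perm$p_bias_guarded),
  file.path(out_dir, "integration.json"), auto_unbox = TRUE, digits = NA)
write.table(peaks, file.path(out_dir, "peak_flags.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

message("stage 3 complete: ", length(ov$consistent_genes),
        " candidate genes in ", out_dir)
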