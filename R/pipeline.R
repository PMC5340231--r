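#' Validate and normalize a pipeline configuration
#'
#' Reads a YAML configuration (or takes an equivalent list), fills defaults,
#' and rejects unknown or malformed keys. Thresholds default to the study
#' conventions: DEG FDR < 0.01 with a 10% fold-change decile, a 2%
#' minimum group fraction for the survival cutpoint scan, prognostic calls
#' at scan FDR < 0.01, over-representation significance at q < 0.05, and
#' 100,000 permutation replicates.
#'
#' @param config Path to a YAML file, or a list with the same structure.
#' @return A normalized list of class `pipeline_config`.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  if (!is.list(config)) stop("config must be a file path or a list")
  known <- c("datasets", "thresholds", "permutation", "qpcr", "peaks",
             "survival_scan_scope", "output_dir", "log_level")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))

  thr_def <- list(fdr_max = 0.01, fc_decile = 0.10,
                  fc_decile_scope = "universe",
                  survival_min_fraction = 0.02, prognostic_fdr = 0.01,
                  ora_q = 0.05)
  thr <- utils::modifyList(thr_def, config$thresholds %||% list())
  extra <- setdiff(names(thr), names(thr_def))
  if (length(extra))
    stop("unknown threshold key(s): ", paste(extra, collapse = ", "))
  for (k in c("fdr_max", "prognostic_fdr", "ora_q"))
    if (!is.numeric(thr[[k]]) || thr[[k]] <= 0 || thr[[k]] > 1)
      stop("threshold out of range: ", k)
  if (thr$fc_decile <= 0 || thr$fc_decile >= 0.5)
    stop("threshold out of range: fc_decile")
  if (thr$survival_min_fraction <= 0 || thr$survival_min_fraction > 0.5)
    stop("threshold out of range: survival_min_fraction")
  if (!thr$fc_decile_scope %in% c("universe", "significant"))
    stop("fc_decile_scope must be 'universe' or 'significant'")

  perm_def <- list(n = 100000, seed = 1L, draw_sizes = NULL)
  perm <- utils::modifyList(perm_def, config$permutation %||% list(),
                            keep.null = TRUE)
  if (perm$n < 1) stop("permutation n must be at least 1")

  datasets <- config$datasets %||% list()
  for (i in seq_along(datasets)) {
    d <- datasets[[i]]
    if (is.null(d$id)) stop("dataset ", i, " is missing an id")
    if (is.null(d$type) ||
        !d$type %in% c("cohort", "cellline", "external_deg"))
      stop("dataset ", d$id %||% i,
           ": type must be cohort, cellline, or external_deg")
    if (d$type == "external_deg") {
      if (is.null(d$path)) stop("dataset ", d$id, ": missing path")
      if (!file.exists(d$path))
        stop("dataset ", d$id, ": file not found: ", d$path)
      datasets[[i]]$preselected <- isTRUE(d$preselected)
    } else {
      for (k in c("expression", "annotations")) {
        if (is.null(d[[k]])) stop("dataset ", d$id, ": missing ", k)
        if (!file.exists(d[[k]]))
          stop("dataset ", d$id, ": file not found: ", d[[k]])
      }
    }
  }
  scope <- config$survival_scan_scope %||% "degs"
  if (!scope %in% c("degs", "all"))
    stop("survival_scan_scope must be 'degs' or 'all'")
  structure(list(datasets = datasets, thresholds = thr, permutation = perm,
                 qpcr = config$qpcr, peaks = config$peaks,
                 survival_scan_scope = scope,
                 output_dir = config$output_dir %||% "pipeline_out",
                 log_level = config$log_level %||% "info"),
            class = "pipeline_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pipeline_log <- function(cfg, ...) {
  if (!identical(cfg$log_level, "quiet"))
    message("[pipeline] ", ...)
}

#' Run the full candidate-gene discovery workflow
#'
#' Executes the study workflow in dependency order: per-dataset differential
#' expression (cohort linear models, cell-line mixed models, or ingestion of
#' an external DEG table), dual-criterion DEG selection, multi-dataset
#' signature intersection with the Monte-Carlo overlap permutation test,
#' per-cohort sliding-window survival scans and Cox models, the
#' DEG-prognosis permutation test, optional qPCR quantification and
#' promoter-peak annotation, and finally the candidate-gene report.
#' Candidate genes are exactly the direction-consistent members of the
#' all-datasets intersection. Every stage writes its artifact (plain TSV or
#' JSON) before the next stage reads it, and a run manifest records
#' thresholds, seeds, and input checksums.
#'
#' @param config A [validate_config()] result, a config list, or a YAML
#'   path.
#' @return Invisibly, a list with `report` (the candidate-gene data frame),
#'   `degs` (per-dataset `deg_table`s), `overlap`, `overlap_permutation`,
#'   `survival` (per-cohort scan and Cox tables), `deg_survival_permutation`,
#'   `qpcr`, `peaks`, and `manifest`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  if (length(config$datasets) == 0) stop("no datasets configured")
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  thr <- config$thresholds
  master_seed <- config$permutation$seed

  ## stage 1: differential expression per dataset -------------------------
  degs <- list(); universes <- list(); cohort_data <- list()
  for (d in config$datasets) {
    pipeline_log(config, "differential expression: ", d$id)
    if (d$type == "external_deg") {
      tab <- ingest_external_deg_table(d$path,
                                       column_map = d$column_map %||% list(),
                                       dataset_id = d$id)
      if (!d$preselected) {
        full <- tab$records
        tab <- select_degs(full, fdr_max = thr$fdr_max,
                           fc_decile = thr$fc_decile,
                           fc_decile_scope = thr$fc_decile_scope,
                           dataset_id = d$id)
        universes[[d$id]] <- sort(unique(full$gene))
      } else {
        universes[[d$id]] <- sort(unique(tab$records$gene))
      }
      degs[[d$id]] <- tab
    } else {
      ds <- read_expression_dataset(d$expression, d$annotations,
                                    feature_map_path = d$feature_map,
                                    dataset_id = d$id)
      de <- differential_expression(
        ds, type = if (d$type == "cohort") "cohort" else "cellline",
        fdr_max = thr$fdr_max, fc_decile = thr$fc_decile,
        fc_decile_scope = thr$fc_decile_scope)
      degs[[d$id]] <- de$degs
      universes[[d$id]] <- sort(unique(de$fits$gene))
      if (d$type == "cohort") cohort_data[[d$id]] <- ds
    }
    write_deg_table(degs[[d$id]], file.path(out_dir,
                                            paste0("deg_", d$id, ".tsv")))
  }

  ## stage 2: intersection + overlap permutation --------------------------
  sets <- lapply(names(degs), function(id)
    signature_set(degs[[id]], universes[[id]], dataset_id = id))
  overlap <- NULL; overlap_perm <- NULL
  candidates <- character(0)
  if (length(sets) >= 2) {
    overlap <- intersect_signatures(sets)
    candidates <- overlap$consistent_genes
    sizes <- vapply(degs, function(d) nrow(d$records), integer(1))
    if (all(sizes > 0)) {
      pipeline_log(config, "overlap permutation test (",
                   config$permutation$n, " reps)")
      overlap_perm <- permutation_overlap_test(
        set_sizes = unname(sizes), universes = unname(universes),
        observed = overlap$n_shared,
        n_permutations = config$permutation$n,
        seed = derive_seed(master_seed, "overlap_permutation"))
    }
    ov_df <- data.frame(gene = overlap$shared_genes,
                        consistent = overlap$shared_genes %in%
                          overlap$consistent_genes)
    utils::write.table(cbind(ov_df, overlap$directions),
                       file.path(out_dir, "overlap.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(member_sets = overlap$member_sets, n_shared = overlap$n_shared,
           n_direction_consistent = overlap$n_direction_consistent,
           permutation_p = overlap_perm$p %||% NA,
           permutation_p_bias_guarded = overlap_perm$p_bias_guarded %||% NA),
      file.path(out_dir, "overlap.json"), auto_unbox = TRUE, digits = NA)
  }

  ## stage 3: survival per cohort -----------------------------------------
  surv <- list()
  for (id in names(cohort_data)) {
    ds <- cohort_data[[id]]
    scan_genes <- if (config$survival_scan_scope == "all")
      rownames(ds$matrix) else
        intersect(unique(degs[[id]]$records$gene), rownames(ds$matrix))
    if (length(scan_genes) == 0) {
      surv[[id]] <- list(scan = NULL, cox = NULL,
                         prognostic = character(0))
      next
    }
    pipeline_log(config, "survival scan: ", id, " (",
                 length(scan_genes), " genes)")
    scan <- scan_all_genes(ds, genes = scan_genes,
                           min_fraction = thr$survival_min_fraction)
    prognostic <- scan$per_gene$gene[!is.na(scan$per_gene$min_q) &
                                       scan$per_gene$min_q < thr$prognostic_fdr]
    cox_genes <- intersect(candidates, rownames(ds$matrix))
    cox <- if (length(cox_genes) && sum(ds$sample_annotations$os_event) >= 10)
      cox_scan(ds, genes = cox_genes) else NULL
    utils::write.table(scan$per_gene,
                       file.path(out_dir, paste0("survival_scan_", id,
                                                 ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(cox))
      utils::write.table(cox, file.path(out_dir, paste0("cox_", id, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    surv[[id]] <- list(scan = scan$per_gene, cox = cox,
                       prognostic = prognostic)
  }

  ## stage 4: DEG-prognosis permutation ------------------------------------
  deg_surv_perm <- NULL
  cohort_ids <- names(cohort_data)
  if (length(cohort_ids) >= 2 && length(candidates) > 0) {
    c1 <- cohort_ids[1]; c2 <- cohort_ids[2]
    deg1 <- unique(degs[[c1]]$records$gene)
    deg2 <- unique(degs[[c2]]$records$gene)
    prog_both <- intersect(surv[[c1]]$prognostic, surv[[c2]]$prognostic)
    observed <- c(sum(intersect(candidates, deg1) %in% prog_both),
                  sum(intersect(candidates, deg2) %in% prog_both))
    draws <- config$permutation$draw_sizes %||%
      c(length(intersect(candidates, deg1)),
        length(intersect(candidates, deg2)))
    if (all(draws >= 1) && all(draws <= c(length(deg1), length(deg2)))) {
      pipeline_log(config, "DEG-prognosis permutation test")
      deg_surv_perm <- deg_survival_permutation(
        list(deg1, deg2), list(surv[[c1]]$prognostic, surv[[c2]]$prognostic),
        draw_sizes = draws, observed = observed,
        n_permutations = config$permutation$n,
        seed = derive_seed(master_seed, "deg_survival_permutation"))
      jsonlite::write_json(
        lapply(deg_surv_perm, function(r)
          list(observed = r$observed, p = r$p,
               p_bias_guarded = r$p_bias_guarded)),
        file.path(out_dir, "deg_survival_permutation.json"),
        auto_unbox = TRUE, digits = NA)
    }
  }

  ## stage 5: qPCR + peaks --------------------------------------------------
  qpcr <- NULL
  if (!is.null(config$qpcr)) {
    pipeline_log(config, "qPCR quantification")
    ct <- utils::read.csv(config$qpcr$ct_table, stringsAsFactors = FALSE)
    qpcr <- quantify_qpcr(ct, reference_gene = config$qpcr$reference_gene)
    utils::write.table(qpcr, file.path(out_dir, "qpcr.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  peaks <- NULL
  if (!is.null(config$peaks)) {
    pipeline_log(config, "promoter peak annotation")
    peaks <- annotate_genes_with_peaks(
      config$peaks$gene_bed, config$peaks$peak_bed,
      promoter_window = config$peaks$promoter_window %||% 2000)
    utils::write.table(peaks, file.path(out_dir, "peak_flags.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  ## stage 6: candidate report ----------------------------------------------
  report <- candidate_report(overlap, degs, surv, qpcr, peaks)
  utils::write.table(report, file.path(out_dir, "candidate_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  input_files <- unlist(lapply(config$datasets, function(d)
    c(d$path, d$expression, d$annotations, d$feature_map)), use.names = FALSE)
  input_files <- c(input_files, config$qpcr$ct_table, config$peaks$gene_bed,
                   config$peaks$peak_bed)
  input_files <- input_files[!vapply(input_files, is.null, logical(1))]
  manifest <- list(
    package_version = as.character(utils::packageVersion("nbhypoxia")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    thresholds = thr,
    permutation = list(n = config$permutation$n, seed = master_seed),
    survival_scan_scope = config$survival_scan_scope,
    inputs = as.list(tools::md5sum(unlist(input_files))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(report = report, degs = degs, overlap = overlap,
                 overlap_permutation = overlap_perm, survival = surv,
                 deg_survival_permutation = deg_surv_perm, qpcr = qpcr,
                 peaks = peaks, manifest = manifest,
                 candidates = candidates))
}

# Assemble the per-gene candidate report from the stage outputs.
candidate_report <- function(overlap, degs, surv, qpcr, peaks) {
  genes <- if (is.null(overlap)) character(0) else overlap$shared_genes
  rep_df <- data.frame(gene = genes, stringsAsFactors = FALSE)
  for (id in names(degs)) {
    recs <- degs[[id]]$records
    m <- match(genes, recs$gene)
    rep_df[[paste0("deg_", id)]] <- !is.na(m)
    rep_df[[paste0("direction_", id)]] <- ifelse(is.na(m), NA,
                                                 recs$direction[m])
  }
  rep_df$direction_consistent <- genes %in%
    (if (is.null(overlap)) character(0) else overlap$consistent_genes)
  rep_df$candidate <- rep_df$direction_consistent
  for (id in names(surv)) {
    sc <- surv[[id]]$scan
    if (!is.null(sc)) {
      m <- match(genes, sc$gene)
      rep_df[[paste0("km_min_q_", id)]] <- sc$min_q[m]
    }
    cx <- surv[[id]]$cox
    if (!is.null(cx)) {
      m <- match(genes, cx$gene)
      rep_df[[paste0("cox_q_uni_", id)]] <- cx$q_uni[m]
      rep_df[[paste0("cox_q_multi_", id)]] <- cx$q_multi[m]
    }
  }
  if (!is.null(qpcr)) {
    m <- match(genes, qpcr$gene)
    rep_df$qpcr_log2_fold <- qpcr$log2_fold[m]
    rep_df$qpcr_p <- qpcr$p[m]
  }
  if (!is.null(peaks)) {
    m <- match(genes, peaks$gene)
    rep_df$peak_flag <- peaks$flagged[m]
  }
  rep_df
}
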