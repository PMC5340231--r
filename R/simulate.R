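#' Derive a module-level seed from a master seed
#'
#' All randomness in the workflow flows from one master seed; per-stage seeds
#' are derived by hashing the stage name into an offset, so that stage-level
#' results are reproducible independently of execution order. The result is
#' always a valid 32-bit integer seed.
#'
#' @param master Integer master seed.
#' @param stage Character stage label (e.g. "cohort1", "permutation").
#' @return An integer seed.
#' @export
derive_seed <- function(master, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 2147480009
  as.integer((as.numeric(master) %% 2147480009 * 7919 + h) %% 2147483647)
}

#' Configuration for the synthetic patient-cohort generator
#'
#' Defaults emulate the structure of a large diagnostic neuroblastoma cohort:
#' 478 patients of whom roughly 19% die during follow-up and 15.5% carry
#' MYCN-amplified tumors, with INSS stage and age at diagnosis correlated
#' with outcome. A latent high-risk state (the top `1 - threshold_quantile`
#' fraction of patients) raises the death hazard by `exp(log_hazard_ratio)`
#' and shifts the planted prognostic genes by `effect_size` log2 units, so
#' expression dichotomized at the `threshold_quantile` cutpoint separates the
#' hazard groups.
#'
#' @param n_patients,n_genes,n_prognostic,n_mycn_genes Cohort and panel sizes.
#'   The prognostic genes are the first `n_prognostic` genes; a disjoint set
#'   of `n_mycn_genes` genes responds to MYCN amplification only.
#' @param effect_size Log2 expression shift of prognostic genes in high-risk
#'   patients.
#' @param mycn_fraction Marginal fraction of MYCN-amplified patients.
#' @param mycn_confound Log2 shift of the MYCN-responsive genes in amplified
#'   patients.
#' @param mycn_risk_assoc In \[0, 1\]: how strongly MYCN amplification is
#'   enriched among high-risk patients (0 = independent).
#' @param baseline_hazard Events per time unit (months) for low-risk patients.
#' @param log_hazard_ratio Log hazard ratio of high- vs low-risk patients.
#' @param threshold_quantile Expression quantile at which the survival effect
#'   switches; the fraction `1 - threshold_quantile` of patients is high-risk.
#' @param censor_rate Target fraction of censored patients; censoring times
#'   are uniform on (0, c_max) with c_max calibrated to hit this rate.
#' @param noise_sd Residual log2 sd.
#' @param stage_probs_low,stage_probs_high INSS stage (1,2,3,4,4S)
#'   probabilities for low- and high-risk patients.
#' @param age_outcome_shift Mean age (months) excess of high-risk patients.
#' @param seed RNG seed.
#' @return A validated list of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n_patients = 478, n_genes = 2000,
                              n_prognostic = 50, n_mycn_genes = n_prognostic,
                              effect_size = 2.5, mycn_fraction = 74 / 478,
                              mycn_confound = 1.0, mycn_risk_assoc = 0.5,
                              baseline_hazard = 5e-4,
                              log_hazard_ratio = log(5),
                              threshold_quantile = 0.6, censor_rate = 0.81,
                              noise_sd = 1.0,
                              stage_probs_low = c(0.30, 0.20, 0.15, 0.20, 0.15),
                              stage_probs_high = c(0.05, 0.10, 0.15, 0.60, 0.10),
                              age_outcome_shift = 20, seed = 1L) {
  cfg <- list(n_patients = n_patients, n_genes = n_genes,
              n_prognostic = n_prognostic, n_mycn_genes = n_mycn_genes,
              effect_size = effect_size, mycn_fraction = mycn_fraction,
              mycn_confound = mycn_confound, mycn_risk_assoc = mycn_risk_assoc,
              baseline_hazard = baseline_hazard,
              log_hazard_ratio = log_hazard_ratio,
              threshold_quantile = threshold_quantile,
              censor_rate = censor_rate, noise_sd = noise_sd,
              stage_probs_low = stage_probs_low,
              stage_probs_high = stage_probs_high,
              age_outcome_shift = age_outcome_shift, seed = seed)
  if (n_prognostic > n_genes) stop("n_prognostic must not exceed n_genes")
  if (n_prognostic + n_mycn_genes > n_genes)
    stop("prognostic and MYCN gene sets must fit disjointly in n_genes")
  if (!is.finite(effect_size) || !is.finite(mycn_confound) ||
      !is.finite(log_hazard_ratio))
    stop("effect sizes must be finite")
  if (threshold_quantile <= 0 || threshold_quantile >= 1)
    stop("threshold_quantile must lie in (0, 1)")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  for (f in c("mycn_fraction", "mycn_risk_assoc", "censor_rate"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must lie in [0, 1]")
  if (baseline_hazard <= 0) stop("baseline_hazard must be positive")
  structure(cfg, class = "cohort_sim_config")
}

#' Simulate a clinically annotated patient expression cohort
#'
#' Generates a features x samples log2 expression matrix, right-censored
#' overall-survival outcomes driven by a threshold effect on the planted
#' prognostic genes, and MYCN/stage/age covariates partially confounded with
#' outcome. Ground truth (planted gene identities, directions, true
#' expression cutpoints, the latent risk group) is returned alongside.
#'
#' @param config A [cohort_sim_config()].
#' @return A list with elements `dataset` (an [expression_dataset()] whose
#'   annotations include `status`, `os_time`, `os_event`, `mycn`, `stage`,
#'   `age`) and `truth` (prognostic gene IDs, directions, true cutpoints,
#'   MYCN gene IDs, latent risk indicator).
#' @export
simulate_patient_cohort <- function(config = cohort_sim_config()) {
  stopifnot(inherits(config, "cohort_sim_config"))
  set.seed(config$seed)
  n <- config$n_patients; g <- config$n_genes
  genes <- sprintf("g%04d", seq_len(g))
  samples <- sprintf("P%04d", seq_len(n))
  prog <- genes[seq_len(config$n_prognostic)]
  mycn_genes <- if (config$n_mycn_genes > 0)
    genes[config$n_prognostic + seq_len(config$n_mycn_genes)] else character(0)

  # latent high-risk state: top (1 - threshold_quantile) fraction of patients
  n_high <- round((1 - config$threshold_quantile) * n)
  z <- integer(n)
  z[sample.int(n, n_high)] <- 1L

  # MYCN amplification enriched among high-risk patients, marginal fraction kept
  f1 <- n_high / n
  p1 <- min(1, config$mycn_fraction * (1 + config$mycn_risk_assoc))
  p0 <- max(0, (config$mycn_fraction - f1 * p1) / max(1 - f1, 1e-12))
  mycn <- stats::rbinom(n, 1, ifelse(z == 1, p1, p0))

  stage_levels <- c("1", "2", "3", "4", "4S")
  stage <- vapply(z, function(zi) {
    pr <- if (zi == 1) config$stage_probs_high else config$stage_probs_low
    sample(stage_levels, 1, prob = pr)
  }, character(1))
  age <- pmax(0, stats::rnorm(n, 30 + config$age_outcome_shift * z, 15))

  base <- stats::runif(g, 6, 12)
  mat <- matrix(stats::rnorm(g * n, 0, config$noise_sd), g, n,
                dimnames = list(genes, samples))
  mat <- mat + base
  mat[prog, ] <- mat[prog, ] +
    config$effect_size * matrix(z, length(prog), n, byrow = TRUE)
  if (length(mycn_genes))
    mat[mycn_genes, ] <- mat[mycn_genes, ] +
      config$mycn_confound * matrix(mycn, length(mycn_genes), n, byrow = TRUE)

  hazard <- config$baseline_hazard * exp(config$log_hazard_ratio * z)
  t_event <- stats::rexp(n, hazard)
  if (config$censor_rate <= 0) {
    os_time <- t_event; os_event <- rep(1L, n)
  } else if (config$censor_rate >= 1) {
    stop("censor_rate must be below 1 for events to occur")
  } else {
    # calibrate uniform censoring C ~ U(0, cmax) so that P(C < T) matches
    cens_frac <- function(cmax) mean(pmin(t_event / cmax, 1)) -
      config$censor_rate
    lo <- min(t_event) / 2; hi <- max(t_event) * 100
    cmax <- if (cens_frac(hi) > 0) hi else
      stats::uniroot(cens_frac, c(lo, hi), tol = 1e-6)$root
    cens <- stats::runif(n, 0, cmax)
    os_event <- as.integer(t_event <= cens)
    os_time <- pmin(t_event, cens)
  }
  os_time <- pmax(os_time, 1e-6)

  ann <- data.frame(
    sample_id = samples,
    status = ifelse(os_event == 1L, "deceased", "survivor"),
    os_time = os_time, os_event = os_event, mycn = mycn,
    stage = stage, age = age, stringsAsFactors = FALSE)

  cutpoints <- apply(mat[prog, , drop = FALSE], 1, stats::quantile,
                     probs = config$threshold_quantile, names = FALSE)
  list(
    dataset = expression_dataset(mat, ann, dataset_id = "synthetic_cohort"),
    truth = list(prognostic_genes = prog,
                 directions = stats::setNames(rep("up", length(prog)), prog),
                 true_cutpoints = cutpoints,
                 mycn_genes = mycn_genes,
                 risk_group = stats::setNames(z, samples))
  )
}

#' Configuration for the synthetic cell-line hypoxia experiment
#'
#' Defaults emulate a panel of 11 neuroblastoma cell lines each profiled in
#' normoxia (21% O2) and hypoxia (1% O2), with between-line variation as a
#' random intercept and MYCN status and N/S growth pattern as line-level
#' attributes.
#'
#' @param n_lines Number of cell lines (each measured in both conditions).
#' @param n_replicates_per_condition Replicates per line and condition.
#' @param n_genes,n_hypoxia_responsive Panel sizes; responsive genes are the
#'   first `n_hypoxia_responsive` genes.
#' @param hypoxia_effect Log2 shift of responsive genes under 1% O2.
#' @param line_sd Between-line random-intercept sd (log2 units).
#' @param noise_sd Residual sd.
#' @param mycn_lines Indices of MYCN-amplified lines (default: first half).
#' @param growth_pattern "N"/"S" label per line (default alternating).
#' @param seed RNG seed.
#' @return A validated list of class `cellline_sim_config`.
#' @export
cellline_sim_config <- function(n_lines = 11, n_replicates_per_condition = 1,
                                n_genes = 2000,
                                n_hypoxia_responsive = min(50, n_genes),
                                hypoxia_effect = 2.0, line_sd = 0.5,
                                noise_sd = 0.5,
                                mycn_lines = seq_len(ceiling(n_lines / 2)),
                                growth_pattern = NULL, seed = 1L) {
  if (n_lines < 1) stop("n_lines must be at least 1")
  if (n_hypoxia_responsive > n_genes)
    stop("n_hypoxia_responsive must not exceed n_genes")
  if (line_sd < 0) stop("line_sd must be non-negative")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  if (!is.finite(hypoxia_effect)) stop("hypoxia_effect must be finite")
  if (is.null(growth_pattern))
    growth_pattern <- rep(c("N", "S"), length.out = n_lines)
  if (length(growth_pattern) != n_lines)
    stop("growth_pattern must have one label per line")
  if (length(mycn_lines) && (min(mycn_lines) < 1 || max(mycn_lines) > n_lines))
    stop("mycn_lines must index lines 1..n_lines")
  structure(list(n_lines = n_lines,
                 n_replicates_per_condition = n_replicates_per_condition,
                 n_genes = n_genes,
                 n_hypoxia_responsive = n_hypoxia_responsive,
                 hypoxia_effect = hypoxia_effect, line_sd = line_sd,
                 noise_sd = noise_sd, mycn_lines = mycn_lines,
                 growth_pattern = growth_pattern, seed = seed),
            class = "cellline_sim_config")
}

#' Simulate a hypoxia vs normoxia cell-line expression experiment
#'
#' Expression is baseline + per-line random intercept + `hypoxia_effect` for
#' responsive genes under hypoxia + residual noise, with condition, line,
#' MYCN, and growth-pattern annotations attached.
#'
#' @param config A [cellline_sim_config()].
#' @return A list with `dataset` (an [expression_dataset()]) and `truth`
#'   (responsive gene IDs and directions).
#' @export
simulate_cellline_experiment <- function(config = cellline_sim_config()) {
  stopifnot(inherits(config, "cellline_sim_config"))
  set.seed(config$seed)
  L <- config$n_lines; r <- config$n_replicates_per_condition
  g <- config$n_genes
  genes <- sprintf("g%04d", seq_len(g))
  resp <- genes[seq_len(config$n_hypoxia_responsive)]

  design <- expand.grid(replicate = seq_len(r),
                        condition = c("normoxia", "hypoxia"),
                        line = sprintf("L%02d", seq_len(L)),
                        stringsAsFactors = FALSE)
  design$sample_id <- sprintf("%s_%s_r%d", design$line, design$condition,
                              design$replicate)
  line_idx <- as.integer(factor(design$line))
  design$mycn <- as.integer(line_idx %in% config$mycn_lines)
  design$growth_pattern <- config$growth_pattern[line_idx]
  n <- nrow(design)

  base <- stats::runif(g, 6, 12)
  line_int <- matrix(stats::rnorm(g * L, 0, config$line_sd), g, L)
  mat <- base + line_int[, line_idx, drop = FALSE] +
    matrix(stats::rnorm(g * n, 0, config$noise_sd), g, n)
  dimnames(mat) <- list(genes, design$sample_id)
  hyp <- design$condition == "hypoxia"
  mat[resp, hyp] <- mat[resp, hyp] + config$hypoxia_effect

  ann <- design[, c("sample_id", "condition", "line", "mycn",
                    "growth_pattern", "replicate")]
  list(
    dataset = expression_dataset(mat, ann, dataset_id = "synthetic_cellline"),
    truth = list(
      responsive_genes = if (config$hypoxia_effect == 0) character(0) else resp,
      directions = if (config$hypoxia_effect == 0)
        stats::setNames(character(0), character(0)) else
          stats::setNames(rep(if (config$hypoxia_effect > 0) "up" else "down",
                              length(resp)), resp))
  )
}

#' Configuration for the synthetic qRT-PCR plate generator
#'
#' @param genes Gene identifiers, including the reference gene.
#' @param true_log2_fold Named (or positionally matched) per-gene log2 fold
#'   change hypoxia vs normoxia; the reference gene must have 0.
#' @param reference_gene Housekeeping reference (default "ACTB").
#' @param n_replicates Replicates per gene and condition (default 3).
#' @param ct_noise_sd Measurement noise in Ct units.
#' @param seed RNG seed.
#' @return A validated list of class `qpcr_sim_config`.
#' @export
qpcr_sim_config <- function(genes = c("SLCO4A1", "ENO1", "HK2", "PGK1",
                                      "MTFP1", "HILPDA", "VKORC1", "TPI1",
                                      "HIST1H1C", "ACTB"),
                            true_log2_fold = c(rep(2, 9), 0),
                            reference_gene = "ACTB", n_replicates = 3,
                            ct_noise_sd = 0.25, seed = 1L) {
  if (!reference_gene %in% genes)
    stop("reference_gene must be among genes")
  if (length(true_log2_fold) != length(genes))
    stop("true_log2_fold must have one value per gene")
  true_log2_fold <- stats::setNames(as.numeric(true_log2_fold), genes)
  if (true_log2_fold[[reference_gene]] != 0)
    stop("reference gene must have true_log2_fold = 0")
  if (n_replicates < 2) stop("n_replicates must be at least 2")
  if (ct_noise_sd < 0) stop("ct_noise_sd must be non-negative")
  structure(list(genes = genes, true_log2_fold = true_log2_fold,
                 reference_gene = reference_gene, n_replicates = n_replicates,
                 ct_noise_sd = ct_noise_sd, seed = seed),
            class = "qpcr_sim_config")
}

#' Simulate a triplicate qRT-PCR Ct plate
#'
#' Each gene has a baseline Ct; hypoxia lowers the Ct of gene g by
#' `true_log2_fold[g]` cycles (one cycle = one log2 expression unit), so the
#' expected delta-delta-Ct equals `-true_log2_fold[g]`. The reference gene's
#' Ct is unaffected by condition.
#'
#' @param config A [qpcr_sim_config()].
#' @return A data.frame with columns `gene`, `condition`, `replicate`, `ct`.
#' @export
simulate_qpcr_plate <- function(config = qpcr_sim_config()) {
  stopifnot(inherits(config, "qpcr_sim_config"))
  set.seed(config$seed)
  baseline <- stats::setNames(
    ifelse(config$genes == config$reference_gene, 15,
           stats::runif(length(config$genes), 18, 26)), config$genes)
  grid <- expand.grid(replicate = seq_len(config$n_replicates),
                      condition = c("normoxia", "hypoxia"),
                      gene = config$genes, stringsAsFactors = FALSE)
  mu <- baseline[grid$gene] -
    ifelse(grid$condition == "hypoxia",
           config$true_log2_fold[grid$gene], 0)
  grid$ct <- as.numeric(mu) + stats::rnorm(nrow(grid), 0, config$ct_noise_sd)
  grid[, c("gene", "condition", "replicate", "ct")]
}

#' Write a Ct table to the pipeline's CSV format
#' @param ct_table Data frame from [simulate_qpcr_plate()].
#' @param path Output CSV path.
#' @export
write_ct_table <- function(ct_table, path) {
  utils::write.csv(ct_table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Generate matched gene/peak BED fixtures for promoter annotation
#'
#' Writes a 6-column gene BED (one TSS per gene, alternating strand, genes
#' spaced far apart on one chromosome) and a peak BED whose peaks fall inside
#' the promoter windows of exactly the flagged genes.
#'
#' @param n_genes Number of genes.
#' @param flagged Character vector of flagged gene names (subset of the
#'   generated `gene0001`-style names) or integer indices.
#' @param promoter_window Half-width (bp) of the promoter window around the
#'   TSS that downstream annotation will use.
#' @param seed RNG seed.
#' @param dir Directory to write `genes.bed` and `peaks.bed` into.
#' @param gene_names Optional explicit gene names (so the fixture can share
#'   the identifier space of an expression panel); default `gene0001`-style.
#' @return List with `gene_bed`, `peak_bed` paths, the gene names, and the
#'   flagged set.
#' @export
simulate_peak_fixtures <- function(n_genes, flagged = character(0),
                                   promoter_window = 2000, seed = 1L,
                                   dir = tempdir(), gene_names = NULL) {
  if (promoter_window < 0) stop("promoter_window must be non-negative")
  set.seed(seed)
  genes <- if (is.null(gene_names)) sprintf("gene%04d", seq_len(n_genes)) else
    as.character(gene_names)
  if (length(genes) != n_genes) stop("gene_names must have length n_genes")
  if (is.numeric(flagged)) flagged <- genes[flagged]
  if (!all(flagged %in% genes)) stop("flagged genes must be a subset of genes")
  spacing <- max(100000, 4 * promoter_window)
  strand <- rep(c("+", "-"), length.out = n_genes)
  start <- spacing * seq_len(n_genes)
  end <- start + 1000
  gene_bed <- data.frame(chrom = "chr1", start = start, end = end,
                         name = genes, score = 0, strand = strand,
                         stringsAsFactors = FALSE)
  gene_path <- file.path(dir, "genes.bed")
  utils::write.table(gene_bed, gene_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  peak_path <- file.path(dir, "peaks.bed")
  if (length(flagged) == 0) {
    file.create(peak_path)
  } else {
    tss <- ifelse(strand == "+", start, end)
    names(tss) <- genes
    w <- max(promoter_window, 1)
    width <- min(200, w)
    off <- vapply(flagged, function(gn)
      sample.int(max(2 * w - width, 1), 1) - w - 1, numeric(1))
    p_start <- pmax(0, tss[flagged] + off)
    peak_bed <- data.frame(chrom = "chr1", start = p_start,
                           end = p_start + width,
                           name = sprintf("peak_%s", flagged),
                           score = 100, strand = ".",
                           stringsAsFactors = FALSE)
    utils::write.table(peak_bed, peak_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  list(gene_bed = gene_path, peak_bed = peak_path, genes = genes,
       flagged = flagged)
}
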