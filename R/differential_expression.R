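#' Per-feature survivor vs deceased linear model with MYCN adjustment
#'
#' Fits, for every feature, the ordinary least-squares model
#' `y ~ status + MYCN` on log2 expression and returns the status coefficient
#' (deceased minus survivor, i.e. the log2 fold change) together with its
#' ordinary two-sided t-test p-value. Fitting is vectorized across features
#' via `limma::lmFit`; the returned statistics are classical OLS, not
#' empirical-Bayes moderated.
#'
#' Features with zero residual variance are returned with `p = 1` and their
#' (typically zero) coefficient, flagged in the `degenerate` column, so that
#' downstream filters behave deterministically. A design in which status is
#' perfectly confounded with MYCN drops the MYCN column with a warning and
#' flags all rows as `confounded`.
#'
#' @param data An [expression_dataset()] whose annotations contain `status`
#'   ("deceased"/"survivor") and binary `mycn`.
#' @return A data.frame with columns `feature`, `log2fc`, `p`, `t`, `df`,
#'   `degenerate`, `confounded`.
#' @export
fit_survivor_model <- function(data) {
  stopifnot(inherits(data, "expression_dataset"))
  ann <- data$sample_annotations
  if (!all(c("status", "mycn") %in% names(ann)))
    stop("annotations must contain status and mycn")
  status <- factor(ann$status, levels = c("survivor", "deceased"))
  if (anyNA(status)) stop("status must be 'survivor' or 'deceased'")
  tab <- table(status)
  if (any(tab < 2))
    stop("level with fewer than 2 samples: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  mycn <- as.numeric(ann$mycn)
  design <- cbind(Intercept = 1, status = as.numeric(status) - 1, mycn = mycn)
  confounded <- FALSE
  if (qr(design)$rank < ncol(design)) {
    warning("status is confounded with MYCN; dropping the MYCN term")
    design <- design[, c("Intercept", "status"), drop = FALSE]
    confounded <- TRUE
  }
  ols_feature_table(data$matrix, design, coef = "status",
                    confounded = confounded)
}

# Classical per-feature OLS t-tests for one coefficient of a shared design,
# computed through limma::lmFit (used for its vectorized QR, not for
# empirical-Bayes moderation).
ols_feature_table <- function(mat, design, coef, confounded = FALSE) {
  fit <- limma::lmFit(mat, design)
  beta <- fit$coefficients[, coef]
  se <- fit$stdev.unscaled[, coef] * fit$sigma
  df <- fit$df.residual
  degenerate <- !is.finite(se) | !is.finite(fit$sigma) |
    fit$sigma < 1e-8  # zero residual variance up to numerical noise
  tstat <- ifelse(degenerate, 0, beta / se)
  p <- ifelse(degenerate, 1, 2 * stats::pt(-abs(tstat), df))
  data.frame(feature = rownames(mat),
             log2fc = ifelse(is.finite(beta), beta, 0),
             p = p, t = tstat, df = df,
             degenerate = degenerate, confounded = confounded,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-feature hypoxia mixed model for cell-line panels
#'
#' Fits, for every feature, the Gaussian linear mixed model
#' `y ~ condition + mycn + growth_pattern + (1 | line)` and returns the
#' hypoxia coefficient (hypoxia minus normoxia log2 fold change) with a
#' Satterthwaite-df t-test p-value (via \pkg{lmerTest}). The response is
#' normalized log intensity, so the identity link is appropriate.
#'
#' With a single cell line (or when the mixed fit fails), the model falls
#' back to ordinary least squares on the fixed effects that still vary, with
#' a warning; the `fallback` column records which features took that path.
#'
#' @param data An [expression_dataset()] whose annotations contain
#'   `condition` ("normoxia"/"hypoxia"), `line`, `mycn`, `growth_pattern`.
#' @return A data.frame with columns `feature`, `log2fc`, `p`, `fallback`.
#' @export
fit_hypoxia_model <- function(data) {
  stopifnot(inherits(data, "expression_dataset"))
  ann <- data$sample_annotations
  need <- c("condition", "line", "mycn", "growth_pattern")
  if (!all(need %in% names(ann)))
    stop("annotations must contain ", paste(need, collapse = ", "))
  cond <- factor(ann$condition, levels = c("normoxia", "hypoxia"))
  if (anyNA(cond)) stop("condition must be 'normoxia' or 'hypoxia'")
  if (length(unique(cond)) < 2) stop("both oxygen conditions are required")
  n_lines <- length(unique(ann$line))

  if (n_lines < 2) {
    warning("single cell line: falling back to fixed-effects OLS")
    return(hypoxia_ols_fallback(data, cond))
  }

  df_ann <- data.frame(condition = cond,
                       mycn = as.numeric(ann$mycn),
                       growth_pattern = factor(ann$growth_pattern),
                       line = factor(ann$line))
  # line-level covariates that do not vary are dropped from the formula
  terms <- c("condition",
             if (length(unique(df_ann$mycn)) > 1) "mycn",
             if (nlevels(df_ann$growth_pattern) > 1) "growth_pattern")
  form <- stats::as.formula(
    paste("y ~", paste(terms, collapse = " + "), "+ (1 | line)"))

  mat <- data$matrix
  out <- matrix(NA_real_, nrow(mat), 2,
                dimnames = list(rownames(mat), c("log2fc", "p")))
  fallback <- logical(nrow(mat))
  for (i in seq_len(nrow(mat))) {
    df_ann$y <- mat[i, ]
    fit <- tryCatch(
      suppressWarnings(suppressMessages(
        lmerTest::lmer(form, data = df_ann,
                       control = lme4::lmerControl(
                         check.conv.singular = "ignore",
                         calc.derivs = FALSE)))),
      error = function(e) NULL)
    if (!is.null(fit) &&
        length(fit@optinfo$conv$lme4$messages) > 0)
      fit <- NULL  # non-converged: flagged, OLS estimate reported
    if (is.null(fit)) {
      ols <- stats::lm(stats::as.formula(
        paste("y ~", paste(terms, collapse = " + "))), data = df_ann)
      sm <- summary(ols)$coefficients
      out[i, ] <- c(sm["conditionhypoxia", 1], sm["conditionhypoxia", 4])
      fallback[i] <- TRUE
    } else {
      sm <- stats::coef(summary(fit))
      out[i, ] <- c(sm["conditionhypoxia", "Estimate"],
                    sm["conditionhypoxia", "Pr(>|t|)"])
    }
  }
  if (any(fallback))
    message(sum(fallback), " feature(s) used the OLS fallback")
  data.frame(feature = rownames(mat), log2fc = out[, "log2fc"],
             p = ifelse(is.finite(out[, "p"]), out[, "p"], 1),
             fallback = fallback, stringsAsFactors = FALSE, row.names = NULL)
}

hypoxia_ols_fallback <- function(data, cond) {
  ann <- data$sample_annotations
  design <- cbind(Intercept = 1, condition = as.numeric(cond) - 1)
  for (extra in c("mycn", "growth_pattern")) {
    v <- ann[[extra]]
    if (length(unique(v)) > 1) {
      col <- as.numeric(factor(v)) - 1
      design <- cbind(design, col)
      colnames(design)[ncol(design)] <- extra
    }
  }
  res <- ols_feature_table(data$matrix, design, coef = "condition")
  data.frame(feature = res$feature, log2fc = res$log2fc, p = res$p,
             fallback = TRUE, stringsAsFactors = FALSE)
}

#' Collapse per-probe statistics to one record per gene
#'
#' For each gene, the probe with the most significant p-value is retained and
#' its effect estimate carried along. Ties are broken deterministically:
#' smallest p, then largest absolute log2 fold change, then lexicographically
#' smallest probe ID. Probes absent from the map are dropped with a message.
#'
#' @param table Data frame with at least `feature`, `log2fc`, `p`.
#' @param feature_map Data frame with `probe_id`, `gene_symbol`.
#' @return The input rows, one per gene, with columns `gene` and
#'   `source_probe` added.
#' @export
collapse_probes <- function(table, feature_map) {
  if (is.null(feature_map) || nrow(feature_map) == 0)
    stop("feature_map is empty")
  idx <- match(table$feature, feature_map$probe_id)
  unmapped <- sum(is.na(idx))
  if (unmapped > 0)
    message(unmapped, " unmapped probe(s) dropped")
  tab <- table[!is.na(idx), , drop = FALSE]
  tab$gene <- feature_map$gene_symbol[idx[!is.na(idx)]]
  ord <- order(tab$gene, tab$p, -abs(tab$log2fc), tab$feature)
  tab <- tab[ord, , drop = FALSE]
  keep <- !duplicated(tab$gene)
  out <- tab[keep, , drop = FALSE]
  out$source_probe <- out$feature
  rownames(out) <- NULL
  out
}

#' Select differentially expressed genes by the dual criterion
#'
#' A gene is called differentially expressed when its q-value is below
#' `fdr_max` AND its log2 fold change lies in the top or bottom `fc_decile`
#' of the signed log2 fold-change distribution. By default the decile is
#' computed over the full tested universe; `fc_decile_scope = "significant"`
#' restricts the decile to the FDR-significant subset.
#'
#' @param table Data frame with `gene`, `log2fc`, `q` populated (one row per
#'   gene).
#' @param fdr_max Maximum q-value (default 0.01).
#' @param fc_decile Tail fraction of the fold-change distribution (default
#'   0.10); must lie in (0, 0.5).
#' @param fc_decile_scope `"universe"` (default) or `"significant"`.
#' @param dataset_id Label carried into the returned table.
#' @return A `deg_table`: list with `records` (the selected rows, with a
#'   `direction` column), `universe_size`, and `dataset_id`.
#' @export
select_degs <- function(table, fdr_max = 0.01, fc_decile = 0.10,
                        fc_decile_scope = c("universe", "significant"),
                        dataset_id = "dataset") {
  fc_decile_scope <- match.arg(fc_decile_scope)
  if (fc_decile <= 0 || fc_decile >= 0.5)
    stop("fc_decile must lie in (0, 0.5)")
  if (!all(c("gene", "log2fc", "q") %in% names(table)))
    stop("table must have gene, log2fc, q columns")
  if (anyNA(table$q) || anyNA(table$log2fc))
    stop("q and log2fc must be populated for all genes")
  universe_size <- nrow(table)
  sig <- table$q < fdr_max
  fc_pool <- if (fc_decile_scope == "universe") table$log2fc else
    table$log2fc[sig]
  if (length(fc_pool) == 0) {
    sel <- table[0, , drop = FALSE]
  } else {
    hi <- stats::quantile(fc_pool, 1 - fc_decile, names = FALSE)
    lo <- stats::quantile(fc_pool, fc_decile, names = FALSE)
    keep <- sig & (table$log2fc >= hi | table$log2fc <= lo)
    sel <- table[keep, , drop = FALSE]
  }
  if (nrow(sel) > 0) {
    sel$direction <- ifelse(sel$log2fc < 0, "down", "up")
    if (any(sel$log2fc == 0))
      warning("zero log2 fold change recorded as direction 'up'")
  } else {
    sel$direction <- character(0)
  }
  sel <- sel[order(sel$gene), , drop = FALSE]
  rownames(sel) <- NULL
  deg_table(sel, universe_size = universe_size, dataset_id = dataset_id)
}

#' Construct a DEG table
#'
#' @param records Data frame of per-gene records (one row per gene) with at
#'   least `gene`, `log2fc`, `q`, `direction`.
#' @param universe_size Number of genes tested in the dataset.
#' @param dataset_id Label.
#' @return An object of class `deg_table`.
#' @export
deg_table <- function(records, universe_size, dataset_id = "dataset") {
  if (anyDuplicated(records$gene))
    stop("one record per gene required")
  if (universe_size < nrow(records))
    stop("universe_size must be at least the number of records")
  structure(list(records = records, universe_size = universe_size,
                 dataset_id = dataset_id),
            class = "deg_table")
}

#' @export
print.deg_table <- function(x, ...) {
  cat("<deg_table> ", x$dataset_id, ": ", nrow(x$records), " DEGs of ",
      x$universe_size, " genes tested\n", sep = "")
  if (nrow(x$records))
    cat("  up: ", sum(x$records$direction == "up"),
        "  down: ", sum(x$records$direction == "down"), "\n", sep = "")
  invisible(x)
}

#' Write / ingest a DEG table in the pipeline's text format
#'
#' The TSV carries columns `gene`, `log2fc`, `p`, `q`, `direction`, and
#' optionally `source_probe`; `universe_size` and `dataset_id` travel in a
#' JSON sidecar (`<path>.json`). Ingesting a table without a `q` column
#' computes q-values from `p` via [compute_qvalues()]; a `q` column present
#' in the file is used verbatim.
#'
#' @param x A `deg_table`.
#' @param path TSV path.
#' @export
write_deg_table <- function(x, path) {
  stopifnot(inherits(x, "deg_table"))
  cols <- intersect(c("gene", "log2fc", "p", "q", "direction", "source_probe"),
                    names(x$records))
  utils::write.table(x$records[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(universe_size = x$universe_size,
                            dataset_id = x$dataset_id),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_deg_table
#' @param column_map Named list mapping the required names (`gene`,
#'   `log2fc`, `p`, and optionally `q`, `direction`) to the file's column
#'   names, for externally produced tables.
#' @param universe_size Override for the tested-universe size when no JSON
#'   sidecar exists (defaults to the number of rows).
#' @param dataset_id Label for the ingested table.
#' @export
ingest_external_deg_table <- function(path, column_map = list(),
                                      universe_size = NULL,
                                      dataset_id = "external") {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  for (std in names(column_map)) {
    src <- column_map[[std]]
    if (!src %in% names(tab))
      stop("mapped column not found in file: ", src)
    names(tab)[names(tab) == src] <- std
  }
  missing <- setdiff(c("gene", "log2fc"), names(tab))
  if (!any(c("p", "q") %in% names(tab)))
    missing <- c(missing, "p (or q)")
  if (length(missing))
    stop("missing mandatory columns: ", paste(missing, collapse = ", "))
  if (!"q" %in% names(tab)) tab$q <- compute_qvalues(tab$p)
  if (!"direction" %in% names(tab))
    tab$direction <- ifelse(tab$log2fc < 0, "down", "up")
  sidecar <- paste0(path, ".json")
  if (is.null(universe_size)) {
    if (file.exists(sidecar)) {
      meta <- jsonlite::read_json(sidecar)
      universe_size <- meta$universe_size
      if (identical(dataset_id, "external") && !is.null(meta$dataset_id))
        dataset_id <- meta$dataset_id
    } else {
      universe_size <- nrow(tab)
    }
  }
  tab <- tab[order(tab$gene), , drop = FALSE]
  rownames(tab) <- NULL
  deg_table(tab, universe_size = universe_size, dataset_id = dataset_id)
}

#' One-call differential expression for a dataset
#'
#' Runs the appropriate per-feature model ([fit_survivor_model()] for
#' patient cohorts, [fit_hypoxia_model()] for cell-line panels), collapses
#' probes when a feature map is present, computes q-values, and applies the
#' dual DEG criterion.
#'
#' @param data An [expression_dataset()].
#' @param type `"cohort"` or `"cellline"`.
#' @param fdr_max,fc_decile,fc_decile_scope Passed to [select_degs()].
#' @param pi0 Optional fixed null proportion for [compute_qvalues()].
#' @return A list with `fits` (the per-gene model table, q-values included)
#'   and `degs` (the selected `deg_table`).
#' @export
differential_expression <- function(data, type = c("cohort", "cellline"),
                                    fdr_max = 0.01, fc_decile = 0.10,
                                    fc_decile_scope = "universe",
                                    pi0 = NULL) {
  type <- match.arg(type)
  fits <- if (type == "cohort") fit_survivor_model(data) else
    fit_hypoxia_model(data)
  if (!is.null(data$feature_map)) {
    fits <- collapse_probes(fits, data$feature_map)
  } else {
    fits$gene <- fits$feature
    fits$source_probe <- fits$feature
  }
  fits$q <- compute_qvalues(fits$p, pi0 = pi0)
  degs <- select_degs(fits, fdr_max = fdr_max, fc_decile = fc_decile,
                      fc_decile_scope = fc_decile_scope,
                      dataset_id = data$dataset_id)
  list(fits = fits, degs = degs)
}
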