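#' Two-group log-rank test
#'
#' Standard 1-df log-rank chi-square over the distinct event times: at each
#' event time the observed minus expected events in group 2 accumulate, with
#' the conditional hypergeometric variance handling ties. Implemented
#' directly (rather than through a model fit) so the sliding-window cutpoint
#' scan can evaluate thousands of dichotomizations cheaply; agrees with
#' `survival::survdiff` on non-degenerate inputs.
#'
#' @param time Positive follow-up times.
#' @param event Event indicators (1 = death, 0 = censored).
#' @param group Two-level grouping (logical, factor, or two-value vector).
#' @return List with `statistic` (chi-square, 1 df), `p` (two-sided),
#'   `n_events`.
#' @export
logrank_test <- function(time, event, group) {
  if (length(time) != length(event) || length(time) != length(group))
    stop("time, event, group must have equal length")
  g <- as.integer(factor(group))
  if (length(unique(g)) != 2) {
    if (length(unique(g)) < 2) stop("both groups must be non-empty")
    stop("exactly two groups are required")
  }
  event <- as.integer(event)
  if (sum(event) == 0) {
    warning("no events observed; log-rank p-value set to 1")
    return(list(statistic = 0, p = 1, n_events = 0L))
  }
  in2 <- g == 2L
  stat <- logrank_stat(time, event, in2)
  p <- if (stat$v > 0)
    stats::pchisq(stat$oe^2 / stat$v, df = 1, lower.tail = FALSE) else 1
  list(statistic = if (stat$v > 0) stat$oe^2 / stat$v else 0, p = p,
       n_events = sum(event))
}

# Core O-E / variance accumulation for group 2, over distinct event times.
logrank_stat <- function(time, event, in2) {
  ut <- sort(unique(time[event == 1L]))
  oe <- 0; v <- 0
  for (tt in ut) {
    at_risk <- time >= tt
    n <- sum(at_risk)
    n2 <- sum(at_risk & in2)
    dead <- event == 1L & time == tt
    d <- sum(dead)
    d2 <- sum(dead & in2)
    oe <- oe + d2 - d * n2 / n
    if (n > 1)
      v <- v + d * (n2 / n) * (1 - n2 / n) * (n - d) / (n - 1)
  }
  list(oe = oe, v = v)
}

#' Sliding-window cutpoint scan for one gene
#'
#' Every admissible expression threshold dichotomizing the patients is
#' evaluated with a log-rank test. Candidate cutpoints are the midpoints
#' between consecutive distinct order statistics such that both the low and
#' the high group contain at least `ceiling(min_fraction * n)` patients
#' (high = expression strictly greater than the cutpoint; values equal to
#' the cutpoint fall in the low group).
#'
#' @param expression Per-sample expression values for one gene, aligned with
#'   `time`/`event`.
#' @param time,event Survival outcome.
#' @param min_fraction Minimum fraction of patients on each side of a
#'   cutpoint (default 0.02).
#' @return Data frame with columns `cutpoint`, `n_low`, `n_high`, `p`;
#'   zero rows (with attribute `scannable = FALSE`) for constant expression.
#' @export
cutpoint_scan <- function(expression, time, event, min_fraction = 0.02) {
  n <- length(expression)
  if (length(time) != n || length(event) != n)
    stop("expression and survival vectors must align")
  if (min_fraction <= 0 || min_fraction > 0.5)
    stop("min_fraction must lie in (0, 0.5]")
  min_side <- ceiling(min_fraction * n)
  xs <- sort(expression)
  # cutpoint after position i splits low = i samples, high = n - i
  valid_i <- seq_len(n - 1)
  valid_i <- valid_i[valid_i >= min_side & (n - valid_i) >= min_side]
  valid_i <- valid_i[xs[valid_i] < xs[valid_i + 1]]  # distinct values only
  if (length(valid_i) == 0) {
    out <- data.frame(cutpoint = numeric(0), n_low = integer(0),
                      n_high = integer(0), p = numeric(0))
    attr(out, "scannable") <- FALSE
    return(out)
  }
  cuts <- (xs[valid_i] + xs[valid_i + 1]) / 2
  event <- as.integer(event)
  any_events <- sum(event) > 0
  p <- vapply(cuts, function(ct) {
    if (!any_events) return(1)
    st <- logrank_stat(time, event, expression > ct)
    if (st$v > 0)
      stats::pchisq(st$oe^2 / st$v, df = 1, lower.tail = FALSE) else 1
  }, numeric(1))
  out <- data.frame(cutpoint = cuts, n_low = valid_i, n_high = n - valid_i,
                    p = p)
  attr(out, "scannable") <- TRUE
  out
}

#' Scan all genes with joint genes-by-windows q-correction
#'
#' Runs [cutpoint_scan()] for every gene, pools ALL (gene, cutpoint)
#' p-values into a single q-value computation (pi0 = 1 by default, since
#' minimum-p selection invalidates smoother-based pi0 estimates on the
#' pooled set), and reports each gene's minimum q with the cutpoint
#' achieving it. Genes are returned ranked by `min_q`.
#'
#' @param data An [expression_dataset()] whose annotations carry `os_time`
#'   and `os_event`, or a matrix plus explicit `time`/`event`.
#' @param genes Optional subset of gene/rownames to scan (default: all).
#' @param min_fraction Minimum group fraction per side (default 0.02).
#' @param pi0 Null proportion for the pooled q-values (default 1).
#' @return List with `per_gene` (data frame: `gene`, `best_cutpoint`,
#'   `min_p`, `min_q`, `n_windows`, `scannable`) and `windows` (the pooled
#'   per-window table with q-values).
#' @export
scan_all_genes <- function(data, genes = NULL, min_fraction = 0.02,
                           pi0 = 1) {
  stopifnot(inherits(data, "expression_dataset"))
  ann <- data$sample_annotations
  if (!all(c("os_time", "os_event") %in% names(ann)))
    stop("annotations must contain os_time and os_event")
  mat <- data$matrix
  if (is.null(genes)) genes <- rownames(mat)
  missing <- setdiff(genes, rownames(mat))
  if (length(missing))
    stop("genes not in dataset: ", paste(utils::head(missing, 5),
                                         collapse = ", "))
  scans <- lapply(genes, function(gn)
    cutpoint_scan(mat[gn, ], ann$os_time, ann$os_event, min_fraction))
  n_win <- vapply(scans, nrow, integer(1))
  windows <- do.call(rbind, scans)
  if (is.null(windows) || nrow(windows) == 0) {
    per_gene <- data.frame(gene = genes, best_cutpoint = NA_real_,
                           min_p = NA_real_, min_q = NA_real_,
                           n_windows = 0L, scannable = FALSE)
    return(list(per_gene = per_gene,
                windows = data.frame(gene = character(0), cutpoint = numeric(0),
                                     p = numeric(0), q = numeric(0))))
  }
  windows$gene <- rep(genes, n_win)
  windows$q <- compute_qvalues(windows$p, pi0 = pi0)
  per_gene <- do.call(rbind, lapply(seq_along(genes), function(i) {
    w <- windows[windows$gene == genes[i], , drop = FALSE]
    if (nrow(w) == 0)
      return(data.frame(gene = genes[i], best_cutpoint = NA_real_,
                        min_p = NA_real_, min_q = NA_real_, n_windows = 0L,
                        scannable = FALSE))
    best <- which.min(w$q)
    data.frame(gene = genes[i], best_cutpoint = w$cutpoint[best],
               min_p = min(w$p), min_q = w$q[best], n_windows = nrow(w),
               scannable = TRUE)
  }))
  per_gene <- per_gene[order(per_gene$min_q, per_gene$gene), , drop = FALSE]
  rownames(per_gene) <- NULL
  list(per_gene = per_gene,
       windows = windows[, c("gene", "cutpoint", "n_low", "n_high", "p", "q")])
}

#' Cox proportional-hazards fit for one gene's expression
#'
#' Univariate mode regresses overall survival on the expression values;
#' multivariate mode additionally adjusts for MYCN status (binary), INSS
#' stage (unordered categorical, stage 1 reference — 4S is not ordinally
#' above 4), and age at diagnosis (continuous). Ties use the Efron
#' approximation; convergence tolerance 1e-9, at most 100 iterations.
#'
#' @param expression Per-sample expression values.
#' @param ann Data frame with `os_time`, `os_event`, and (for the
#'   multivariate model) `mycn`, `stage`, `age`.
#' @param covariates `"none"` for univariate or `"clinical"` for the
#'   MYCN + stage + age adjusted model.
#' @param min_events Minimum number of events required (default 10).
#' @return List with `hazard_ratio` (per expression unit), `log_hr`, `se`,
#'   `p`, `ci` (Wald 95%), `converged`, `flag`, and the covariate
#'   coefficient table in multivariate mode.
#' @export
cox_fit <- function(expression, ann, covariates = c("none", "clinical"),
                    min_events = 10) {
  covariates <- match.arg(covariates)
  if (!all(c("os_time", "os_event") %in% names(ann)))
    stop("annotations must contain os_time and os_event")
  if (sum(ann$os_event) < min_events)
    stop("fewer than ", min_events, " events")
  df <- data.frame(os_time = ann$os_time, os_event = ann$os_event,
                   expr = expression)
  form <- survival::Surv(os_time, os_event) ~ expr
  if (covariates == "clinical") {
    if (!all(c("mycn", "stage", "age") %in% names(ann)))
      stop("multivariate model needs mycn, stage, age")
    df$mycn <- as.numeric(ann$mycn)
    df$stage <- stats::relevel(factor(as.character(ann$stage)), ref = "1")
    df$age <- as.numeric(ann$age)
    form <- survival::Surv(os_time, os_event) ~ expr + mycn + stage + age
    # non-identifiable designs (e.g. expression collinear with MYCN) are
    # flagged, not silently dropped
    X <- stats::model.matrix(~ expr + mycn + stage + age, df)
    if (qr(X)$rank < ncol(X))
      return(list(hazard_ratio = NA_real_, log_hr = NA_real_, se = NA_real_,
                  p = NA_real_, ci = c(NA_real_, NA_real_), converged = FALSE,
                  flag = "non_identifiable", covariate_table = NULL))
  }
  fit <- tryCatch(
    survival::coxph(form, data = df, ties = "efron",
                    control = survival::coxph.control(eps = 1e-9,
                                                      iter.max = 100)),
    error = function(e) NULL)
  if (is.null(fit) || anyNA(stats::coef(fit)["expr"]))
    return(list(hazard_ratio = NA_real_, log_hr = NA_real_, se = NA_real_,
                p = NA_real_, ci = c(NA_real_, NA_real_), converged = FALSE,
                flag = "failed", covariate_table = NULL))
  sm <- summary(fit)
  beta <- stats::coef(fit)[["expr"]]
  se <- sm$coefficients["expr", "se(coef)"]
  flag <- "ok"
  if (!is.null(fit$info) && isTRUE(fit$info > 0)) flag <- "warned"
  inf <- tryCatch(any(abs(beta / se) > 50), error = function(e) TRUE)
  if (isTRUE(inf)) flag <- "possible_separation"
  list(hazard_ratio = exp(beta), log_hr = beta, se = se,
       p = sm$coefficients["expr", "Pr(>|z|)"],
       ci = exp(beta + c(-1, 1) * stats::qnorm(0.975) * se),
       converged = TRUE, flag = flag,
       covariate_table = if (covariates == "clinical")
         sm$coefficients else NULL)
}

#' Cox fits across genes with q-values
#'
#' Fits [cox_fit()] for each gene in both univariate and clinical-adjusted
#' multivariate mode and computes q-values per model across the converged
#' fits (non-converged fits are excluded from the q computation and
#' reported with their flag).
#'
#' @param data An [expression_dataset()] with survival annotations.
#' @param genes Genes to fit (default all rows).
#' @param min_events Passed to [cox_fit()].
#' @return Data frame with `gene`, `hr_uni`, `p_uni`, `q_uni`, `hr_multi`,
#'   `p_multi`, `q_multi`, `flag_uni`, `flag_multi`.
#' @export
cox_scan <- function(data, genes = NULL, min_events = 10) {
  stopifnot(inherits(data, "expression_dataset"))
  ann <- data$sample_annotations
  if (is.null(genes)) genes <- rownames(data$matrix)
  fit1 <- lapply(genes, function(gn)
    cox_fit(data$matrix[gn, ], ann, "none", min_events))
  fit2 <- lapply(genes, function(gn)
    cox_fit(data$matrix[gn, ], ann, "clinical", min_events))
  out <- data.frame(
    gene = genes,
    hr_uni = vapply(fit1, `[[`, numeric(1), "hazard_ratio"),
    p_uni = vapply(fit1, `[[`, numeric(1), "p"),
    hr_multi = vapply(fit2, `[[`, numeric(1), "hazard_ratio"),
    p_multi = vapply(fit2, `[[`, numeric(1), "p"),
    flag_uni = vapply(fit1, `[[`, character(1), "flag"),
    flag_multi = vapply(fit2, `[[`, character(1), "flag"),
    stringsAsFactors = FALSE)
  for (side in c("uni", "multi")) {
    pcol <- paste0("p_", side); qcol <- paste0("q_", side)
    ok <- !is.na(out[[pcol]])
    if (sum(!ok) > 0)
      message(sum(!ok), " non-converged ", side,
              "variate fit(s) excluded from q computation")
    out[[qcol]] <- NA_real_
    if (any(ok)) out[[qcol]][ok] <- compute_qvalues(out[[pcol]][ok])
  }
  out[, c("gene", "hr_uni", "p_uni", "q_uni", "hr_multi", "p_multi",
          "q_multi", "flag_uni", "flag_multi")]
}

#' Permutation test linking differential expression to prognosis
#'
#' Draws, in each replicate, a fixed number of genes without replacement
#' from each cohort's DEG list and counts how many of the drawn genes are
#' prognostic (survival-scan FDR below the threshold) in BOTH cohorts. One
#' upper-tail p-value is reported per cohort's draw, against that cohort's
#' observed count, using the plain count / n rule (bias-guarded companion
#' estimate included).
#'
#' @param deg_genes List of two character vectors: each cohort's DEG list.
#' @param prognostic_genes List of two character vectors: genes prognostic
#'   in each cohort (e.g. scan min_q < 0.01).
#' @param draw_sizes Integer vector of length 2 (how many genes to draw from
#'   each cohort's DEG list; the study draws 8 and 9).
#' @param observed Integer vector of length 2: observed
#'   prognostic-in-both-cohorts counts for the two draws.
#' @param n_permutations Replicates (default 100000).
#' @param seed RNG seed.
#' @return List of two `permutation_result` objects (one per cohort draw).
#' @export
deg_survival_permutation <- function(deg_genes, prognostic_genes,
                                     draw_sizes = c(8, 9), observed,
                                     n_permutations = 100000, seed = 1L) {
  if (length(deg_genes) != 2 || length(prognostic_genes) != 2)
    stop("two cohorts are required")
  if (any(draw_sizes > lengths(deg_genes)))
    stop("draw size exceeds the DEG list size")
  if (length(observed) != 2) stop("one observed count per cohort draw")
  prog_both <- intersect(prognostic_genes[[1]], prognostic_genes[[2]])
  set.seed(seed)
  res <- lapply(1:2, function(ci) {
    is_prog <- deg_genes[[ci]] %in% prog_both
    m <- length(is_prog)
    k <- draw_sizes[ci]
    counts <- vapply(seq_len(n_permutations), function(r)
      sum(is_prog[sample.int(m, k)]), integer(1))
    n_extreme <- sum(counts >= observed[ci])
    structure(list(observed = observed[ci], n_permutations = n_permutations,
                   n_as_extreme = n_extreme, p = n_extreme / n_permutations,
                   p_bias_guarded = (n_extreme + 1) / (n_permutations + 1),
                   seed = seed, null_distribution = table(counts)),
              class = "permutation_result")
  })
  names(res) <- c("cohort1_draw", "cohort2_draw")
  res
}
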