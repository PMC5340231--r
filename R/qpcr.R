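#' Relative quantification of one gene by the 2^-ddCt rule
#'
#' Per condition, the delta-Ct is the mean over replicates of
#' (Ct_gene - Ct_reference), pairing each gene replicate with the reference
#' replicate of the same index (same plate run). The delta-delta-Ct is
#' delta-Ct(treated) - delta-Ct(control); the fold change is
#' 2^(-delta-delta-Ct) and the log2 fold is its negation.
#'
#' @param ct_table Data frame with columns `gene`, `condition`, `replicate`,
#'   `ct` (as written by [simulate_qpcr_plate()]).
#' @param gene Target gene.
#' @param reference_gene Housekeeping reference (must be measured in every
#'   condition/replicate block in which the target is measured).
#' @param treated,control Condition labels (defaults "hypoxia"/"normoxia").
#' @return List with `gene`, `delta_ct` (named per condition),
#'   `delta_delta_ct`, `fold_change`, `log2_fold`, and the per-replicate
#'   delta-Ct values used.
#' @examples
#' ct <- data.frame(gene = rep(c("HK2", "ACTB"), each = 4),
#'                  condition = rep(c("hypoxia", "hypoxia",
#'                                    "normoxia", "normoxia"), 2),
#'                  replicate = rep(1:2, 4),
#'                  ct = c(20, 20, 24, 24, 15, 15, 15, 15))
#' delta_delta_ct(ct, "HK2", "ACTB")$fold_change  # 16
#' @export
delta_delta_ct <- function(ct_table, gene, reference_gene,
                           treated = "hypoxia", control = "normoxia") {
  need <- c("gene", "condition", "replicate", "ct")
  if (!all(need %in% names(ct_table)))
    stop("ct_table must have columns ", paste(need, collapse = ", "))
  tgt <- ct_table[ct_table$gene == gene, ]
  ref <- ct_table[ct_table$gene == reference_gene, ]
  if (nrow(tgt) == 0) stop("no measurements for gene ", gene)
  if (nrow(ref) == 0) stop("no measurements for reference ", reference_gene)
  dct <- list()
  for (cond in c(control, treated)) {
    tc <- tgt[tgt$condition == cond, ]
    rc <- ref[ref$condition == cond, ]
    if (nrow(tc) == 0) stop("no measurements for condition ", cond)
    m <- match(tc$replicate, rc$replicate)
    if (anyNA(m)) {
      miss <- tc$replicate[is.na(m)][1]
      stop("reference gene missing for (", cond, ", replicate ", miss, ")")
    }
    dct[[cond]] <- tc$ct - rc$ct[m]
  }
  dmean <- vapply(dct, mean, numeric(1))
  ddct <- dmean[[treated]] - dmean[[control]]
  list(gene = gene,
       delta_ct = dmean,
       delta_delta_ct = ddct,
       fold_change = 2^(-ddct),
       log2_fold = -ddct,
       replicate_delta_ct = dct)
}

#' Replicate-level significance of a qPCR fold change
#'
#' Welch two-sample t-test on the per-replicate delta-Ct values between
#' conditions. When both conditions have zero variance and equal means the
#' p-value is 1 (a guarded degenerate case rather than an error).
#'
#' @param replicate_delta_ct Named list of per-replicate delta-Ct vectors
#'   (one per condition), as returned by [delta_delta_ct()].
#' @param treated,control Condition labels.
#' @param alpha Significance level for the `significant_up` call.
#' @return List with `p` and `significant_up` (TRUE iff p < alpha and the
#'   log2 fold change is positive).
#' @export
replicate_significance <- function(replicate_delta_ct,
                                   treated = "hypoxia",
                                   control = "normoxia", alpha = 0.05) {
  a <- replicate_delta_ct[[treated]]
  b <- replicate_delta_ct[[control]]
  if (length(a) < 2 || length(b) < 2)
    stop("at least 2 replicates per condition are required")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    p <- if (mean(a) == mean(b)) 1 else 0
  } else {
    p <- tryCatch(stats::t.test(a, b)$p.value, error = function(e) 1)
  }
  log2_fold <- -(mean(a) - mean(b))
  list(p = p, significant_up = p < alpha && log2_fold > 0)
}

#' Quantify every gene on a qPCR plate
#'
#' Applies [delta_delta_ct()] and [replicate_significance()] to each
#' non-reference gene.
#'
#' @inheritParams delta_delta_ct
#' @param alpha Significance level.
#' @return Data frame with columns `gene`, `delta_delta_ct`, `fold_change`,
#'   `log2_fold`, `p`, `significant_up`.
#' @export
quantify_qpcr <- function(ct_table, reference_gene,
                          treated = "hypoxia", control = "normoxia",
                          alpha = 0.05) {
  genes <- setdiff(unique(ct_table$gene), reference_gene)
  if (!reference_gene %in% ct_table$gene)
    stop("reference gene ", reference_gene, " not on the plate")
  rows <- lapply(genes, function(gn) {
    rel <- delta_delta_ct(ct_table, gn, reference_gene, treated, control)
    sig <- replicate_significance(rel$replicate_delta_ct, treated, control,
                                  alpha)
    data.frame(gene = gn, delta_delta_ct = rel$delta_delta_ct,
               fold_change = rel$fold_change, log2_fold = rel$log2_fold,
               p = sig$p, significant_up = sig$significant_up,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
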