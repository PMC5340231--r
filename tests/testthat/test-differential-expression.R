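test_that("survivor model matches closed-form OLS on a constructed design", {
  set.seed(10)
  n <- 100
  status <- rep(c("survivor", "deceased"), each = n / 2)
  mycn <- rbinom(n, 1, 0.3)
  x_status <- as.numeric(status == "deceased")
  y <- 1.0 * x_status + rnorm(n, 0, 0.1)
  mat <- rbind(gA = y, gB = rnorm(n, 5, 1))
  colnames(mat) <- sprintf("S%03d", 1:n)
  ds <- expression_dataset(mat, data.frame(sample_id = colnames(mat),
                                           status = status, mycn = mycn))
  fit <- fit_survivor_model(ds)

  # oracle: closed-form OLS on the same design matrix
  X <- cbind(1, x_status, mycn)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% beta
  s2 <- sum(res^2) / (n - 3)
  se <- sqrt(s2 * solve(t(X) %*% X)[2, 2])
  p_hand <- 2 * pt(-abs(beta[2] / se), n - 3)

  expect_equal(fit$log2fc[fit$feature == "gA"], beta[2], tolerance = 1e-10)
  expect_equal(fit$p[fit$feature == "gA"], p_hand, tolerance = 1e-10)
  expect_lt(abs(fit$log2fc[fit$feature == "gA"] - 1.0), 0.1)
})

test_that("MYCN adjustment removes a confounded MYCN-only effect", {
  set.seed(11)
  n <- 200
  status <- rep(c("survivor", "deceased"), each = n / 2)
  # MYCN correlated ~0.5 with status, drives expression; status effect is 0
  mycn <- ifelse(status == "deceased", rbinom(n, 1, 0.75), rbinom(n, 1, 0.25))
  y <- 2 * mycn + rnorm(n, 0, 0.5)
  mat <- rbind(g1 = y)
  colnames(mat) <- sprintf("S%03d", 1:n)
  ds <- expression_dataset(mat, data.frame(sample_id = colnames(mat),
                                           status = status, mycn = mycn))
  fit <- fit_survivor_model(ds)
  X <- cbind(1, as.numeric(status == "deceased"), mycn)
  se <- sqrt(sum(lm.fit(X, y)$residuals^2) / (n - 3) *
               solve(t(X) %*% X)[2, 2])
  expect_lt(abs(fit$log2fc[1]), 3 * se)
  # without adjustment the naive group difference is far from zero
  naive <- mean(y[status == "deceased"]) - mean(y[status == "survivor"])
  expect_gt(abs(naive), 3 * se)
})

test_that("degenerate and confounded designs are flagged, not fatal", {
  ds <- make_cohort_fixture(n_per_group = 10, n_genes = 3, seed = 1)
  ds$matrix[1, ] <- 7.5  # constant feature
  fit <- fit_survivor_model(ds)
  expect_equal(fit$log2fc[1], 0)
  expect_equal(fit$p[1], 1)
  expect_true(fit$degenerate[1])

  # status perfectly confounded with MYCN: MYCN dropped with a warning
  conf <- make_cohort_fixture(n_per_group = 10, n_genes = 3, seed = 2,
                              mycn = rep(c(0, 1), each = 10))
  expect_warning(fit2 <- fit_survivor_model(conf), "confounded")
  expect_true(all(fit2$confounded))

  # a status level with < 2 samples errors naming the level
  tiny <- make_cohort_fixture(n_per_group = 10, n_genes = 3, seed = 3)
  tiny$sample_annotations$status <- c("deceased", rep("survivor", 19))
  expect_error(fit_survivor_model(tiny), "deceased")
})

test_that("single-line hypoxia design falls back to two-group OLS", {
  sim <- simulate_cellline_experiment(
    cellline_sim_config(n_lines = 1, n_replicates_per_condition = 4,
                        n_genes = 20, n_hypoxia_responsive = 5,
                        hypoxia_effect = 1.5, line_sd = 0, noise_sd = 0.3,
                        seed = 6))
  expect_warning(fit <- fit_hypoxia_model(sim$dataset), "single cell line")
  expect_true(all(fit$fallback))
  ann <- sim$dataset$sample_annotations
  hyp <- ann$condition == "hypoxia"
  d <- rowMeans(sim$dataset$matrix[, hyp]) -
    rowMeans(sim$dataset$matrix[, !hyp])
  expect_equal(fit$log2fc, unname(d), tolerance = 1e-10)
})

test_that("mixed model recovers the planted hypoxia effect across lines", {
  sim <- simulate_cellline_experiment(
    cellline_sim_config(n_lines = 6, n_replicates_per_condition = 2,
                        n_genes = 30, n_hypoxia_responsive = 10,
                        hypoxia_effect = 2.0, line_sd = 1.0, noise_sd = 0.4,
                        seed = 14))
  fit <- fit_hypoxia_model(sim$dataset)
  est <- fit$log2fc[fit$feature %in% sim$truth$responsive_genes]
  # oracle: per-line paired differences averaged across lines
  ann <- sim$dataset$sample_annotations
  hand <- vapply(sim$truth$responsive_genes, function(gn) {
    y <- sim$dataset$matrix[gn, ]
    mean(vapply(unique(ann$line), function(l) {
      mean(y[ann$line == l & ann$condition == "hypoxia"]) -
        mean(y[ann$line == l & ann$condition == "normoxia"])
    }, numeric(1)))
  }, numeric(1))
  expect_equal(est, unname(hand), tolerance = 1e-6)
  expect_lt(abs(mean(est) - 2.0), 0.15)
})

test_that("probe collapse keeps the most significant probe with deterministic ties", {
  tab <- data.frame(
    feature = c("pr1", "pr2", "pr3", "pr4", "pr5"),
    log2fc = c(1, -2, 0.5, 0.5, -0.5),
    p = c(0.01, 0.001, 0.2, 0.2, 0.2),
    stringsAsFactors = FALSE)
  fmap <- data.frame(probe_id = c("pr1", "pr2", "pr3", "pr4", "pr5"),
                     gene_symbol = c("A", "A", "B", "B", "C"),
                     stringsAsFactors = FALSE)
  out <- collapse_probes(tab, fmap)
  # gene A: smaller p wins, carrying its fold change
  expect_equal(out$p[out$gene == "A"], 0.001)
  expect_equal(out$log2fc[out$gene == "A"], -2)
  expect_equal(out$source_probe[out$gene == "A"], "pr2")
  # gene B: equal p and equal |fc| -> lexicographically smallest probe
  expect_equal(out$source_probe[out$gene == "B"], "pr3")
  expect_equal(nrow(out), 3)

  # one probe per gene: identity
  one <- collapse_probes(tab, data.frame(probe_id = tab$feature,
                                         gene_symbol = paste0("G", 1:5)))
  expect_equal(one$p, tab$p)
  # unmapped probes dropped with a message; empty map errors
  expect_message(collapse_probes(tab, fmap[1:3, ]), "unmapped")
  expect_error(collapse_probes(tab, fmap[0, ]), "empty")
})

test_that("dual DEG criterion applies FDR and fold-change decile jointly", {
  set.seed(20)
  n <- 100
  tab <- data.frame(gene = sprintf("G%03d", 1:n),
                    log2fc = rnorm(n),
                    q = runif(n, 0.02, 1))
  sig <- sample(n, 20)
  tab$q[sig] <- runif(20, 0, 0.009)
  # oracle: brute-force double filter over the rows
  hi <- quantile(tab$log2fc, 0.9, names = FALSE)
  lo <- quantile(tab$log2fc, 0.1, names = FALSE)
  expected <- tab$gene[tab$q < 0.01 & (tab$log2fc >= hi | tab$log2fc <= lo)]
  out <- select_degs(tab, fdr_max = 0.01, fc_decile = 0.10)
  expect_setequal(out$records$gene, expected)
  expect_equal(out$universe_size, n)
  expect_true(all(out$records$direction ==
                    ifelse(out$records$log2fc < 0, "down", "up")))

  # invariant to row order
  out2 <- select_degs(tab[sample(n), ], fdr_max = 0.01, fc_decile = 0.10)
  expect_equal(out$records$gene, out2$records$gene)

  # all q above threshold: empty selection
  tab$q <- pmax(tab$q, 0.02)
  expect_equal(nrow(select_degs(tab)$records), 0)

  expect_error(select_degs(tab, fc_decile = 0.6), "fc_decile")
})

test_that("significant-scope decile restricts the fold-change pool", {
  tab <- data.frame(gene = paste0("G", 1:10),
                    log2fc = c(5, 4, 3, 2, 1, -1, -2, -3, -4, -5),
                    q = c(rep(0.001, 4), rep(0.5, 6)))
  uni <- select_degs(tab, fdr_max = 0.01, fc_decile = 0.25,
                     fc_decile_scope = "universe")
  sig <- select_degs(tab, fdr_max = 0.01, fc_decile = 0.25,
                     fc_decile_scope = "significant")
  # universe scope: 75th percentile of all ten fold changes is 3.25, the
  # 25th is -3.25; only significant genes in those tails qualify
  expect_setequal(uni$records$gene, c("G1", "G2", "G3"))
  # significant scope: decile over the four significant fold changes only
  expect_setequal(sig$records$gene, c("G1", "G4"))
})

test_that("external DEG tables round-trip and q is computed only when absent", {
  dir <- withr::local_tempdir()
  recs <- data.frame(gene = c("A", "B", "C"), log2fc = c(2, -1, 0.5),
                     p = c(0.001, 0.5, 1.0), q = c(0.003, 0.75, 1.0),
                     direction = c("up", "down", "up"),
                     stringsAsFactors = FALSE)
  tab <- deg_table(recs, universe_size = 50, dataset_id = "ext")
  path <- file.path(dir, "deg.tsv")
  write_deg_table(tab, path)
  back <- ingest_external_deg_table(path)
  expect_equal(back$records$gene, recs$gene)
  expect_equal(back$records$q, recs$q)  # q used verbatim
  expect_equal(back$universe_size, 50)
  expect_equal(back$dataset_id, "ext")

  # without a q column, q is computed from p
  write.table(recs[, c("gene", "log2fc", "p")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  unlink(paste0(path, ".json"))
  back2 <- ingest_external_deg_table(path)
  expect_equal(back2$records$q, compute_qvalues(recs$p))

  # missing mandatory columns are named
  write.table(recs[, "gene", drop = FALSE], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(ingest_external_deg_table(path), "log2fc")

  # column mapping
  alt <- recs[, c("gene", "log2fc", "p")]
  names(alt) <- c("gene_id", "lfc", "pval")
  write.table(alt, path, sep = "\t", quote = FALSE, row.names = FALSE)
  back3 <- ingest_external_deg_table(path, column_map = list(
    gene = "gene_id", log2fc = "lfc", p = "pval"))
  expect_equal(back3$records$gene, recs$gene)
})
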