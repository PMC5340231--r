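test_that("log-rank statistic matches hand computation on tiny fixtures", {
  fixtures <- list(
    list(time = c(1, 2, 3, 4), event = c(1, 1, 1, 1), group = c(1, 1, 2, 2)),
    list(time = c(1, 1, 2, 3), event = c(1, 0, 1, 1), group = c(1, 2, 1, 2)),
    list(time = c(2, 2, 2, 5, 6), event = c(1, 1, 0, 1, 0),
         group = c(1, 2, 1, 2, 2)),
    list(time = c(1, 2, 3, 4, 5, 6), event = c(1, 1, 1, 0, 1, 0),
         group = c(1, 1, 1, 2, 2, 2)),
    list(time = c(3, 3, 3, 3), event = c(1, 1, 1, 1), group = c(1, 2, 1, 2)))
  for (fx in fixtures) {
    got <- logrank_test(fx$time, fx$event, fx$group)
    hand <- logrank_by_hand(fx$time, fx$event, fx$group)
    expect_equal(got$statistic, hand$statistic, tolerance = 1e-12)
    expect_equal(got$p, hand$p, tolerance = 1e-12)
    # independent implementation: survival::survdiff
    if (got$statistic > 0) {
      sd <- survival::survdiff(
        survival::Surv(fx$time, fx$event) ~ fx$group)
      expect_equal(got$statistic, unname(sd$chisq), tolerance = 1e-9)
    }
  }
  # frozen value for the two-vs-two fixture: O-E = -7/6, V = 17/36
  got <- logrank_test(c(1, 2, 3, 4), c(1, 1, 1, 1), c(1, 1, 2, 2))
  expect_equal(got$statistic, (7 / 6)^2 / (17 / 36), tolerance = 1e-12)
})

test_that("log-rank is symmetric in group order and time-rescale invariant", {
  set.seed(30)
  tm <- rexp(40); ev <- rbinom(40, 1, 0.6); gr <- rep(1:2, 20)
  a <- logrank_test(tm, ev, gr)
  b <- logrank_test(tm, ev, 3 - gr)
  expect_equal(a$statistic, b$statistic, tolerance = 1e-12)
  c2 <- logrank_test(17.3 * tm, ev, gr)
  expect_equal(a$statistic, c2$statistic, tolerance = 1e-12)
})

test_that("log-rank degenerate inputs follow the contract", {
  expect_warning(res <- logrank_test(c(1, 2, 3, 4), c(0, 0, 0, 0),
                                     c(1, 1, 2, 2)), "no events")
  expect_equal(res$p, 1)
  expect_error(logrank_test(c(1, 2), c(1, 1), c(1, 1)), "group")
  # identical groups: statistic 0, p 1
  tm <- c(1, 2, 3, 1, 2, 3); ev <- c(1, 1, 0, 1, 1, 0)
  res2 <- logrank_test(tm, ev, rep(1:2, each = 3))
  expect_equal(res2$statistic, 0, tolerance = 1e-12)
  expect_equal(res2$p, 1)
})

test_that("cutpoint scan enumerates exactly the admissible windows", {
  set.seed(31)
  x <- rnorm(100)  # distinct values almost surely
  tm <- rexp(100); ev <- rbinom(100, 1, 0.5)
  scan <- cutpoint_scan(x, tm, ev, min_fraction = 0.02)
  # oracle: splits 2 vs 98 through 98 vs 2 on distinct order statistics
  expect_equal(nrow(scan), 97)
  expect_true(all(scan$n_low >= 2 & scan$n_high >= 2))
  expect_equal(scan$n_low + scan$n_high, rep(100, 97))

  # constant expression: not scannable
  flat <- cutpoint_scan(rep(1, 50), tm[1:50], ev[1:50])
  expect_equal(nrow(flat), 0)
  expect_false(attr(flat, "scannable"))

  # monotone-transform invariance of cut p-values
  scan2 <- cutpoint_scan(exp(x), tm, ev, min_fraction = 0.02)
  expect_equal(scan$p, scan2$p, tolerance = 1e-12)
})

test_that("minimum p over windows is anti-conservative under the null", {
  set.seed(32)
  n <- 80
  hits <- vapply(1:40, function(i) {
    x <- rnorm(n); tm <- rexp(n); ev <- rbinom(n, 1, 0.6)
    min(cutpoint_scan(x, tm, ev, 0.05)$p) < 0.05
  }, logical(1))
  # the per-gene minimum p rejects far more often than alpha = 5%
  expect_gt(mean(hits), 0.3)
})

test_that("pooled genes-by-windows q-correction reports per-gene minima", {
  sim <- simulate_patient_cohort(
    cohort_sim_config(n_patients = 80, n_genes = 12, n_prognostic = 3,
                      n_mycn_genes = 2, seed = 33))
  scan <- scan_all_genes(sim$dataset, min_fraction = 0.05)
  expect_setequal(scan$per_gene$gene, rownames(sim$dataset$matrix))
  # min_q is the minimum q over the gene's windows
  for (gn in scan$per_gene$gene[1:4]) {
    w <- scan$windows[scan$windows$gene == gn, ]
    expect_equal(scan$per_gene$min_q[scan$per_gene$gene == gn], min(w$q))
  }
  # pooled q at fixed p is never smaller than a per-gene-alone q (more tests)
  one <- scan_all_genes(sim$dataset, genes = scan$per_gene$gene[1],
                        min_fraction = 0.05)
  g1 <- scan$per_gene$gene[1]
  expect_gte(scan$per_gene$min_q[scan$per_gene$gene == g1],
             one$per_gene$min_q[one$per_gene$gene == g1] - 1e-12)
  # single gene, single cutpoint reduces to the BH-adjusted single p
  x <- as.numeric(1:10)
  ds <- expression_dataset(
    matrix(x, 1, 10, dimnames = list("gX", paste0("s", 1:10))),
    data.frame(sample_id = paste0("s", 1:10),
               os_time = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10),
               os_event = rep(1, 10)))
  sc1 <- scan_all_genes(ds, min_fraction = 0.45)
  expect_equal(sc1$per_gene$n_windows, 1)
  expect_equal(sc1$per_gene$min_q, sc1$windows$p[1])
})

test_that("scan errors on unmatched genes and handles no-window datasets", {
  sim <- simulate_patient_cohort(
    cohort_sim_config(n_patients = 30, n_genes = 5, n_prognostic = 1,
                      n_mycn_genes = 1, seed = 34))
  expect_error(scan_all_genes(sim$dataset, genes = c("g0001", "nope")),
               "nope")
})

test_that("Cox fit recovers a known hazard ratio and flags degenerate designs", {
  set.seed(35)
  n <- 300
  x <- rnorm(n)
  tm <- rexp(n, 0.05 * exp(0.7 * x))
  cens <- runif(n, 0, quantile(tm, 0.9) * 2)
  ann <- data.frame(os_time = pmin(tm, cens),
                    os_event = as.integer(tm <= cens))
  fit <- cox_fit(x, ann, "none")
  expect_true(fit$converged)
  expect_true(fit$ci[1] < exp(0.7) && exp(0.7) < fit$ci[2])
  # against the survival package called directly
  ref <- survival::coxph(survival::Surv(ann$os_time, ann$os_event) ~ x,
                         ties = "efron")
  expect_equal(fit$log_hr, unname(coef(ref)), tolerance = 1e-6)

  # expression collinear with MYCN in multivariate mode: flagged
  ann$mycn <- as.integer(x > 0)
  ann$stage <- sample(c("1", "2", "3", "4", "4S"), n, replace = TRUE)
  ann$age <- runif(n, 0, 60)
  collinear <- cox_fit(as.numeric(ann$mycn), ann, "clinical")
  expect_false(collinear$converged)
  expect_equal(collinear$flag, "non_identifiable")

  # too few events
  ann2 <- ann; ann2$os_event <- c(1, rep(0, n - 1))
  expect_error(cox_fit(x, ann2, "none"), "events")
})

test_that("multivariate Cox adjusts for MYCN, stage, and age", {
  sim <- simulate_patient_cohort(
    cohort_sim_config(n_patients = 250, n_genes = 10, n_prognostic = 2,
                      n_mycn_genes = 2, seed = 36))
  ann <- sim$dataset$sample_annotations
  fit <- cox_fit(sim$dataset$matrix["g0001", ], ann, "clinical")
  expect_true(fit$converged)
  expect_true(all(c("mycn", "age") %in% rownames(fit$covariate_table)))
  expect_true(any(grepl("stage", rownames(fit$covariate_table))))
  # stage is categorical with 4 non-reference levels
  expect_equal(sum(grepl("^stage", rownames(fit$covariate_table))), 4)
})

test_that("cox_scan computes per-model q-values over converged fits", {
  sim <- simulate_patient_cohort(
    cohort_sim_config(n_patients = 150, n_genes = 8, n_prognostic = 2,
                      n_mycn_genes = 2, seed = 37))
  res <- cox_scan(sim$dataset)
  expect_equal(nrow(res), 8)
  ok <- !is.na(res$p_uni)
  expect_equal(res$q_uni[ok], compute_qvalues(res$p_uni[ok]))
  expect_true(all(res$hr_uni[ok] > 0))
})

test_that("DEG-prognosis permutation converges to the hypergeometric tail", {
  # single-cohort reduction: 10 DEGs, 5 prognostic in both cohorts, draw 3,
  # observed 3 -> p = C(5,3)/C(10,3) = 1/12
  degs <- list(paste0("a", 1:10), paste0("a", 1:10))
  prog <- list(paste0("a", 1:5), paste0("a", 1:5))
  res <- deg_survival_permutation(degs, prog, draw_sizes = c(3, 3),
                                  observed = c(3, 3),
                                  n_permutations = 40000, seed = 41)
  exact <- choose(5, 3) / choose(10, 3)
  mc_se <- sqrt(exact * (1 - exact) / 40000)
  expect_lt(abs(res$cohort1_draw$p - exact), 3 * mc_se)
  expect_lt(abs(res$cohort2_draw$p - exact), 3 * mc_se)

  # observed 0 -> p = 1; all DEGs prognostic -> p = 1 at full draw
  res0 <- deg_survival_permutation(degs, prog, draw_sizes = c(2, 2),
                                   observed = c(0, 0),
                                   n_permutations = 100, seed = 1)
  expect_equal(res0$cohort1_draw$p, 1)
  all_prog <- list(paste0("a", 1:10), paste0("a", 1:10))
  res1 <- deg_survival_permutation(degs, all_prog, draw_sizes = c(4, 4),
                                   observed = c(4, 4),
                                   n_permutations = 100, seed = 1)
  expect_equal(res1$cohort1_draw$p, 1)

  expect_error(deg_survival_permutation(degs, prog, draw_sizes = c(11, 3),
                                        observed = c(1, 1)), "draw size")
})
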