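make_sig <- function(id, genes, dirs, universe) {
  signature_set(data.frame(gene = genes, direction = dirs,
                           stringsAsFactors = FALSE),
                universe = universe, dataset_id = id)
}

test_that("signature intersection counts shared and direction-consistent genes", {
  uni <- paste0("G", 1:20)
  s1 <- make_sig("d1", c("A1", "B1", "C1"), c("up", "up", "down"),
                 c(uni, "A1", "B1", "C1"))
  s2 <- make_sig("d2", c("B1", "C1", "D1"), c("down", "down", "up"),
                 c(uni, "A1", "B1", "C1", "D1"))
  ov <- intersect_signatures(list(s1, s2))
  expect_setequal(ov$shared_genes, c("B1", "C1"))
  expect_equal(ov$n_shared, 2)
  expect_equal(ov$consistent_genes, "C1")
  expect_equal(ov$n_direction_consistent, 1)

  # idempotent and order-invariant
  ov2 <- intersect_signatures(list(s2, s1))
  expect_equal(ov2$n_shared, ov$n_shared)
  expect_setequal(ov2$consistent_genes, ov$consistent_genes)
  same <- intersect_signatures(list(s1, s1))
  expect_equal(same$n_shared, 3)
  expect_equal(same$n_direction_consistent, 3)

  # empty signature warns and yields an empty intersection
  s0 <- make_sig("d0", character(0), character(0), uni)
  expect_warning(ov0 <- intersect_signatures(list(s1, s0)), "empty")
  expect_equal(ov0$n_shared, 0)
})

test_that("four-way intersection reproduces a 14-shared / 9-consistent pattern", {
  # fixture built to the candidate-gene pattern: 14 genes shared by all four
  # datasets, 9 of them agreeing in direction everywhere
  uni <- paste0("G", 1:200)
  shared <- paste0("S", 1:14)
  consistent <- shared[1:9]
  sets <- lapply(1:4, function(i) {
    extra <- paste0("X", i, "_", 1:10)
    dirs <- ifelse(shared %in% consistent, "up",
                   ifelse(rep(i, 14) %% 2 == 0, "down", "up"))
    make_sig(paste0("d", i), c(shared, extra),
             c(dirs, rep("up", 10)), c(uni, shared, extra))
  })
  ov <- intersect_signatures(sets)
  expect_equal(ov$n_shared, 14)
  expect_equal(ov$n_direction_consistent, 9)
  expect_setequal(ov$consistent_genes, consistent)
})

test_that("exact overlap p-values match enumeration", {
  # sum_{j>=3} C(5,j) C(15,5-j) / C(20,5) = 1126/15504
  expect_equal(exact_overlap_pvalue(20, 5, 5, 3), 1126 / 15504)
  expect_equal(exact_overlap_pvalue(4, 2, 2, 2), 1 / 6)
  expect_equal(exact_overlap_pvalue(50, 10, 4, 0), 1)
  expect_warning(p <- exact_overlap_pvalue(10, 3, 4, 5), "exceeds")
  expect_equal(p, 0)
  expect_error(exact_overlap_pvalue(5, 6, 2, 1), "universe")
})

test_that("permutation overlap test converges to the hypergeometric tail", {
  uni <- paste0("g", 1:20)
  res <- permutation_overlap_test(c(5, 5), list(uni, uni), observed = 3,
                                  n_permutations = 40000, seed = 17)
  exact <- exact_overlap_pvalue(20, 5, 5, 3)
  mc_se <- sqrt(exact * (1 - exact) / 40000)
  expect_lt(abs(res$p - exact), 3 * mc_se)
  expect_equal(res$n_as_extreme / res$n_permutations, res$p)
  expect_equal(res$p_bias_guarded, (res$n_as_extreme + 1) / 40001)

  # observed 0 -> p = 1 exactly; identical universes fully overlapping
  expect_equal(permutation_overlap_test(c(5, 5), list(uni, uni), 0,
                                        n_permutations = 50, seed = 1)$p, 1)
  full <- permutation_overlap_test(c(20, 20), list(uni, uni), 20,
                                   n_permutations = 50, seed = 1)
  expect_equal(full$p, 1)

  # determinism under a fixed seed
  r1 <- permutation_overlap_test(c(4, 6), list(uni, uni), 2,
                                 n_permutations = 500, seed = 99)
  r2 <- permutation_overlap_test(c(4, 6), list(uni, uni), 2,
                                 n_permutations = 500, seed = 99)
  expect_identical(r1$p, r2$p)
  expect_identical(r1$null_distribution, r2$null_distribution)

  expect_error(permutation_overlap_test(c(30, 5), list(uni, uni), 1),
               "exceeds")
  expect_error(permutation_overlap_test(c(2, 2), list(uni, uni), 1,
                                        n_permutations = 0), "n_permutations")
})

test_that("three-set permutation null matches exhaustive enumeration on a tiny universe", {
  N <- 6; sizes <- c(3, 3, 2)
  uni <- paste0("g", 1:N)
  exact_dist <- enumerate_overlap_distribution(N, sizes)
  res <- permutation_overlap_test(sizes, list(uni, uni, uni), observed = 1,
                                  n_permutations = 30000, seed = 5)
  emp <- rep(0, length(exact_dist))
  cnts <- as.integer(names(res$null_distribution))
  emp[cnts + 1] <- as.numeric(res$null_distribution) / 30000
  for (k in seq_along(exact_dist)) {
    se <- sqrt(exact_dist[k] * (1 - exact_dist[k]) / 30000)
    expect_lt(abs(emp[k] - exact_dist[k]), 3 * se + 1e-9)
  }
  # tail p agrees with the enumerated tail
  expect_lt(abs(res$p - sum(exact_dist[2:length(exact_dist)])),
            3 * sqrt(res$p * (1 - res$p) / 30000) + 1e-9)
})

test_that("over-representation analysis uses the hypergeometric kernel", {
  uni <- paste0("g", 1:20)
  coll <- list(setA = uni[1:5], setB = uni[6:17], setC = paste0("x", 1:4))
  query <- c(uni[1:3], uni[18:19])
  res <- ora_enrichment(query, coll, uni)
  expect_equal(res$p[res$set == "setA"], exact_overlap_pvalue(20, 5, 5, 3))
  # a set disjoint from the universe tests an empty set: p = 1
  expect_equal(res$overlap[res$set == "setC"], 0)
  expect_equal(res$p[res$set == "setC"], 1)
  # query identical to a collection set is the most enriched
  res2 <- ora_enrichment(uni[1:5], coll, uni)
  expect_equal(res2$set[1], "setA")
  expect_error(ora_enrichment(query, coll, character(0)), "universe")
  expect_error(ora_enrichment("nope", coll, uni), "contained")
})

test_that("GMT collections round-trip through read_gmt", {
  dir <- withr::local_tempdir()
  gmt <- file.path(dir, "sets.gmt")
  writeLines(c("glycolysis\tsource\tHK2\tPGK1\tENO1\tTPI1",
               "hif_targets\tsource\tHILPDA\tPGK1\tVKORC1"), gmt)
  coll <- read_gmt(gmt)
  expect_named(coll, c("glycolysis", "hif_targets"))
  expect_setequal(coll$glycolysis, c("HK2", "PGK1", "ENO1", "TPI1"))
})

test_that("promoter-window annotation honors half-open boundary semantics", {
  dir <- withr::local_tempdir()
  gene_bed <- file.path(dir, "g.bed")
  peak_bed <- file.path(dir, "p.bed")
  # + strand gene, TSS at 10000 (0-based); window w=1000 -> [9000, 11000)
  writeLines("chr1\t10000\t12000\tgeneA\t0\t+", gene_bed)
  # peak exactly abutting the window end: [11000, 11200) -> NOT flagged
  writeLines("chr1\t11000\t11200\tpk1\t5\t.", peak_bed)
  ann <- annotate_genes_with_peaks(gene_bed, peak_bed, 1000)
  expect_false(ann$flagged[1])
  # peak overlapping the last base of the window [10999, 11000): flagged
  writeLines("chr1\t10999\t11000\tpk2\t5\t.", peak_bed)
  expect_true(annotate_genes_with_peaks(gene_bed, peak_bed, 1000)$flagged[1])
  # peak ending exactly at window start [8900, 9000): NOT flagged
  writeLines("chr1\t8900\t9000\tpk3\t5\t.", peak_bed)
  expect_false(annotate_genes_with_peaks(gene_bed, peak_bed, 1000)$flagged[1])
  # - strand gene: TSS is the BED end coordinate
  writeLines("chr1\t10000\t12000\tgeneB\t0\t-", gene_bed)
  writeLines("chr1\t12500\t12600\tpk4\t5\t.", peak_bed)
  ann2 <- annotate_genes_with_peaks(gene_bed, peak_bed, 1000)
  expect_true(ann2$flagged[1])

  # malformed BED line errors with its line number
  writeLines(c("chr1\t100\t200\tok\t0\t+", "chr1\tnope\t300"), gene_bed)
  expect_error(annotate_genes_with_peaks(gene_bed, peak_bed, 1000), "line 2")

  # empty peak file: nothing flagged
  writeLines("chr1\t10000\t12000\tgeneA\t0\t+", gene_bed)
  file.create(peak_bed)
  writeLines(character(0), peak_bed)
  expect_false(any(annotate_genes_with_peaks(gene_bed, peak_bed,
                                             1000)$flagged))
})
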