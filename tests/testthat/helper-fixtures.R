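# Shared fixture builders. All fixtures are generated in code at test time.

# Small two-group expression dataset with explicit status/mycn annotations.
make_cohort_fixture <- function(n_per_group = 25, n_genes = 30, seed = 42,
                                mycn = NULL) {
  set.seed(seed)
  n <- 2 * n_per_group
  status <- rep(c("survivor", "deceased"), each = n_per_group)
  if (is.null(mycn)) mycn <- rbinom(n, 1, 0.2)
  mat <- matrix(rnorm(n_genes * n, 8, 1), n_genes, n,
                dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                sprintf("S%03d", seq_len(n))))
  ann <- data.frame(sample_id = colnames(mat), status = status, mycn = mycn,
                    stringsAsFactors = FALSE)
  expression_dataset(mat, ann, dataset_id = "fixture")
}

# Direct O-E / hypergeometric-variance evaluation of the two-group log-rank
# statistic, written independently of the package kernel (row-wise over a
# risk table) to serve as an oracle.
logrank_by_hand <- function(time, event, group) {
  g2 <- group == sort(unique(group))[2]
  oe <- 0; v <- 0
  for (tt in sort(unique(time[event == 1]))) {
    risk <- which(time >= tt)
    n <- length(risk)
    n2 <- sum(g2[risk])
    d <- sum(event == 1 & time == tt)
    d2 <- sum(event == 1 & time == tt & g2)
    oe <- oe + (d2 - d * n2 / n)
    if (n > 1) v <- v + d * (n2 / n) * (1 - n2 / n) * (n - d) / (n - 1)
  }
  chisq <- if (v > 0) oe^2 / v else 0
  list(statistic = chisq,
       p = if (v > 0) pchisq(chisq, 1, lower.tail = FALSE) else 1)
}

# Exhaustive overlap-size distribution for k random subsets of a common
# universe (tiny N only): enumerates all subsets as bitmasks.
enumerate_overlap_distribution <- function(N, sizes) {
  popcount <- vapply(0:(2^N - 1), function(m) sum(bitwAnd(m, 2^(0:(N - 1))) > 0),
                     numeric(1))
  masks <- lapply(sizes, function(k) {
    cols <- utils::combn(N, k)
    apply(cols, 2, function(ix) sum(2^(ix - 1)))
  })
  dist <- rep(0, min(sizes) + 1)
  rec <- function(i, acc_mask, weight) {
    if (i > length(masks)) {
      ov <- popcount[acc_mask + 1]
      dist[ov + 1] <<- dist[ov + 1] + weight
      return(invisible())
    }
    for (m in masks[[i]]) rec(i + 1, bitwAnd(acc_mask, m), weight)
  }
  rec(1, 2^N - 1, 1)
  dist / sum(dist)
}
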