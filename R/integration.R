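#' Build a signature set from a DEG table
#'
#' @param degs A [deg_table()] (or a data.frame with `gene` and `direction`).
#' @param universe Character vector of all genes tested in the dataset; when
#'   `degs` is a `deg_table` its records' genes must be contained in it.
#' @param dataset_id Label (defaults to the DEG table's).
#' @return An object of class `signature_set` with fields `dataset_id`,
#'   `genes` (named character vector: gene -> direction), `universe`.
#' @export
signature_set <- function(degs, universe, dataset_id = NULL) {
  if (inherits(degs, "deg_table")) {
    if (is.null(dataset_id)) dataset_id <- degs$dataset_id
    recs <- degs$records
  } else {
    recs <- degs
    if (is.null(dataset_id)) dataset_id <- "dataset"
  }
  genes <- stats::setNames(as.character(recs$direction),
                           as.character(recs$gene))
  if (!all(genes %in% c("up", "down")))
    stop("directions must be 'up' or 'down'")
  universe <- unique(as.character(universe))
  if (!all(names(genes) %in% universe))
    stop("signature genes must be contained in the universe")
  structure(list(dataset_id = dataset_id, genes = genes, universe = universe),
            class = "signature_set")
}

#' Intersect differential-expression signatures across datasets
#'
#' Computes the k-way intersection of gene signatures by symbol, and counts
#' how many shared genes change in the same direction in every member set
#' (direction consistency).
#'
#' @param sets A list of [signature_set()] objects (at least two).
#' @return An `overlap_report`: list with `member_sets`, `shared_genes`,
#'   `n_shared`, `consistent_genes`, `n_direction_consistent`, and a
#'   `directions` matrix (shared genes x datasets).
#' @export
intersect_signatures <- function(sets) {
  if (length(sets) < 2) stop("at least two signature sets are required")
  if (!all(vapply(sets, inherits, logical(1), "signature_set")))
    stop("all elements must be signature_set objects")
  ids <- vapply(sets, `[[`, character(1), "dataset_id")
  if (any(vapply(sets, function(s) length(s$genes) == 0, logical(1))))
    warning("empty signature in at least one set; intersection is empty")
  shared <- Reduce(intersect, lapply(sets, function(s) names(s$genes)))
  shared <- sort(shared)
  dirs <- vapply(sets, function(s) unname(s$genes[shared]),
                 character(length(shared)))
  if (length(shared) == 1) dirs <- matrix(dirs, nrow = 1)
  if (length(shared) == 0)
    dirs <- matrix(character(0), 0, length(sets))
  dimnames(dirs) <- list(shared, ids)
  consistent <- shared[apply(dirs, 1, function(d) length(unique(d)) == 1)]
  structure(list(member_sets = ids, shared_genes = shared,
                 n_shared = length(shared),
                 consistent_genes = consistent,
                 n_direction_consistent = length(consistent),
                 directions = dirs),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat("<overlap_report> ", paste(x$member_sets, collapse = " * "), "\n",
      "  shared genes: ", x$n_shared,
      "   direction-consistent: ", x$n_direction_consistent, "\n", sep = "")
  invisible(x)
}

#' Monte-Carlo permutation test for multi-dataset signature overlap
#'
#' For each replicate, a uniform random gene set of the observed signature
#' size is drawn (without replacement) from each dataset's own tested
#' universe; the size of the k-way intersection by symbol forms the null
#' distribution. The primary p-value follows the plain counting rule
#' p = (number of replicates with overlap >= observed) / n_permutations;
#' because that estimator can return 0, the bias-guarded estimate
#' (count + 1) / (n + 1) is also reported.
#'
#' @param set_sizes Integer vector, one signature size per dataset.
#' @param universes List of character vectors, one tested universe per
#'   dataset. With `common_universe = TRUE` the universes are intersected
#'   before sampling.
#' @param observed Observed overlap count.
#' @param n_permutations Number of Monte-Carlo replicates (default 100000).
#' @param seed RNG seed.
#' @param common_universe Intersect universes before sampling.
#' @return A `permutation_result`: list with `observed`, `n_permutations`,
#'   `n_as_extreme`, `p`, `p_bias_guarded`, `seed`, and
#'   `null_distribution` (a table of permuted overlap sizes).
#' @export
permutation_overlap_test <- function(set_sizes, universes, observed,
                                     n_permutations = 100000, seed = 1L,
                                     common_universe = FALSE) {
  if (n_permutations < 1) stop("n_permutations must be at least 1")
  if (observed < 0) stop("observed must be non-negative")
  k <- length(set_sizes)
  if (length(universes) != k)
    stop("one universe per set size is required")
  if (common_universe) {
    shared <- Reduce(intersect, universes)
    universes <- rep(list(shared), k)
  }
  sym <- unique(unlist(universes, use.names = FALSE))
  uid <- lapply(universes, function(u) match(unique(u), sym))
  sizes <- vapply(uid, length, integer(1))
  if (any(set_sizes > sizes))
    stop("set size exceeds its universe size")
  n_sym <- length(sym)
  set.seed(seed)
  counts <- integer(n_permutations)
  for (r in seq_len(n_permutations)) {
    drawn <- unlist(lapply(seq_len(k), function(d)
      uid[[d]][sample.int(sizes[d], set_sizes[d])]), use.names = FALSE)
    counts[r] <- sum(tabulate(drawn, n_sym) == k)
  }
  n_extreme <- sum(counts >= observed)
  structure(list(observed = observed, n_permutations = n_permutations,
                 n_as_extreme = n_extreme,
                 p = n_extreme / n_permutations,
                 p_bias_guarded = (n_extreme + 1) / (n_permutations + 1),
                 seed = seed,
                 null_distribution = table(counts)),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("<permutation_result> observed = ", x$observed, ", ",
      format(x$n_permutations, big.mark = ","), " permutations\n",
      "  p = ", signif(x$p, 4),
      "  (bias-guarded ", signif(x$p_bias_guarded, 4), ")\n", sep = "")
  invisible(x)
}

#' Exact overlap p-value for two random subsets of a common universe
#'
#' The overlap of two uniformly drawn subsets of sizes k1 and k2 from a
#' universe of size N is hypergeometric; this returns the exact upper tail
#' P(X >= observed), the analytic oracle for the two-set case of
#' [permutation_overlap_test()].
#'
#' @param universe_size,k1,k2 Universe and subset sizes.
#' @param observed Observed overlap.
#' @return The exact tail probability.
#' @examples
#' exact_overlap_pvalue(20, 5, 5, 3)  # 1126/15504
#' @export
exact_overlap_pvalue <- function(universe_size, k1, k2, observed) {
  if (k1 > universe_size || k2 > universe_size)
    stop("subset sizes must not exceed the universe size")
  if (observed <= 0) return(1)
  if (observed > min(k1, k2)) {
    warning("observed overlap exceeds min(k1, k2); returning p = 0")
    return(0)
  }
  stats::phyper(observed - 1, k1, universe_size - k1, k2, lower.tail = FALSE)
}

#' Hypergeometric over-representation analysis against a gene-set collection
#'
#' For each collection set (intersected with the universe first), computes
#' the hypergeometric upper-tail p-value for its overlap with the query, and
#' q-values across the collection via [compute_qvalues()].
#'
#' @param query Character vector of genes (must lie in the universe).
#' @param collection Named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @param universe Character vector of tested genes.
#' @param q_max Significance threshold recorded in the `significant` column
#'   (default 0.05).
#' @return Data frame with columns `set`, `set_size`, `overlap`, `p`, `q`,
#'   `significant`, `overlap_genes`, ordered by p.
#' @export
ora_enrichment <- function(query, collection, universe, q_max = 0.05) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("universe is empty")
  query <- unique(query)
  if (!all(query %in% universe))
    stop("query genes must be contained in the universe")
  if (length(collection) == 0)
    return(data.frame(set = character(0), set_size = integer(0),
                      overlap = integer(0), p = numeric(0), q = numeric(0),
                      significant = logical(0), overlap_genes = character(0)))
  sets <- lapply(collection, intersect, universe)
  overlap <- vapply(sets, function(s) length(intersect(s, query)), integer(1))
  set_size <- lengths(sets)
  p <- vapply(seq_along(sets), function(i)
    exact_overlap_pvalue(length(universe), set_size[i], length(query),
                         overlap[i]), numeric(1))
  q <- compute_qvalues(p)
  out <- data.frame(set = names(collection), set_size = set_size,
                    overlap = overlap, p = p, q = q,
                    significant = q < q_max,
                    overlap_genes = vapply(sets, function(s)
                      paste(sort(intersect(s, query)), collapse = ","),
                      character(1)),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$p, out$set), ]
}

#' Read a GMT gene-set collection
#'
#' @param path GMT file path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Parse a 6-column BED file
#'
#' BED coordinates are 0-based half-open; the returned `GRanges` uses the
#' usual 1-based closed convention. Malformed lines raise an error naming
#' the line number.
#'
#' @param path BED path (3 to 6 columns, tab-delimited, no header).
#' @return A `GRanges` with `name` and `score` metadata columns when present.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0)
    return(GenomicRanges::GRanges())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("malformed BED line ", which(nf < 3)[1], ": fewer than 3 fields")
  start <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 2)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 3)))
  bad <- which(!is.finite(start) | !is.finite(end) | start < 0 | end < start)
  if (length(bad))
    stop("malformed BED line ", bad[1], ": invalid coordinates")
  chrom <- vapply(fields, `[`, character(1), 1)
  name <- ifelse(nf >= 4, vapply(fields, function(f) f[4], character(1)),
                 sprintf("feature_%d", seq_along(fields)))
  strand <- ifelse(nf >= 6, vapply(fields, function(f) f[6], character(1)),
                   "*")
  strand[!strand %in% c("+", "-")] <- "*"
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1, end = pmax(end, start + 1)),
    strand = strand)
  gr$name <- name
  # zero-width intervals are kept as width-1 anchors at the start position
  gr
}

#' Flag genes whose promoter windows contain peaks
#'
#' A gene is flagged when at least one peak overlaps the half-open window
#' \[TSS - w, TSS + w) around its strand-adjusted transcription start site
#' (BED start for + strand, BED end for - strand). A peak exactly abutting
#' the window end is not an overlap.
#'
#' @param gene_bed,peak_bed BED file paths (genes must carry names; strand
#'   used when present).
#' @param promoter_window Window half-width w in basepairs (default 2000).
#' @return Data frame with columns `gene`, `flagged`, `peaks`
#'   (comma-separated overlapping peak names).
#' @export
annotate_genes_with_peaks <- function(gene_bed, peak_bed,
                                      promoter_window = 2000) {
  if (promoter_window < 0) stop("promoter_window must be non-negative")
  genes <- read_bed(gene_bed)
  peaks <- read_bed(peak_bed)
  if (length(genes) == 0)
    return(data.frame(gene = character(0), flagged = logical(0),
                      peaks = character(0)))
  w <- promoter_window
  if (w == 0)  # zero-width windows cannot contain any peak
    return(data.frame(gene = genes$name, flagged = FALSE, peaks = "",
                      stringsAsFactors = FALSE))
  minus <- as.character(GenomicRanges::strand(genes)) == "-"
  tss0 <- ifelse(minus, GenomicRanges::end(genes),
                 GenomicRanges::start(genes) - 1)  # 0-based TSS
  # half-open 0-based window [tss - w, tss + w) -> 1-based closed
  win <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(genes),
    ranges = IRanges::IRanges(start = pmax(tss0 - w, 0) + 1,
                              end = tss0 + w))
  hits <- GenomicRanges::findOverlaps(win, peaks, ignore.strand = TRUE)
  out <- data.frame(gene = genes$name,
                    flagged = seq_along(genes) %in%
                      unique(S4Vectors::queryHits(hits)),
                    peaks = "", stringsAsFactors = FALSE)
  if (length(hits) > 0) {
    agg <- tapply(peaks$name[S4Vectors::subjectHits(hits)],
                  S4Vectors::queryHits(hits),
                  function(x) paste(sort(unique(x)), collapse = ","))
    out$peaks[as.integer(names(agg))] <- unname(agg)
  }
  out
}
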