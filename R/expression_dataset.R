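#' Construct an expression dataset
#'
#' Bundles a features x samples matrix of normalized, log2-scale intensities
#' with per-sample annotations and an optional probe-to-gene map. This is the
#' container every differential-expression and survival routine in the
#' package consumes.
#'
#' @param matrix Numeric matrix, features in rows, samples in columns.
#'   Rownames are feature (probe or gene) identifiers, colnames sample IDs.
#' @param sample_annotations `data.frame` with one row per sample and a
#'   `sample_id` column matching `colnames(matrix)`. Further columns depend on
#'   the design: patient cohorts carry `status` ("deceased"/"survivor"),
#'   `mycn` (0/1), and optionally `os_time`, `os_event`, `stage`, `age`;
#'   cell-line panels carry `condition` ("normoxia"/"hypoxia"), `line`,
#'   `mycn`, `growth_pattern`.
#' @param feature_map Optional `data.frame` with columns `probe_id`,
#'   `gene_symbol` mapping matrix rownames to gene symbols.
#' @param dataset_id Label used in downstream reports.
#'
#' @return An object of class `expression_dataset`.
#' @export
expression_dataset <- function(matrix, sample_annotations, feature_map = NULL,
                               dataset_id = "dataset") {
  if (!is.matrix(matrix) || !is.numeric(matrix))
    stop("`matrix` must be a numeric matrix (features x samples)")
  if (is.null(rownames(matrix)))
    stop("`matrix` must have feature rownames")
  if (is.null(colnames(matrix)))
    stop("`matrix` must have sample colnames")
  if (anyDuplicated(colnames(matrix)))
    stop("duplicate sample IDs in matrix columns")
  if (!is.data.frame(sample_annotations) ||
      !"sample_id" %in% names(sample_annotations))
    stop("`sample_annotations` must be a data.frame with a sample_id column")
  if (!identical(sort(as.character(sample_annotations$sample_id)),
                 sort(colnames(matrix))))
    stop("sample_annotations$sample_id must match matrix colnames")
  if (any(!is.finite(matrix) & !is.na(matrix)))
    stop("matrix values must be finite (use NA for missing)")
  # align annotation rows to column order
  sample_annotations <-
    sample_annotations[match(colnames(matrix),
                             sample_annotations$sample_id), , drop = FALSE]
  rownames(sample_annotations) <- NULL
  if (!is.null(feature_map)) {
    if (!all(c("probe_id", "gene_symbol") %in% names(feature_map)))
      stop("`feature_map` needs probe_id and gene_symbol columns")
  }
  structure(
    list(matrix = matrix,
         sample_annotations = sample_annotations,
         feature_map = feature_map,
         dataset_id = dataset_id),
    class = "expression_dataset"
  )
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat("<expression_dataset> ", x$dataset_id, "\n", sep = "")
  cat("  features: ", nrow(x$matrix), "   samples: ", ncol(x$matrix), "\n",
      sep = "")
  ann <- setdiff(names(x$sample_annotations), "sample_id")
  cat("  annotations: ", paste(ann, collapse = ", "), "\n", sep = "")
  if (!is.null(x$feature_map))
    cat("  feature_map: ", nrow(x$feature_map), " probes -> ",
        length(unique(x$feature_map$gene_symbol)), " genes\n", sep = "")
  invisible(x)
}

#' Write / read the pipeline's expression and clinical text formats
#'
#' Expression is stored as a tab-delimited table with features in rows and a
#' header row of sample IDs; clinical/experimental annotations as a
#' tab-delimited table with a `sample_id` column. These are the formats the
#' synthetic-data generators emit and `run_pipeline()` ingests.
#'
#' @param dataset An `expression_dataset`.
#' @param expression_path,annotation_path Output file paths.
#' @return `write_expression_dataset` invisibly returns the paths;
#'   `read_expression_dataset` returns an `expression_dataset`.
#' @export
write_expression_dataset <- function(dataset, expression_path,
                                     annotation_path) {
  stopifnot(inherits(dataset, "expression_dataset"))
  mat <- data.frame(feature_id = rownames(dataset$matrix),
                    dataset$matrix, check.names = FALSE)
  utils::write.table(mat, expression_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(dataset$sample_annotations, annotation_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(expression = expression_path, annotation = annotation_path))
}

#' @rdname write_expression_dataset
#' @param feature_map_path Optional probe map TSV (`probe_id`, `gene_symbol`).
#' @param dataset_id Label for the ingested dataset.
#' @export
read_expression_dataset <- function(expression_path, annotation_path,
                                    feature_map_path = NULL,
                                    dataset_id = "dataset") {
  tab <- utils::read.table(expression_path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (!"feature_id" %in% names(tab))
    stop("expression TSV must have a feature_id column")
  mat <- as.matrix(tab[, setdiff(names(tab), "feature_id"), drop = FALSE])
  rownames(mat) <- tab$feature_id
  ann <- utils::read.table(annotation_path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  ann$sample_id <- as.character(ann$sample_id)
  fmap <- NULL
  if (!is.null(feature_map_path))
    fmap <- utils::read.table(feature_map_path, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE)
  expression_dataset(mat, ann, feature_map = fmap, dataset_id = dataset_id)
}
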