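#' Expression data container
#'
#' Holds a genes x samples numeric matrix together with per-sample
#' annotations and a data-kind flag. \code{kind = "counts"} marks raw
#' sequencing counts (non-negative integers, analysed with negative
#' binomial models); \code{kind = "continuous"} marks microarray /
#' proteomics style intensities assumed to be on a log scale (analysed
#' with linear models).
#'
#' @param mat numeric matrix, genes in rows (rownames = gene IDs),
#'   samples in columns (colnames = sample IDs).
#' @param annotations data.frame with one row per sample; must contain a
#'   \code{sample_id} column matching \code{colnames(mat)} and typically a
#'   \code{group} column. If missing, a minimal annotation table is built.
#' @param kind \code{"counts"} or \code{"continuous"}.
#' @return An object of class \code{ExpressionData}: a list with elements
#'   \code{matrix}, \code{annotations}, \code{kind}.
#' @export
expression_data <- function(mat, annotations = NULL,
                            kind = c("continuous", "counts")) {
  kind <- match.arg(kind)
  if (!is.matrix(mat) || !is.numeric(mat))
    stopf("`mat` must be a numeric matrix")
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    stopf("`mat` must have gene IDs as rownames and sample IDs as colnames")
  if (anyDuplicated(rownames(mat)))
    stopf("duplicate gene IDs: %s",
          paste(unique(rownames(mat)[duplicated(rownames(mat))]), collapse = ", "))
  if (anyDuplicated(colnames(mat)))
    stopf("duplicate sample IDs: %s",
          paste(unique(colnames(mat)[duplicated(colnames(mat))]), collapse = ", "))
  if (anyNA(mat)) stopf("expression matrix contains missing values")
  if (kind == "counts") {
    if (any(mat < 0)) stopf("negative count in counts-kind data")
    if (any(mat != floor(mat))) stopf("non-integral count in counts-kind data")
  }
  if (is.null(annotations)) {
    annotations <- data.frame(sample_id = colnames(mat),
                              stringsAsFactors = FALSE)
  }
  if (!"sample_id" %in% names(annotations))
    stopf("`annotations` must contain a sample_id column")
  if (!identical(as.character(annotations$sample_id), colnames(mat)))
    stopf("annotations$sample_id must match colnames(mat) in order")
  structure(list(matrix = mat, annotations = annotations, kind = kind),
            class = "ExpressionData")
}

#' @export
dim.ExpressionData <- function(x) dim(x$matrix)

#' @export
print.ExpressionData <- function(x, ...) {
  cat(sprintf("ExpressionData: %d genes x %d samples (%s)\n",
              nrow(x$matrix), ncol(x$matrix), x$kind))
  if ("group" %in% names(x$annotations)) {
    tab <- table(x$annotations$group)
    cat("groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Gene and sample identifiers
#' @param x an \code{ExpressionData} object.
#' @return character vector of IDs.
#' @export
gene_ids <- function(x) rownames(x$matrix)

#' @rdname gene_ids
#' @export
sample_ids <- function(x) colnames(x$matrix)

#' Read an expression matrix (and optional sample metadata) from TSV
#'
#' The expression file is tab-separated with a header line whose first
#' field is \code{gene_id}, followed by sample IDs; each subsequent row is
#' a gene. The metadata file has columns \code{sample_id} and annotation
#' columns such as \code{group}.
#'
#' @param path path to the expression TSV.
#' @param meta_path optional path to the sample-metadata TSV.
#' @param kind \code{"counts"} or \code{"continuous"}.
#' @return an \code{ExpressionData} object.
#' @export
read_expression <- function(path, meta_path = NULL,
                            kind = c("continuous", "counts")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stopf("expression file not found: %s", path)
  if (file.size(path) == 0) stopf("empty expression file: %s", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) != 1L)
    stopf("ragged rows in %s: field counts %s", path,
          paste(unique(nf), collapse = "/"))
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (length(header) < 2L || header[1] != "gene_id")
    stopf("malformed header in %s: first column must be 'gene_id'", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stopf("duplicate gene IDs in %s: %s", path,
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(mat)) stopf("non-numeric expression values in %s", path)
  rownames(mat) <- ids
  ann <- NULL
  if (!is.null(meta_path)) {
    if (!file.exists(meta_path)) stopf("metadata file not found: %s", meta_path)
    ann <- utils::read.delim(meta_path, header = TRUE, sep = "\t", quote = "",
                             check.names = FALSE, stringsAsFactors = FALSE)
    if (!"sample_id" %in% names(ann))
      stopf("metadata %s lacks a sample_id column", meta_path)
    miss <- setdiff(colnames(mat), ann$sample_id)
    if (length(miss))
      stopf("samples missing from metadata: %s", paste(miss, collapse = ", "))
    ann <- ann[match(colnames(mat), ann$sample_id), , drop = FALSE]
    rownames(ann) <- NULL
  }
  expression_data(mat, ann, kind)
}

#' Write expression data (and metadata) as TSV
#'
#' @param ed an \code{ExpressionData} object.
#' @param path output path for the expression TSV.
#' @param meta_path optional output path for the sample metadata TSV.
#' @return invisibly, \code{path}.
#' @export
write_expression <- function(ed, path, meta_path = NULL) {
  stopifnot(inherits(ed, "ExpressionData"))
  df <- data.frame(gene_id = rownames(ed$matrix), ed$matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(meta_path))
    utils::write.table(ed$annotations, meta_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(path)
}
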