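#' Construct and validate an expression matrix
#'
#' An expression matrix holds log2-scale expression values with features
#' (mRNAs or miRNAs) as rows and samples as columns. Feature and sample
#' identifiers must be unique and every value finite; a matrix holds one
#' feature kind only.
#'
#' @param values Numeric matrix with rownames (feature ids) and colnames
#'   (sample ids).
#' @param feature_kind `"mRNA"` or `"miRNA"`.
#' @return The validated matrix with a `feature_kind` attribute and class
#'   `"expr_matrix"`.
#' @export
expression_matrix <- function(values, feature_kind = c("mRNA", "miRNA")) {
  feature_kind <- match.arg(feature_kind)
  if (!is.matrix(values) || !is.numeric(values))
    stop("expression values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs feature ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite expression value at feature '%s', sample '%s'",
                 rownames(values)[bad[1L]], colnames(values)[bad[2L]]))
  }
  structure(values, feature_kind = feature_kind,
            class = c("expr_matrix", class(values)))
}

#' Read a log2 expression matrix from TSV
#'
#' Expects a header row of sample ids, a first column of feature ids, and a
#' numeric body. Row and column order are preserved. Non-numeric cells
#' (including `NA`) are rejected with their coordinates; missing values are
#' not imputed.
#'
#' @param path Path to a tab-separated file.
#' @param feature_kind `"mRNA"` or `"miRNA"`.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, feature_kind = c("mRNA", "miRNA")) {
  feature_kind <- match.arg(feature_kind)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("expression TSV needs a feature-id column plus >=1 sample column")
  ids <- raw[[1L]]
  samples <- colnames(raw)[-1L]
  body <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  bad <- which(is.na(num) | is.na(body), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-numeric expression cell '%s' at feature '%s' (row %d), sample '%s'",
                 body[bad[1L, 1L], bad[1L, 2L]], ids[bad[1L, 1L]], bad[1L, 1L],
                 samples[bad[1L, 2L]]))
  }
  dimnames(num) <- list(ids, samples)
  expression_matrix(num, feature_kind)
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression()]: the written file round-trips to an
#' identical matrix.
#'
#' @param mat An [expression_matrix()] (or plain named numeric matrix).
#' @param path Output path.
#' @export
write_expression <- function(mat, path) {
  df <- data.frame(feature_id = rownames(mat), unclass(mat),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample design table
#'
#' Columns: `sample_id`, `condition` (`normal`/`tumor`), `subtype` (free text,
#' `"unknown"` when not recorded), `pair_id` (optional matching key; empty
#' when unpaired). Each condition must contain at least two samples.
#'
#' @param path Path to a tab-separated design file.
#' @return A data.frame with one row per sample.
#' @export
read_design <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", stringsAsFactors = FALSE)
  need <- c("sample_id", "condition")
  if (!all(need %in% colnames(df)))
    stop("design TSV must contain columns: ", paste(need, collapse = ", "))
  if (!"subtype" %in% colnames(df)) df$subtype <- "unknown"
  if (!"pair_id" %in% colnames(df)) df$pair_id <- ""
  validate_design(df[, c("sample_id", "condition", "subtype", "pair_id")])
}

#' @rdname read_design
#' @param design A design data.frame to validate.
#' @export
validate_design <- function(design) {
  if (anyDuplicated(design$sample_id))
    stop("duplicate sample ids in design: ",
         paste(unique(design$sample_id[duplicated(design$sample_id)]), collapse = ", "))
  bad <- setdiff(unique(design$condition), c("normal", "tumor"))
  if (length(bad) > 0L)
    stop("unknown condition label(s): ", paste(bad, collapse = ", "))
  tab <- table(factor(design$condition, levels = c("normal", "tumor")))
  if (any(tab < 2L))
    stop("each condition needs at least 2 samples (got normal=",
         tab[["normal"]], ", tumor=", tab[["tumor"]], ")")
  design$subtype[is.na(design$subtype) | design$subtype == ""] <- "unknown"
  design$pair_id[is.na(design$pair_id)] <- ""
  design
}

#' @rdname read_design
#' @param design A design data.frame.
#' @param path Output path.
#' @export
write_design <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Check that an expression matrix and design table agree
#'
#' @param mat An [expression_matrix()].
#' @param design A design data.frame.
#' @return The design reordered to match the matrix columns, invisibly usable
#'   downstream.
#' @export
align_design <- function(mat, design) {
  missing <- setdiff(colnames(mat), design$sample_id)
  if (length(missing) > 0L)
    stop("samples absent from design: ", paste(missing, collapse = ", "))
  design[match(colnames(mat), design$sample_id), , drop = FALSE]
}

#' Quantile-normalize an expression matrix
#'
#' Forces every sample (column) to share the identical distribution of
#' values: the value at rank r in each column is replaced by the mean over
#' columns of the r-th smallest values, with ties resolved by averaging the
#' reference values over the tied ranks. Delegates to
#' [limma::normalizeQuantiles()] with `ties = TRUE`. The operation is
#' idempotent and leaves a single-column matrix unchanged.
#'
#' @param mat An [expression_matrix()].
#' @return The normalized matrix with the same dimnames and feature kind.
#' @export
quantile_normalize <- function(mat) {
  kind <- attr(mat, "feature_kind")
  if (is.null(kind)) kind <- "mRNA"
  out <- limma::normalizeQuantiles(unclass(mat), ties = TRUE)
  dimnames(out) <- dimnames(mat)
  expression_matrix(out, kind)
}
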