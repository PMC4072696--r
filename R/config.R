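#' Pipeline configuration
#'
#' Collects the tunable thresholds of the loop-detection pipeline in a single
#' validated object. Defaults follow common practice for two-condition
#' microarray studies: per-transcript differential expression is called at
#' FDR 0.05, gene-set enrichment at the more permissive FDR 0.25, validated
#' miRNA target sets need at least eight in-universe members to be testable,
#' predicted miRNA-target edges need support from at least two sequence-based
#' prediction algorithms, and the reporting fold-change filter is 2.
#'
#' @param fdr_de FDR threshold for per-transcript differential-expression
#'   calls (Benjamini-Hochberg adjusted). Default 0.05.
#' @param fdr_gsea FDR threshold for gene-set enrichment calls, applied
#'   within each set family. Default 0.25.
#' @param min_set_size Minimum number of in-universe members for a validated
#'   miRNA target set to be tested. Default 8.
#' @param min_predictors Minimum number of sequence-based prediction
#'   algorithms supporting a predicted miRNA-target edge. Default 2.
#' @param fc_threshold Fold-change (linear scale) used by the reporting
#'   filter: features are kept when `2^delta >= fc_threshold` or
#'   `2^delta <= 1/fc_threshold`. Default 2.
#' @param seed Integer seed propagated to every stochastic stage.
#'
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(fdr_de = 0.05, fdr_gsea = 0.25, min_set_size = 8,
                            min_predictors = 2, fc_threshold = 2, seed = 1L) {
  stopifnot(
    is.numeric(fdr_de), length(fdr_de) == 1L, fdr_de > 0, fdr_de < 1,
    is.numeric(fdr_gsea), length(fdr_gsea) == 1L, fdr_gsea > 0, fdr_gsea < 1,
    is.numeric(min_set_size), min_set_size >= 1,
    is.numeric(min_predictors), min_predictors >= 1,
    is.numeric(fc_threshold), fc_threshold >= 1,
    is.numeric(seed), length(seed) == 1L, is.finite(seed)
  )
  structure(
    list(
      fdr_de = fdr_de, fdr_gsea = fdr_gsea,
      min_set_size = as.integer(min_set_size),
      min_predictors = as.integer(min_predictors),
      fc_threshold = fc_threshold, seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("Pipeline configuration\n")
  cat(sprintf("  DE FDR threshold:        %g\n", x$fdr_de))
  cat(sprintf("  GSEA FDR threshold:      %g\n", x$fdr_gsea))
  cat(sprintf("  min miRNA set size:      %d\n", x$min_set_size))
  cat(sprintf("  min predictors per edge: %d\n", x$min_predictors))
  cat(sprintf("  fold-change filter:      %g\n", x$fc_threshold))
  cat(sprintf("  seed:                    %d\n", x$seed))
  invisible(x)
}
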