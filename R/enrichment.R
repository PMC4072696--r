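# Gene-set enrichment stage: Wilcoxon rank-sum set tests over three set
# families (TF target sets, validated miRNA target sets, pathway sets),
# BH-adjusted within family, then merged with the per-transcript calls into
# combined deregulation lists.

#' Build TF-indexed target gene sets for enrichment
#'
#' One set per transcription factor that was *not* called differentially
#' expressed per-transcript (MHT FDR above `config$fdr_de`): its members are
#' the TF's directly regulated target genes restricted to the expression
#' universe. TFs without in-universe targets, or absent from the expression
#' data, yield no set. Already-significant TFs need no rescue and are
#' excluded.
#'
#' @param priordb A `"prior_db"` (see [read_priors()]).
#' @param universe Character vector of features present in the mRNA matrix.
#' @param de_results mRNA `"de_result"` table.
#' @param config A [pipeline_config()].
#' @return Named list of member vectors, one per testable TF.
#' @export
build_tf_sets <- function(priordb, universe, de_results, config = pipeline_config()) {
  fdr <- de_results$fdr[match(unique(priordb$tf_gene$regulator), de_results$feature_id)]
  tfs <- unique(priordb$tf_gene$regulator)
  keep <- !is.na(fdr) & fdr > config$fdr_de
  tfs <- sort(tfs[keep])
  sets <- lapply(tfs, function(tf) {
    sort(intersect(priordb$tf_gene$target[priordb$tf_gene$regulator == tf], universe))
  })
  names(sets) <- tfs
  sets[lengths(sets) > 0L]
}

#' Build validated-target gene sets for whitelisted miRNAs
#'
#' Sets are built only for miRNAs on an externally supplied whitelist (e.g.
#' miRNAs independently established as deregulated in the tissue of
#' interest), restricted to those not already called per-transcript; members
#' are the miRNA's experimentally validated targets (evidence `validated` or
#' `both`) in the expression universe. Sets smaller than
#' `config$min_set_size` are discarded to limit small-set bias.
#'
#' @param priordb A `"prior_db"`.
#' @param whitelist Character vector of eligible miRNA ids.
#' @param universe Character vector of mRNA features.
#' @param de_results miRNA `"de_result"` table.
#' @param config A [pipeline_config()].
#' @return Named list of member vectors.
#' @export
build_mirna_sets <- function(priordb, whitelist, universe, de_results,
                             config = pipeline_config()) {
  mg <- priordb$mirna_gene
  mg <- mg[mg$evidence %in% c("validated", "both"), , drop = FALSE]
  mirnas <- sort(intersect(unique(mg$regulator), whitelist))
  fdr <- de_results$fdr[match(mirnas, de_results$feature_id)]
  mirnas <- mirnas[!is.na(fdr) & fdr > config$fdr_de]
  sets <- lapply(mirnas, function(m) {
    sort(intersect(mg$target[mg$regulator == m], universe))
  })
  names(sets) <- mirnas
  sets[lengths(sets) >= config$min_set_size]
}

#' Wilcoxon rank-sum gene-set test
#'
#' Tests whether a gene set's per-feature statistics are shifted relative to
#' the rest of the universe. With `alternative = "mixed"` the absolute
#' statistics are ranked and the test is one-sided toward large `|t|`
#' (enrichment for deregulation in either direction); `"up"`/`"down"` rank
#' the signed statistics one-sided toward +/-. For universes of at most 10
#' features the p-value is computed by exact enumeration of all rank splits;
#' otherwise by the normal approximation with tie-corrected variance and a
#' 0.5 continuity correction.
#'
#' @param statistics Named numeric vector of per-feature statistics
#'   (typically moderated t), names spanning the universe.
#' @param set Character vector of member ids (must be a proper subset of the
#'   universe). Members absent from the universe are excluded with a message.
#' @param alternative `"mixed"`, `"up"` or `"down"`.
#' @return One-sided p-value.
#' @export
rank_sum_set_test <- function(statistics, set,
                              alternative = c("mixed", "up", "down")) {
  alternative <- match.arg(alternative)
  if (is.null(names(statistics))) stop("statistics must be a named vector")
  n_missing <- sum(!set %in% names(statistics))
  if (n_missing > 0L) {
    message(n_missing, " set member(s) absent from the universe excluded")
    set <- intersect(set, names(statistics))
  }
  if (length(set) == 0L) stop("set has no members in the universe")
  x <- switch(alternative,
              mixed = abs(statistics),
              up = statistics,
              down = -statistics)
  in_set <- names(x) %in% set
  N <- length(x)
  k <- sum(in_set)
  if (k == N) stop("set equals the universe; complement is empty")
  r <- rank(x)
  W <- sum(r[in_set])
  if (N <= 10L) {
    splits <- utils::combn(N, k)
    Wnull <- colSums(matrix(r[splits], nrow = k))
    return(mean(Wnull >= W))
  }
  m <- N - k
  mu <- k * (N + 1) / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- (k * m / 12) * (N + 1 - tie_term)
  if (sigma2 <= 0) return(1)
  z <- (W - mu - 0.5) / sqrt(sigma2)
  stats::pnorm(z, lower.tail = FALSE)
}

#' Run gene-set enrichment over the three set families
#'
#' TF and pathway families are tested with the undirected (`mixed`)
#' alternative; each miRNA set is tested for a shift in the direction
#' *opposite* to its miRNA's own deregulation (validated targets of an
#' upregulated miRNA are expected to move down, and vice versa).
#' Benjamini-Hochberg adjustment is applied within each family separately.
#'
#' @param tf_sets,mirna_sets,pathway_sets Named lists of member vectors
#'   (possibly empty) from [build_tf_sets()], [build_mirna_sets()],
#'   or GMT pathway sets restricted to the universe.
#' @param mrna_results mRNA `"de_result"` table (source of the ranked
#'   statistics).
#' @param mirna_results miRNA `"de_result"` table (source of miRNA
#'   directions).
#' @param config A [pipeline_config()].
#' @return A data.frame with columns `set_id`, `index_kind`
#'   (`TF`/`miRNA`/`pathway`), `alternative`, `p`, `fdr`,
#'   `implied_direction` (the miRNA's direction for miRNA sets, 0
#'   otherwise).
#' @export
run_gsea <- function(tf_sets = list(), mirna_sets = list(),
                     pathway_sets = list(), mrna_results, mirna_results = NULL,
                     config = pipeline_config()) {
  statistics <- stats::setNames(mrna_results$t_mod, mrna_results$feature_id)
  test_family <- function(sets, kind) {
    if (length(sets) == 0L)
      return(data.frame(set_id = character(0), index_kind = character(0),
                        alternative = character(0), p = numeric(0),
                        fdr = numeric(0), implied_direction = integer(0),
                        stringsAsFactors = FALSE))
    if (kind == "miRNA") {
      if (is.null(mirna_results))
        stop("miRNA sets supplied but no miRNA results to take directions from")
      dir <- mirna_results$direction[match(names(sets), mirna_results$feature_id)]
      if (anyNA(dir))
        stop("miRNA set(s) without a measured miRNA: ",
             paste(names(sets)[is.na(dir)], collapse = ", "))
      alts <- ifelse(dir > 0, "down", "up")
    } else {
      dir <- rep(0L, length(sets))
      alts <- rep("mixed", length(sets))
    }
    p <- vapply(seq_along(sets), function(i)
      rank_sum_set_test(statistics, sets[[i]], alts[i]), numeric(1))
    data.frame(set_id = names(sets), index_kind = kind, alternative = alts,
               p = p, fdr = bh_adjust(p), implied_direction = as.integer(dir),
               stringsAsFactors = FALSE)
  }
  out <- rbind(test_family(tf_sets, "TF"),
               test_family(mirna_sets, "miRNA"),
               test_family(pathway_sets, "pathway"))
  rownames(out) <- NULL
  out
}

#' Combine per-transcript and enrichment-based deregulation calls
#'
#' Union of the MHT-significant features and the regulators rescued by a
#' significant gene set (GSEA FDR at most `fdr_gsea`). A feature significant
#' by both routes is listed once with `source = "MHT"`. GSEA-sourced entries
#' take their direction from the sign of their own moderated t-statistic.
#'
#' @param mht_list Output of [call_differential()] for this feature kind.
#' @param gsea_results Rows of [run_gsea()] output for the matching family
#'   (index_kind `TF` for mRNAs, `miRNA` for miRNAs).
#' @param de_results The full `"de_result"` table for this feature kind
#'   (source of statistics for rescued features).
#' @param fdr_gsea GSEA FDR threshold (default 0.25).
#' @return A data.frame with columns `feature_id`, `source` (`MHT`/`GSEA`),
#'   `direction`, `mht_p`, `mht_fdr`, `gsea_fdr` (NA for MHT-only entries).
#' @export
combine_lists <- function(mht_list, gsea_results, de_results, fdr_gsea = 0.25) {
  n_mht <- nrow(mht_list)
  mht <- data.frame(feature_id = mht_list$feature_id,
                    source = rep("MHT", n_mht),
                    direction = mht_list$direction, mht_p = mht_list$p,
                    mht_fdr = mht_list$fdr,
                    gsea_fdr = rep(NA_real_, n_mht),
                    stringsAsFactors = FALSE)
  sig <- NULL
  if (!is.null(gsea_results) && nrow(gsea_results) > 0L) {
    sig <- gsea_results[gsea_results$fdr <= fdr_gsea, , drop = FALSE]
    sig <- sig[!sig$set_id %in% mht$feature_id, , drop = FALSE]
  }
  if (!is.null(sig) && nrow(sig) > 0L) {
    idx <- match(sig$set_id, de_results$feature_id)
    if (anyNA(idx))
      stop("GSEA-rescued feature(s) absent from the expression results: ",
           paste(sig$set_id[is.na(idx)], collapse = ", "))
    gsea <- data.frame(feature_id = sig$set_id, source = "GSEA",
                       direction = de_results$direction[idx],
                       mht_p = de_results$p[idx],
                       mht_fdr = de_results$fdr[idx],
                       gsea_fdr = sig$fdr,
                       stringsAsFactors = FALSE)
    mht <- rbind(mht, gsea)
  }
  rownames(mht) <- NULL
  mht
}
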