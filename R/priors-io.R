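# Readers for regulatory-prior tables, GMT gene sets and pathway edge lists.
# Schemas are deliberately neutral TSVs so that exports from any TF-target,
# TF-miRNA or miRNA-target resource can be fed in after a trivial reshape.

.regulation_levels <- c("activation", "repression")

read_tsv_cols <- function(path, cols) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", stringsAsFactors = FALSE)
  if (!all(cols %in% colnames(df)))
    stop(basename(path), ": expected columns ", paste(cols, collapse = ", "))
  df[, cols, drop = FALSE]
}

check_regulation <- function(x, path) {
  bad <- setdiff(unique(x), .regulation_levels)
  if (length(bad) > 0L)
    stop(basename(path), ": unknown regulation token(s): ",
         paste(bad, collapse = ", "))
  x
}

#' Read and merge the regulatory-prior tables
#'
#' Loads four tab-separated prior tables and assembles the merged prior
#' database used for loop construction:
#'
#' * `tf_gene.tsv` — columns `tf_id, target_gene, regulation`; direct
#'   TF-to-gene regulation with sign (`activation`/`repression`).
#' * `tf_mirna.tsv` — columns `tf_id, target_mirna, regulation`; direct
#'   transcriptional regulation of a miRNA by a TF.
#' * `mirna_targets_predicted.tsv` — columns `mirna_id, target_gene,
#'   n_predictors`; sequence-based target predictions with the number of
#'   supporting prediction algorithms.
#' * `mirna_targets_validated.tsv` — columns `mirna_id, target_gene`;
#'   experimentally validated miRNA targets.
#'
#' Predicted edges supported by fewer than `config$min_predictors` algorithms
#' are dropped (balancing false-positive against false-negative predictions),
#' and the surviving predictions are amended with the validated targets:
#' pairs present in both tables get `evidence = "both"`, validated-only pairs
#' `evidence = "validated"` (kept even with zero predictor support),
#' predicted-only pairs `evidence = "predicted"`. miRNA-target regulation is
#' always repression.
#'
#' @param tf_gene_path,tf_mirna_path,mirna_pred_path,mirna_valid_path Paths
#'   to the four TSVs.
#' @param config A [pipeline_config()].
#' @return A list of class `"prior_db"` with data.frames `tf_gene`,
#'   `tf_mirna`, `mirna_gene`, each with columns `regulator`, `target`,
#'   `regulation`, `evidence`, `n_predictors` and no duplicated
#'   (regulator, target) pair.
#' @export
read_priors <- function(tf_gene_path, tf_mirna_path, mirna_pred_path,
                        mirna_valid_path, config = pipeline_config()) {
  tg <- read_tsv_cols(tf_gene_path, c("tf_id", "target_gene", "regulation"))
  check_regulation(tg$regulation, tf_gene_path)
  tm <- read_tsv_cols(tf_mirna_path, c("tf_id", "target_mirna", "regulation"))
  check_regulation(tm$regulation, tf_mirna_path)
  mp <- read_tsv_cols(mirna_pred_path, c("mirna_id", "target_gene", "n_predictors"))
  np <- suppressWarnings(as.integer(mp$n_predictors))
  if (anyNA(np) || any(np < 0L))
    stop(basename(mirna_pred_path), ": n_predictors must be non-negative integers")
  mv <- read_tsv_cols(mirna_valid_path, c("mirna_id", "target_gene"))

  prior_db(
    tf_gene = data.frame(regulator = tg$tf_id, target = tg$target_gene,
                         regulation = tg$regulation, evidence = "curated",
                         n_predictors = 0L, stringsAsFactors = FALSE),
    tf_mirna = data.frame(regulator = tm$tf_id, target = tm$target_mirna,
                          regulation = tm$regulation, evidence = "curated",
                          n_predictors = 0L, stringsAsFactors = FALSE),
    mirna_gene = merge_mirna_targets(mp$mirna_id, mp$target_gene, np,
                                     mv$mirna_id, mv$target_gene,
                                     config$min_predictors)
  )
}

#' Merge predicted and validated miRNA-target edges
#'
#' Applies the minimum-predictor filter to the predicted edges and the
#' validated-target amendment, producing one edge per (miRNA, gene) pair with
#' its evidence label. Used by [read_priors()] and exported for programmatic
#' prior construction.
#'
#' @param pred_mirna,pred_gene,n_predictors Parallel vectors describing
#'   predicted edges.
#' @param valid_mirna,valid_gene Parallel vectors describing validated edges.
#' @param min_predictors Minimum predictor support for a predicted edge.
#' @return A data.frame of merged miRNA-gene edges (regulation is always
#'   `"repression"`).
#' @export
merge_mirna_targets <- function(pred_mirna, pred_gene, n_predictors,
                                valid_mirna, valid_gene, min_predictors = 2L) {
  keep <- n_predictors >= min_predictors
  pred_key <- paste(pred_mirna[keep], pred_gene[keep], sep = "\r")
  # collapse duplicate predictions keeping the max support
  if (anyDuplicated(pred_key)) {
    np <- tapply(n_predictors[keep], pred_key, max)
    pred_key <- names(np)
    pred_np <- as.integer(np)
  } else {
    pred_np <- n_predictors[keep]
  }
  valid_key <- unique(paste(valid_mirna, valid_gene, sep = "\r"))
  all_key <- union(pred_key, valid_key)
  in_pred <- all_key %in% pred_key
  in_valid <- all_key %in% valid_key
  parts <- strsplit(all_key, "\r", fixed = TRUE)
  np_all <- integer(length(all_key))
  np_all[in_pred] <- pred_np[match(all_key[in_pred], pred_key)]
  out <- data.frame(
    regulator = vapply(parts, `[[`, "", 1L),
    target = vapply(parts, `[[`, "", 2L),
    regulation = "repression",
    evidence = ifelse(in_pred & in_valid, "both",
                      ifelse(in_valid, "validated", "predicted")),
    n_predictors = np_all,
    stringsAsFactors = FALSE
  )
  out[order(out$regulator, out$target), , drop = FALSE]
}

#' @rdname read_priors
#' @param tf_gene,tf_mirna,mirna_gene Edge data.frames (see [read_priors()]).
#' @export
prior_db <- function(tf_gene, tf_mirna, mirna_gene) {
  for (nm in c("tf_gene", "tf_mirna", "mirna_gene")) {
    df <- get(nm)
    if (anyDuplicated(paste(df$regulator, df$target, sep = "\r")))
      stop("duplicate (regulator, target) pair in ", nm)
  }
  if (nrow(mirna_gene) > 0L && any(mirna_gene$regulation != "repression"))
    stop("miRNA-target regulation must be repression")
  rownames(tf_gene) <- rownames(tf_mirna) <- rownames(mirna_gene) <- NULL
  structure(list(tf_gene = tf_gene, tf_mirna = tf_mirna,
                 mirna_gene = mirna_gene),
            class = "prior_db")
}

#' @export
print.prior_db <- function(x, ...) {
  cat("Regulatory prior database\n")
  cat(sprintf("  TF -> gene edges:    %d\n", nrow(x$tf_gene)))
  cat(sprintf("  TF -> miRNA edges:   %d\n", nrow(x$tf_mirna)))
  cat(sprintf("  miRNA -> gene edges: %d (both=%d, validated=%d, predicted=%d)\n",
              nrow(x$mirna_gene),
              sum(x$mirna_gene$evidence == "both"),
              sum(x$mirna_gene$evidence == "validated"),
              sum(x$mirna_gene$evidence == "predicted")))
  invisible(x)
}

#' Read gene sets in GMT format
#'
#' Standard GMT: one set per line, tab-separated `set_id`, description, then
#' member ids. Empty member lists are rejected.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors (members per set).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(ids))
    stop(basename(path), ": duplicate set id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  sets <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  empty <- lengths(sets) == 0L
  if (any(empty))
    stop(basename(path), ": empty member list for set(s): ",
         paste(ids[empty], collapse = ", "))
  names(sets) <- ids
  sets
}

#' @rdname read_gmt
#' @param sets Named list of member vectors.
#' @param descriptions Optional character vector of set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- mapply(function(id, desc, members)
    paste(c(id, desc, members), collapse = "\t"),
    names(sets), descriptions, sets)
  writeLines(unname(lines), path)
  invisible(path)
}

#' Read pathway interaction edge lists
#'
#' Columns `pathway_id, gene1, gene2, effect` with `effect` in
#' `{direct, indirect}`. Edges are unordered protein-interaction pairs from a
#' pathway map; self-edges are rejected and each edge is canonicalized so
#' `gene1 < gene2` lexicographically.
#'
#' @param path Path to a tab-separated edge list.
#' @return A data.frame of pathway edges.
#' @export
read_pathway_edges <- function(path) {
  df <- read_tsv_cols(path, c("pathway_id", "gene1", "gene2", "effect"))
  bad <- setdiff(unique(df$effect), c("direct", "indirect"))
  if (length(bad) > 0L)
    stop(basename(path), ": unknown effect token(s): ", paste(bad, collapse = ", "))
  self <- df$gene1 == df$gene2
  if (any(self))
    stop(basename(path), ": self-edge(s) for gene(s): ",
         paste(unique(df$gene1[self]), collapse = ", "))
  swap <- df$gene1 > df$gene2
  tmp <- df$gene1[swap]; df$gene1[swap] <- df$gene2[swap]; df$gene2[swap] <- tmp
  df <- unique(df)
  rownames(df) <- NULL
  df
}

#' @rdname read_pathway_edges
#' @param edges Pathway edge data.frame.
#' @export
write_pathway_edges <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
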