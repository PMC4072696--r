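# Post-hoc analytics over the scored loop tables: subtype fractions,
# per-miRNA transcriptome attribution, co-targeting overlaps, miRNA-TF pair
# extraction, and loop querying.

ffl_only <- function(loops) loops[loops$loop_type %in% c("I", "II"), , drop = FALSE]

#' Fractions of deregulated FFL subtypes
#'
#' For each of the six feed-forward-loop subtypes (Type I and Type II-A/B,
#' coherent and incoherent) split by consistent/inconsistent deregulation:
#' the fraction of all Type I/II loops in that cell. Fractions sum to 1.
#'
#' @param loops A scored loop table (Type III rows are ignored).
#' @return A data.frame with columns `group`, `consistency`, `count`,
#'   `fraction`.
#' @export
subtype_fractions <- function(loops) {
  ffl <- ffl_only(loops)
  if (nrow(ffl) == 0L) stop("no Type I/II loops; fractions are undefined")
  groups <- setdiff(loop_groups(), "III")
  grid <- expand.grid(group = groups,
                      consistency = c("consistent", "inconsistent"),
                      stringsAsFactors = FALSE)
  key <- paste(loop_group(ffl), ffl$consistent)
  grid$count <- vapply(paste(grid$group, grid$consistency),
                       function(k) sum(key == k), integer(1))
  grid$fraction <- grid$count / nrow(ffl)
  grid
}

#' Per-miRNA transcriptome deregulation attribution
#'
#' For each miRNA appearing in a deregulated FFL: the percentage of all
#' differentially expressed mRNAs that appear among its distinct FFL mRNA
#' targets, split into a consistent portion (targets anti-correlated with
#' the miRNA) and an inconsistent portion. The cumulative curve unions the
#' consistent target sets over miRNAs ranked by decreasing consistent
#' percentage, counting each mRNA once, so it is monotone and bounded by
#' 100.
#'
#' @param loops Scored loop table.
#' @param de_mrna Differentially expressed mRNAs: either a `"de_result"`
#'   subset (from [call_differential()]) whose `direction` column supplies
#'   the mRNA directions, or a character vector of ids (then
#'   `mrna_directions` must be given).
#' @param mirna_directions Named vector of miRNA directions (+1/-1).
#' @param mrna_directions Optional named vector of mRNA directions; ignored
#'   when `de_mrna` is a data.frame.
#' @return A list with `per_mirna` (data.frame: `mirna`,
#'   `pct_consistent`, `pct_inconsistent`, `pct_total`) and `cumulative`
#'   (data.frame: `mirna`, `cumulative_pct`), percentages on a 0-100 scale.
#' @export
mirna_attribution <- function(loops, de_mrna, mirna_directions,
                              mrna_directions = NULL) {
  if (is.data.frame(de_mrna)) {
    mrna_directions <- stats::setNames(de_mrna$direction, de_mrna$feature_id)
    de_mrna_ids <- de_mrna$feature_id
  } else {
    de_mrna_ids <- as.character(de_mrna)
  }
  if (length(de_mrna_ids) == 0L) stop("no differentially expressed mRNAs")
  if (is.null(mrna_directions)) stop("mRNA directions are required")
  ffl <- ffl_only(loops)
  mirnas <- sort(unique(ffl$mirna))
  n_de <- length(unique(de_mrna_ids))
  cons_sets <- list()
  per <- lapply(mirnas, function(m) {
    tg <- unique(ffl$mrna_or_gene2[ffl$mirna == m])
    tg <- intersect(tg, de_mrna_ids)
    dir_m <- mirna_directions[[m]]
    if (is.null(dir_m) || is.na(dir_m)) stop("no direction for miRNA ", m)
    # consistent interaction: anti-correlated deregulation
    cons <- tg[mrna_directions[tg] == -dir_m]
    cons_sets[[m]] <<- cons
    data.frame(mirna = m,
               pct_consistent = 100 * length(cons) / n_de,
               pct_inconsistent = 100 * (length(tg) - length(cons)) / n_de,
               pct_total = 100 * length(tg) / n_de,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  if (is.null(per)) per <- data.frame(mirna = character(0),
                                      pct_consistent = numeric(0),
                                      pct_inconsistent = numeric(0),
                                      pct_total = numeric(0))
  ord <- order(-per$pct_consistent, per$mirna)
  seen <- character(0)
  cum <- numeric(length(ord))
  for (i in seq_along(ord)) {
    seen <- union(seen, cons_sets[[per$mirna[ord[i]]]])
    cum[i] <- 100 * length(seen) / n_de
  }
  list(per_mirna = per,
       cumulative = data.frame(mirna = per$mirna[ord], cumulative_pct = cum,
                               stringsAsFactors = FALSE))
}

#' Co-targeting overlap of miRNA target sets
#'
#' For a chosen group of miRNAs, computes each miRNA's set of distinct FFL
#' mRNA targets and the size of every region of the resulting Venn
#' partition (all `2^k - 1` non-empty membership patterns). Region counts
#' sum to the size of the union.
#'
#' @param mirna_ids Character vector of miRNAs (k >= 1).
#' @param loops Scored loop table.
#' @return A data.frame with columns `region` (e.g. `"m1&m2"`), `count`.
#' @export
cotargeting_overlap <- function(mirna_ids, loops) {
  stopifnot(length(mirna_ids) >= 1L)
  ffl <- ffl_only(loops)
  sets <- lapply(mirna_ids, function(m) unique(ffl$mrna_or_gene2[ffl$mirna == m]))
  names(sets) <- mirna_ids
  all_targets <- unique(unlist(sets))
  member <- vapply(sets, function(s) all_targets %in% s,
                   logical(length(all_targets)))
  if (length(all_targets) == 1L) member <- matrix(member, nrow = 1L)
  k <- length(mirna_ids)
  patterns <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1L, , drop = FALSE]
  region <- apply(patterns, 1L, function(p)
    paste(mirna_ids[as.logical(p)], collapse = "&"))
  count <- apply(patterns, 1L, function(p) {
    if (length(all_targets) == 0L) return(0L)
    sum(apply(member, 1L, function(row) all(row == as.logical(p))))
  })
  data.frame(region = region, count = as.integer(count),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Extract miRNA-TF pairs from the deregulated FFLs
#'
#' Lists every distinct (miRNA, TF) pair occurring in a Type I/II loop,
#' categorized by the interaction type of the pair's edge: `miRNA-|TF`
#' (Type I), `TF->miRNA` or `TF-|miRNA` (Type II, by regulation sign), with
#' a consistency flag for the pair's edge relation (anti-correlated
#' directions for repression, correlated for activation) and the number of
#' loops the pair occurs in.
#'
#' @param loops Scored loop table.
#' @param mrna_results,mirna_results Full `"de_result"` tables (node
#'   directions).
#' @return A data.frame with columns `mirna`, `tf`, `interaction`,
#'   `pair_consistent`, `n_loops`.
#' @export
extract_mirna_tf_pairs <- function(loops, mrna_results, mirna_results) {
  ffl <- ffl_only(loops)
  if (nrow(ffl) == 0L)
    return(data.frame(mirna = character(0), tf = character(0),
                      interaction = character(0), pair_consistent = logical(0),
                      n_loops = integer(0), stringsAsFactors = FALSE))
  interaction <- ifelse(ffl$loop_type == "I", "miRNA-|TF",
                        ifelse(ffl$tf_mirna_sign == "activation",
                               "TF->miRNA", "TF-|miRNA"))
  key <- paste(ffl$mirna, ffl$tf_or_gene1, interaction, sep = "\r")
  agg <- as.data.frame(table(key), stringsAsFactors = FALSE)
  parts <- strsplit(agg$key, "\r", fixed = TRUE)
  out <- data.frame(
    mirna = vapply(parts, `[[`, "", 1L),
    tf = vapply(parts, `[[`, "", 2L),
    interaction = vapply(parts, `[[`, "", 3L),
    n_loops = as.integer(agg$Freq),
    stringsAsFactors = FALSE
  )
  dm <- mirna_results$direction[match(out$mirna, mirna_results$feature_id)]
  dt <- mrna_results$direction[match(out$tf, mrna_results$feature_id)]
  edge_sign <- ifelse(out$interaction == "TF->miRNA", 1L, -1L)
  out$pair_consistent <- dm * dt == edge_sign
  out <- out[order(out$mirna, out$tf, out$interaction),
             c("mirna", "tf", "interaction", "pair_consistent", "n_loops")]
  rownames(out) <- NULL
  out
}

#' Query a loop table
#'
#' Returns the loops whose node identities match every provided filter
#' (exact-id sets per role) and, optionally, the requested loop types,
#' subtypes, coherence and consistency classes. Empty filters return the
#' input unchanged; the operation is idempotent.
#'
#' @param loops Loop table.
#' @param mirna,tf_or_gene1,mrna_or_gene2 Optional character vectors of
#'   admissible node ids per role.
#' @param nodes Optional character vector: every node of a returned loop
#'   must come from this closed list.
#' @param loop_type,subtype,coherence Optional filters on loop class.
#' @param consistency Optional `"consistent"`/`"inconsistent"` filter.
#' @return The matching subset of `loops`.
#' @export
query_loops <- function(loops, mirna = NULL, tf_or_gene1 = NULL,
                        mrna_or_gene2 = NULL, nodes = NULL, loop_type = NULL,
                        subtype = NULL, coherence = NULL, consistency = NULL) {
  keep <- rep(TRUE, nrow(loops))
  if (!is.null(mirna)) keep <- keep & loops$mirna %in% mirna
  if (!is.null(tf_or_gene1)) keep <- keep & loops$tf_or_gene1 %in% tf_or_gene1
  if (!is.null(mrna_or_gene2)) keep <- keep & loops$mrna_or_gene2 %in% mrna_or_gene2
  if (!is.null(nodes))
    keep <- keep & loops$mirna %in% nodes & loops$tf_or_gene1 %in% nodes &
      loops$mrna_or_gene2 %in% nodes
  if (!is.null(loop_type)) keep <- keep & loops$loop_type %in% loop_type
  if (!is.null(subtype)) keep <- keep & loops$subtype %in% subtype
  if (!is.null(coherence)) keep <- keep & loops$coherence %in% coherence
  if (!is.null(consistency)) keep <- keep & loops$consistent %in% consistency
  out <- loops[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
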