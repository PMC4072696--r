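# Significance ranking of feed-forward loops: Fisher's combined probability
# statistic over the three node-level p-values, consistency labeling against
# the loop's edge-sign structure, and within-group ranking.

#' Fisher combined score for a three-node loop
#'
#' Combines the three unadjusted per-transcript p-values of a loop's nodes
#' with Fisher's summary statistic `T = -2 (ln p1 + ln p2 + ln p3)`. Under
#' independent uniform nulls `T` is chi-square distributed with 6 degrees of
#' freedom and the score is the upper-tail probability at `T`. Because the
#' three tests are not independent in general, the score is used as a
#' ranking device (lower = more significant), not as a formal p-value.
#'
#' @param p1,p2,p3 Unadjusted p-values in (0, 1] (vectorized; floored at
#'   1e-300).
#' @return A list with components `T` (summary statistic, >= 0) and `score`
#'   (chi-square(6) survival probability in (0, 1]).
#' @export
fisher_score <- function(p1, p2, p3) {
  p <- cbind(p1, p2, p3)
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  p <- pmax(p, 1e-300)
  T <- -2 * rowSums(log(p))
  list(T = unname(T),
       score = unname(stats::pchisq(T, df = 6, lower.tail = FALSE)))
}

#' Degrees of freedom of the loop-combining statistic
#'
#' The Fisher summary statistic over a loop's three node tests is referred
#' to a chi-square distribution with 2 degrees of freedom per combined test.
#'
#' @return 6.
#' @export
fisher_df <- function() 6L

#' Label a loop's deregulation consistency
#'
#' Nodes joined by an activating edge are expected to show correlated
#' deregulation and nodes joined by a repressing edge anti-correlated
#' deregulation. A loop is *consistent* when (a) the regulator-regulator
#' edge obeys this rule (Type I: miRNA represses the TF transcript, so
#' miRNA and TF must be anti-correlated; Type II: TF and miRNA must be
#' correlated under activation, anti-correlated under repression) and (b)
#' the miRNA and its target mRNA are anti-correlated. For coherent loops
#' this pairwise rule is equivalent to all three edges obeying the rule
#' simultaneously; for incoherent loops (where the three edge relations can
#' never hold at once) it is the operative definition. Exactly 2 of the 8
#' direction assignments are consistent for every subtype.
#'
#' @param loop_type `"I"` or `"II"`.
#' @param tf_mirna_sign `"activation"`/`"repression"` for Type II, `NA` for
#'   Type I.
#' @param dir_mirna,dir_tf,dir_mrna Node deregulation directions, +1 or -1
#'   (sign of the moderated t; a zero direction is refused).
#' @return Logical: `TRUE` when consistent. Vectorized.
#' @export
label_consistency <- function(loop_type, tf_mirna_sign,
                              dir_mirna, dir_tf, dir_mrna) {
  if (any(dir_mirna == 0 | dir_tf == 0 | dir_mrna == 0))
    stop("node directions must be +1 or -1; resolve sign before labeling")
  stopifnot(all(loop_type %in% c("I", "II")))
  reg_edge_sign <- ifelse(loop_type == "I", -1L, sign_of(tf_mirna_sign))
  reg_pair_ok <- ifelse(loop_type == "I",
                        dir_mirna * dir_tf == reg_edge_sign,
                        dir_tf * dir_mirna == reg_edge_sign)
  target_ok <- dir_mirna * dir_mrna == -1L
  reg_pair_ok & target_ok
}

#' Label miRNA-target edge evidence
#'
#' Maps the merged prior evidence of a miRNA-target edge to the reporting
#' category: edges both predicted and validated are `true_positive`
#' (prediction confirmed), validated-only edges are `false_negative` (missed
#' by the predictive module), predicted-only edges are `novel`.
#'
#' @param evidence Character vector in `{both, validated, predicted}`.
#' @return Character vector of evidence categories.
#' @export
label_evidence <- function(evidence) {
  map <- c(both = "true_positive", validated = "false_negative",
           predicted = "novel")
  bad <- setdiff(unique(evidence), names(map))
  if (length(bad) > 0L) stop("unknown evidence token(s): ",
                             paste(bad, collapse = ", "))
  unname(map[evidence])
}

#' The five functional loop categories
#'
#' Loops fall into five functional categories: Type I coherent, Type I
#' incoherent, Type II coherent, Type II incoherent, and Type III; for
#' reporting, the Type II categories are further split by subtype A/B,
#' giving the seven output groups of [rank_and_group()].
#'
#' @return Character vector of the five category labels.
#' @export
loop_categories <- function() {
  c("I-coherent", "I-incoherent", "II-coherent", "II-incoherent", "III")
}

loop_group <- function(loops) {
  ifelse(loops$loop_type == "III", "III",
         ifelse(loops$loop_type == "I",
                paste0("I-", loops$coherence),
                paste0("II-", loops$subtype, "-", loops$coherence)))
}

#' Score and label a loop table
#'
#' Attaches to every Type I/II loop its three node-level unadjusted
#' p-values, the Fisher combined score, the consistency flag, and the
#' miRNA-target evidence category. Node directions are the signs of the
#' moderated t-statistics regardless of significance. Type III loops carry
#' no score or consistency flag (they involve genes, not specific loop-node
#' transcripts).
#'
#' @param loops Loop data.frame from the `build_type*` constructors.
#' @param mrna_results,mirna_results Full `"de_result"` tables.
#' @return The loop table with columns `p_mirna`, `p_tf`, `p_mrna`,
#'   `score`, `consistent` (`"consistent"`/`"inconsistent"`/`""`) and
#'   `evidence_category` added.
#' @export
score_loops <- function(loops, mrna_results, mirna_results) {
  n <- nrow(loops)
  loops$p_mirna <- loops$p_tf <- loops$p_mrna <- rep(NA_real_, n)
  loops$score <- rep(NA_real_, n)
  loops$consistent <- rep("", n)
  loops$evidence_category <- label_evidence(loops$evidence)
  ffl <- loops$loop_type %in% c("I", "II")
  if (any(ffl)) {
    mi <- match(loops$mirna[ffl], mirna_results$feature_id)
    ti <- match(loops$tf_or_gene1[ffl], mrna_results$feature_id)
    gi <- match(loops$mrna_or_gene2[ffl], mrna_results$feature_id)
    if (anyNA(mi) || anyNA(ti) || anyNA(gi))
      stop("loop node(s) missing from the expression results")
    p1 <- mirna_results$p[mi]
    p2 <- mrna_results$p[ti]
    p3 <- mrna_results$p[gi]
    fs <- fisher_score(p1, p2, p3)
    loops$p_mirna[ffl] <- p1
    loops$p_tf[ffl] <- p2
    loops$p_mrna[ffl] <- p3
    loops$score[ffl] <- fs$score
    cons <- label_consistency(
      loops$loop_type[ffl],
      ifelse(loops$loop_type[ffl] == "II", loops$tf_mirna_sign[ffl], NA),
      mirna_results$direction[mi],
      mrna_results$direction[ti],
      mrna_results$direction[gi]
    )
    loops$consistent[ffl] <- ifelse(cons, "consistent", "inconsistent")
  }
  loops
}

#' Group and rank scored loops
#'
#' Sorts loops into the seven output groups (Type I coherent/incoherent,
#' Type II-A coherent/incoherent, Type II-B coherent/incoherent, Type III)
#' and ranks Type I/II loops within each group by ascending Fisher score
#' (rank 1 = most significant; lower scores mean higher significance). Ties
#' are broken lexicographically on (miRNA, TF, mRNA) for reproducibility.
#' Type III loops are grouped but carry no rank.
#'
#' @param loops A scored loop data.frame from [score_loops()].
#' @return The loop table with `group` and `rank` columns, ordered by group
#'   then rank.
#' @export
rank_and_group <- function(loops) {
  loops$group <- loop_group(loops)
  loops$rank <- rep(NA_integer_, nrow(loops))
  for (g in unique(loops$group)) {
    idx <- which(loops$group == g)
    if (g == "III" || length(idx) == 0L) next
    sub <- loops[idx, , drop = FALSE]
    ord <- order(sub$score, sub$mirna, sub$tf_or_gene1, sub$mrna_or_gene2)
    loops$rank[idx[ord]] <- seq_along(idx)
  }
  out <- loops[order(loops$group, ifelse(is.na(loops$rank), 0L, loops$rank)),
               , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @rdname rank_and_group
#' @return `loop_groups()` returns the seven group labels.
#' @export
loop_groups <- function() {
  c("I-coherent", "I-incoherent", "II-A-coherent", "II-A-incoherent",
    "II-B-coherent", "II-B-incoherent", "III")
}
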