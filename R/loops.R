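# Construction of three-node regulatory loops from the restricted prior:
# Type I   miRNA -| TF, miRNA -| mRNA, TF -> mRNA (miRNA upstream)
# Type II  TF -> miRNA, TF -> mRNA, miRNA -| mRNA (TF upstream; subtype A/B
#          by whether the TF activates or represses the mRNA)
# Type III miRNA targeting both endpoints of a direct pathway interaction.
# Coherence compares the signs of the two regulator-to-target paths; every
# miRNA-target edge carries sign -1 (repression).

sign_of <- function(regulation) ifelse(regulation == "activation", 1L, -1L)

empty_loops <- function() {
  data.frame(loop_type = character(0), subtype = character(0),
             coherence = character(0), mirna = character(0),
             tf_or_gene1 = character(0), mrna_or_gene2 = character(0),
             tf_mrna_sign = character(0), tf_mirna_sign = character(0),
             pathway_id = character(0), evidence = character(0),
             stringsAsFactors = FALSE)
}

#' Restrict the prior database to deregulated regulators
#'
#' Keeps TF-gene edges whose TF is in the combined mRNA deregulation list
#' and whose target is measured; TF-miRNA edges whose TF is combined-list
#' mRNA and whose miRNA is combined-list miRNA; and miRNA-gene edges whose
#' miRNA is in the combined miRNA list and whose target is measured. Target
#' mRNAs themselves need not be differentially expressed.
#'
#' @param priordb A `"prior_db"`.
#' @param combined_mrna,combined_mirna Combined deregulation lists from
#'   [combine_lists()] (or any data.frame with a `feature_id` column /
#'   character vector of ids).
#' @param universe Features measured in the mRNA matrix.
#' @return A `"prior_db"` with the restricted tables.
#' @export
restrict_priors <- function(priordb, combined_mrna, combined_mirna, universe) {
  ids <- function(x) if (is.data.frame(x)) x$feature_id else as.character(x)
  mrna_ids <- ids(combined_mrna)
  mirna_ids <- ids(combined_mirna)
  tg <- priordb$tf_gene
  tg <- tg[tg$regulator %in% mrna_ids & tg$target %in% universe, , drop = FALSE]
  tm <- priordb$tf_mirna
  tm <- tm[tm$regulator %in% mrna_ids & tm$target %in% mirna_ids, , drop = FALSE]
  mg <- priordb$mirna_gene
  mg <- mg[mg$regulator %in% mirna_ids & mg$target %in% universe, , drop = FALSE]
  prior_db(tf_gene = tg, tf_mirna = tm, mirna_gene = mg)
}

#' Classify a feed-forward loop's subtype and coherence
#'
#' The two paths from the upstream regulator to the target mRNA either agree
#' in net sign (coherent) or oppose each other (incoherent). For a Type I
#' loop (miRNA upstream) the direct path is the miRNA's repression (-) and
#' the indirect path runs miRNA -| TF -> mRNA, so the loop is coherent
#' exactly when the TF activates the mRNA. For Type II (TF upstream) the
#' direct path is the TF's regulation of the mRNA (subtype A when
#' activation, B when repression) and the indirect path composes the TF's
#' regulation of the miRNA with the miRNA's repression of the mRNA.
#'
#' @param loop_type `"I"` or `"II"`.
#' @param tf_mrna_sign `"activation"` or `"repression"` (TF -> mRNA edge).
#' @param tf_mirna_sign `"activation"`/`"repression"` for Type II; `NA` for
#'   Type I (which has no TF -> miRNA edge).
#' @return A list with elements `subtype` (`"A"`, `"B"` or `"none"`) and
#'   `coherence` (`"coherent"`/`"incoherent"`). Vectorized over edges.
#' @export
classify_subtype <- function(loop_type, tf_mrna_sign, tf_mirna_sign = NA) {
  stopifnot(all(loop_type %in% c("I", "II")),
            all(tf_mrna_sign %in% c("activation", "repression")))
  n <- max(length(loop_type), length(tf_mrna_sign), length(tf_mirna_sign))
  loop_type <- rep_len(loop_type, n)
  tf_mrna_sign <- rep_len(tf_mrna_sign, n)
  tf_mirna_sign <- rep_len(tf_mirna_sign, n)
  if (any(loop_type == "II" & is.na(tf_mirna_sign)))
    stop("Type II loops need a TF->miRNA regulation sign")
  if (any(loop_type == "I" & !is.na(tf_mirna_sign)))
    stop("Type I loops have no TF->miRNA edge")
  if (!all(tf_mirna_sign[loop_type == "II"] %in% c("activation", "repression")))
    stop("invalid TF->miRNA regulation sign")
  s1 <- sign_of(tf_mrna_sign)
  direct <- ifelse(loop_type == "I", -1L, s1)
  indirect <- ifelse(loop_type == "I",
                     -1L * s1,                      # miRNA -| TF -> mRNA
                     sign_of(tf_mirna_sign) * -1L)  # TF -> miRNA -| mRNA
  list(
    subtype = ifelse(loop_type == "I", "none", ifelse(s1 > 0, "A", "B")),
    coherence = ifelse(direct == indirect, "coherent", "incoherent")
  )
}

#' Construct Type I feed-forward loops
#'
#' Forms one loop per triplet (miRNA, TF, mRNA) such that the restricted
#' prior contains the TF -> mRNA edge and the miRNA targets both the TF
#' transcript and the mRNA. The TF transcript is identified by the same gene
#' id it carries in the expression matrix.
#'
#' @param tf_gene,mirna_gene Restricted edge tables (see
#'   [restrict_priors()]).
#' @return A loop data.frame (one row per loop) with subtype/coherence
#'   classification and the miRNA->mRNA evidence label.
#' @export
build_type1 <- function(tf_gene, mirna_gene) {
  if (nrow(tf_gene) == 0L || nrow(mirna_gene) == 0L) return(empty_loops())
  # miRNAs hitting each TF transcript
  m_tf <- mirna_gene[, c("regulator", "target")]
  names(m_tf) <- c("mirna", "tf")
  tg <- tf_gene[, c("regulator", "target", "regulation")]
  names(tg) <- c("tf", "mrna", "tf_mrna_sign")
  pairs <- merge(m_tf, tg, by = "tf")
  if (nrow(pairs) == 0L) return(empty_loops())
  mg <- mirna_gene[, c("regulator", "target", "evidence")]
  names(mg) <- c("mirna", "mrna", "evidence")
  trip <- merge(pairs, mg, by = c("mirna", "mrna"))
  trip <- trip[trip$tf != trip$mrna, , drop = FALSE]
  if (nrow(trip) == 0L) return(empty_loops())
  cls <- classify_subtype("I", trip$tf_mrna_sign)
  out <- data.frame(loop_type = "I", subtype = "none",
                    coherence = cls$coherence, mirna = trip$mirna,
                    tf_or_gene1 = trip$tf, mrna_or_gene2 = trip$mrna,
                    tf_mrna_sign = trip$tf_mrna_sign, tf_mirna_sign = "",
                    pathway_id = "", evidence = trip$evidence,
                    stringsAsFactors = FALSE)
  order_loops(out)
}

#' Construct Type II feed-forward loops
#'
#' Crosses every (TF, miRNA) pair in the restricted TF->miRNA table with the
#' mRNAs regulated by the TF and simultaneously targeted by the miRNA, and
#' classifies subtype (A/B) and coherence from the two TF edge signs.
#'
#' @param tf_mirna,tf_gene,mirna_gene Restricted edge tables.
#' @return A loop data.frame.
#' @export
build_type2 <- function(tf_mirna, tf_gene, mirna_gene) {
  if (nrow(tf_mirna) == 0L || nrow(tf_gene) == 0L || nrow(mirna_gene) == 0L)
    return(empty_loops())
  tm <- tf_mirna[, c("regulator", "target", "regulation")]
  names(tm) <- c("tf", "mirna", "tf_mirna_sign")
  tg <- tf_gene[, c("regulator", "target", "regulation")]
  names(tg) <- c("tf", "mrna", "tf_mrna_sign")
  pairs <- merge(tm, tg, by = "tf")
  if (nrow(pairs) == 0L) return(empty_loops())
  mg <- mirna_gene[, c("regulator", "target", "evidence")]
  names(mg) <- c("mirna", "mrna", "evidence")
  trip <- merge(pairs, mg, by = c("mirna", "mrna"))
  trip <- trip[trip$tf != trip$mrna, , drop = FALSE]
  if (nrow(trip) == 0L) return(empty_loops())
  cls <- classify_subtype("II", trip$tf_mrna_sign, trip$tf_mirna_sign)
  out <- data.frame(loop_type = "II", subtype = cls$subtype,
                    coherence = cls$coherence, mirna = trip$mirna,
                    tf_or_gene1 = trip$tf, mrna_or_gene2 = trip$mrna,
                    tf_mrna_sign = trip$tf_mrna_sign,
                    tf_mirna_sign = trip$tf_mirna_sign,
                    pathway_id = "", evidence = trip$evidence,
                    stringsAsFactors = FALSE)
  order_loops(out)
}

#' Construct Type III pathway loops
#'
#' For each significant pathway, takes the direct (physical-interaction)
#' gene pairs whose two endpoints are both expressed and forms one loop per
#' (miRNA, pair) such that the miRNA targets both endpoint transcripts.
#' Pairs are unordered: endpoints are reported in lexicographic order, and
#' the evidence label combines the two miRNA-target edges (the weaker of the
#' two when they differ).
#'
#' @param pathway_edges Pathway edge data.frame
#'   (see [read_pathway_edges()]).
#' @param mirna_gene Restricted miRNA-target edge table.
#' @param expressed_genes Features present in the mRNA matrix.
#' @param significant_pathways Pathway ids flagged by enrichment.
#' @return A loop data.frame (`subtype`, `coherence` are `"none"`).
#' @export
build_type3 <- function(pathway_edges, mirna_gene, expressed_genes,
                        significant_pathways) {
  pe <- pathway_edges[pathway_edges$pathway_id %in% significant_pathways &
                        pathway_edges$effect == "direct" &
                        pathway_edges$gene1 %in% expressed_genes &
                        pathway_edges$gene2 %in% expressed_genes, , drop = FALSE]
  if (nrow(pe) == 0L || nrow(mirna_gene) == 0L) return(empty_loops())
  mg <- mirna_gene[, c("regulator", "target", "evidence")]
  names(mg) <- c("mirna", "gene", "evidence")
  e1 <- merge(pe, mg, by.x = "gene1", by.y = "gene")
  names(e1)[names(e1) == "evidence"] <- "evidence1"
  both <- merge(e1, mg, by.x = c("gene2", "mirna"), by.y = c("gene", "mirna"))
  if (nrow(both) == 0L) return(empty_loops())
  # combined evidence: both edges must be "both" for true-positive-grade
  ev_rank <- c(predicted = 1L, validated = 2L, both = 3L)
  ev <- ifelse(ev_rank[both$evidence1] < ev_rank[both$evidence],
               both$evidence1, both$evidence)
  out <- data.frame(loop_type = "III", subtype = "none", coherence = "none",
                    mirna = both$mirna, tf_or_gene1 = both$gene1,
                    mrna_or_gene2 = both$gene2, tf_mrna_sign = "",
                    tf_mirna_sign = "", pathway_id = both$pathway_id,
                    evidence = unname(ev), stringsAsFactors = FALSE)
  out <- unique(out)
  order_loops(out)
}

order_loops <- function(loops) {
  out <- loops[order(loops$loop_type, loops$subtype, loops$coherence,
                     loops$mirna, loops$tf_or_gene1, loops$mrna_or_gene2,
                     loops$pathway_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a loop table to TSV
#'
#' @param loops Loop data.frame (optionally scored/ranked).
#' @param path Output TSV path.
#' @export
write_loops <- function(loops, path) {
  utils::write.table(loops, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
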