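# End-to-end orchestration: preprocess -> moderated-t/SVA -> GSEA ->
# combined lists -> prior restriction -> loop construction -> scoring ->
# summaries, from a single flat YAML configuration.

default_run_options <- function() {
  list(quantile_normalize = FALSE, use_sva = TRUE, n_sv = NULL,
       n_permutations = 100L, sva_alpha = 0.10)
}

#' Run the full loop-detection pipeline
#'
#' Executes every stage from files named in a flat YAML configuration (or an
#' equivalent named list): expression and design input, optional quantile
#' normalization, surrogate-variable-adjusted moderated-t differential
#' expression for mRNAs and miRNAs, rank-sum gene-set enrichment over the
#' TF/miRNA/pathway set families, combined deregulation lists, prior
#' restriction, Type I/II/III loop construction, Fisher scoring with
#' consistency and evidence labels, within-group ranking, and summary
#' tables. Every intermediate and final table is written to `out_dir` as
#' TSV, plus a JSON run manifest recording the package version, seed,
#' thresholds and input checksums. Outputs are a pure function of (inputs,
#' config, seed); any stage failure aborts with the stage name.
#'
#' Configuration keys: input paths `mrna`, `mirna`, `design`, `tf_gene`,
#' `tf_mirna`, `mirna_pred`, `mirna_valid`, `tf_sets_gmt`,
#' `pathway_sets_gmt`, `pathway_edges`, `whitelist`; output directory
#' `out_dir`; options `quantile_normalize`, `use_sva`, `n_sv`,
#' `n_permutations`, `sva_alpha`; thresholds `fdr_de`, `fdr_gsea`,
#' `min_set_size`, `min_predictors`, `fc_threshold`; and `seed`.
#'
#' @param config Path to a YAML file or a named list of the keys above.
#' @return Invisibly, a list with every stage's in-memory result
#'   (`de_mrna`, `de_mirna`, `sv`, `gsea`, `combined_mrna`,
#'   `combined_mirna`, `loops`, `summaries`, `manifest`, `out_dir`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stage <- "configuration"
  abort <- function(e) stop("pipeline stage '", stage, "' failed: ",
                            conditionMessage(e), call. = FALSE)
  tryCatch({
    opts <- utils::modifyList(default_run_options(),
                              config[intersect(names(config),
                                               names(default_run_options()))])
    thr <- pipeline_config(
      fdr_de = config$fdr_de %||% 0.05,
      fdr_gsea = config$fdr_gsea %||% 0.25,
      min_set_size = config$min_set_size %||% 8,
      min_predictors = config$min_predictors %||% 2,
      fc_threshold = config$fc_threshold %||% 2,
      seed = config$seed %||% 1L
    )
    out_dir <- config$out_dir %||% stop("config needs an out_dir")
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

    stage <- "read expression"
    mrna <- read_expression(config$mrna, "mRNA")
    mirna <- read_expression(config$mirna, "miRNA")
    design <- read_design(config$design)
    if (isTRUE(opts$quantile_normalize)) {
      mrna <- quantile_normalize(mrna)
      mirna <- quantile_normalize(mirna)
    }
    message(sprintf("expression: %d mRNAs, %d miRNAs, %d samples",
                    nrow(mrna), nrow(mirna), ncol(mrna)))

    stage <- "read priors"
    priordb <- read_priors(config$tf_gene, config$tf_mirna,
                           config$mirna_pred, config$mirna_valid, thr)
    tf_sets_gmt <- if (!is.null(config$tf_sets_gmt) &&
                       file.exists(config$tf_sets_gmt))
      read_gmt(config$tf_sets_gmt) else list()
    pathway_sets <- if (!is.null(config$pathway_sets_gmt) &&
                        file.exists(config$pathway_sets_gmt))
      read_gmt(config$pathway_sets_gmt) else list()
    pathway_edges <- if (!is.null(config$pathway_edges) &&
                         file.exists(config$pathway_edges))
      read_pathway_edges(config$pathway_edges) else NULL
    whitelist <- if (!is.null(config$whitelist) &&
                     file.exists(config$whitelist))
      readLines(config$whitelist, warn = FALSE) else character(0)

    stage <- "surrogate variable analysis"
    sv <- NULL
    if (isTRUE(opts$use_sva)) {
      sv <- estimate_surrogate_variables(
        mrna, design, n_permutations = opts$n_permutations,
        alpha = opts$sva_alpha, seed = thr$seed, n_sv = opts$n_sv)
      message(sprintf("surrogate variables retained: %d", ncol(sv)))
    }

    stage <- "differential expression"
    de_mrna <- fit_moderated_t(mrna, design, covariates = sv)
    de_mirna <- fit_moderated_t(mirna, design)
    mht_mrna <- call_differential(de_mrna, thr$fdr_de)
    mht_mirna <- call_differential(de_mirna, thr$fdr_de)
    message(sprintf("MHT calls at FDR %.3g: %d mRNAs, %d miRNAs",
                    thr$fdr_de, nrow(mht_mrna), nrow(mht_mirna)))
    write_de_results(de_mrna, file.path(out_dir, "de_mrna.tsv"))
    write_de_results(de_mirna, file.path(out_dir, "de_mirna.tsv"))

    stage <- "gene set enrichment"
    universe <- de_mrna$feature_id
    tf_sets <- restrict_tf_gmt(tf_sets_gmt, universe, de_mrna, thr)
    if (length(tf_sets) == 0L)
      tf_sets <- build_tf_sets(priordb, universe, de_mrna, thr)
    mirna_sets <- build_mirna_sets(priordb, whitelist, universe, de_mirna, thr)
    pw_sets <- lapply(pathway_sets, intersect, y = universe)
    pw_sets <- pw_sets[lengths(pw_sets) > 0L &
                         lengths(pw_sets) < length(universe)]
    gsea <- run_gsea(tf_sets, mirna_sets, pw_sets, de_mrna, de_mirna, thr)
    message(sprintf("GSEA: %d TF sets, %d miRNA sets, %d pathway sets tested",
                    length(tf_sets), length(mirna_sets), length(pw_sets)))
    utils::write.table(gsea, file.path(out_dir, "gsea.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)

    stage <- "combine deregulation lists"
    combined_mrna <- combine_lists(
      mht_mrna, gsea[gsea$index_kind == "TF", , drop = FALSE],
      de_mrna, thr$fdr_gsea)
    combined_mirna <- combine_lists(
      mht_mirna, gsea[gsea$index_kind == "miRNA", , drop = FALSE],
      de_mirna, thr$fdr_gsea)
    message(sprintf("combined lists: %d mRNAs (%d GSEA-rescued), %d miRNAs (%d GSEA-rescued)",
                    nrow(combined_mrna), sum(combined_mrna$source == "GSEA"),
                    nrow(combined_mirna), sum(combined_mirna$source == "GSEA")))
    utils::write.table(combined_mrna, file.path(out_dir, "combined_mrna.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(combined_mirna, file.path(out_dir, "combined_mirna.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    stage <- "loop construction"
    restricted <- restrict_priors(priordb, combined_mrna, combined_mirna,
                                  universe)
    sig_pathways <- gsea$set_id[gsea$index_kind == "pathway" &
                                  gsea$fdr <= thr$fdr_gsea]
    loops <- rbind(
      build_type1(restricted$tf_gene, restricted$mirna_gene),
      build_type2(restricted$tf_mirna, restricted$tf_gene,
                  restricted$mirna_gene),
      if (!is.null(pathway_edges))
        build_type3(pathway_edges, restricted$mirna_gene, universe,
                    sig_pathways) else empty_loops()
    )

    stage <- "scoring and ranking"
    loops <- score_loops(loops, de_mrna, de_mirna)
    loops <- rank_and_group(loops)
    counts <- table(factor(loops$group, levels = loop_groups()))
    message("loops per group: ",
            paste(sprintf("%s=%d", names(counts), counts), collapse = ", "))
    write_loops(loops, file.path(out_dir, "loops.tsv"))
    for (g in unique(loops$group))
      write_loops(loops[loops$group == g, , drop = FALSE],
                  file.path(out_dir, paste0("loops_", g, ".tsv")))

    stage <- "summaries"
    summaries <- list()
    if (any(loops$loop_type %in% c("I", "II"))) {
      summaries$subtype_fractions <- subtype_fractions(loops)
      utils::write.table(summaries$subtype_fractions,
                         file.path(out_dir, "subtype_fractions.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      summaries$mirna_attribution <- mirna_attribution(
        loops, mht_mrna,
        stats::setNames(de_mirna$direction, de_mirna$feature_id))
      utils::write.table(summaries$mirna_attribution$per_mirna,
                         file.path(out_dir, "mirna_attribution.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      summaries$mirna_tf_pairs <- extract_mirna_tf_pairs(loops, de_mrna,
                                                         de_mirna)
      utils::write.table(summaries$mirna_tf_pairs,
                         file.path(out_dir, "mirna_tf_pairs.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }

    stage <- "manifest"
    input_keys <- c("mrna", "mirna", "design", "tf_gene", "tf_mirna",
                    "mirna_pred", "mirna_valid", "tf_sets_gmt",
                    "pathway_sets_gmt", "pathway_edges", "whitelist")
    inputs <- unlist(config[intersect(input_keys, names(config))])
    inputs <- inputs[file.exists(inputs)]
    manifest <- list(
      package = "mirloop",
      version = as.character(utils::packageVersion("mirloop")),
      seed = thr$seed,
      thresholds = unclass(thr),
      options = opts,
      input_checksums = as.list(tools::md5sum(inputs)),
      counts = list(
        n_mrna = nrow(mrna), n_mirna = nrow(mirna), n_samples = ncol(mrna),
        n_sv = if (is.null(sv)) 0L else ncol(sv),
        mht_mrna = nrow(mht_mrna), mht_mirna = nrow(mht_mirna),
        combined_mrna = nrow(combined_mrna),
        combined_mirna = nrow(combined_mirna),
        sets_tested = c(TF = length(tf_sets), miRNA = length(mirna_sets),
                        pathway = length(pw_sets)),
        loops_per_group = as.list(unclass(counts))
      )
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(list(de_mrna = de_mrna, de_mirna = de_mirna, sv = sv,
                   gsea = gsea, combined_mrna = combined_mrna,
                   combined_mirna = combined_mirna, loops = loops,
                   summaries = summaries, manifest = manifest,
                   out_dir = out_dir))
  }, error = abort)
}

# TF family sets from an externally supplied GMT (e.g. TF-target signatures):
# keep sets whose indexing TF is measured but not MHT-significant, restricted
# to the universe.
restrict_tf_gmt <- function(sets, universe, de_results, config) {
  if (length(sets) == 0L) return(list())
  fdr <- de_results$fdr[match(names(sets), de_results$feature_id)]
  sets <- sets[!is.na(fdr) & fdr > config$fdr_de]
  sets <- lapply(sets, intersect, y = universe)
  sets[lengths(sets) > 0L & lengths(sets) < length(universe)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
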