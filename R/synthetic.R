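# Synthetic two-condition expression study with planted ground truth.
# Emulates the structure of a paired normal/tumor microarray design with a
# hidden binary molecular-subtype factor (e.g. gene-fusion status): Gaussian
# log2 expression, a subset of features shifted between conditions, an
# optional batch/subtype effect on a fraction of features, and a regulatory
# prior with planted feed-forward loops of every subtype plus decoy edges
# among null features.

#' Simulation configuration
#'
#' Defaults describe the reference synthetic bundle used throughout the
#' package's validation: 2000 genes and 40 miRNAs over 20 samples per
#' condition, 100 differentially expressed genes and 10 miRNAs with
#' |log2 effect| 2 and noise sd 0.25, two planted loops per feed-forward
#' subtype (one designated consistent, one inconsistent) plus two Type III
#' loops, and 30 decoy loop skeletons among null features.
#'
#' @param n_genes,n_mirnas Number of gene and miRNA features.
#' @param n_per_condition Samples per condition (same samples measured on
#'   both platforms, i.e. a matched design).
#' @param n_de_genes,n_de_mirnas Number of planted differentially expressed
#'   features (random +1/-1 directions).
#' @param effect Absolute log2 condition effect for planted DE features.
#' @param noise_sd Residual Gaussian sd (log2 units).
#' @param batch_effect Absolute log2 effect of the hidden subtype/batch
#'   factor (0 disables it).
#' @param batch_feature_frac Fraction of gene features carrying the batch
#'   effect (random sign per feature).
#' @param batch_alignment Probability that a sample's batch label equals its
#'   condition indicator (0.5 = independent, 1 = fully confounded).
#' @param n_planted Named integer vector of planted loop counts per group
#'   (names from [loop_groups()]).
#' @param n_decoy_loops Number of decoy loop skeletons built from non-DE
#'   features.
#' @param predictor_range Range of predictor counts for predicted
#'   miRNA-target edges.
#' @param seed Integer seed.
#' @return A list of class `"sim_config"`.
#' @export
simulation_config <- function(n_genes = 2000L, n_mirnas = 40L,
                              n_per_condition = 20L, n_de_genes = 100L,
                              n_de_mirnas = 10L, effect = 2, noise_sd = 0.25,
                              batch_effect = 0, batch_feature_frac = 0.4,
                              batch_alignment = 0.5,
                              n_planted = c("I-coherent" = 2L,
                                            "I-incoherent" = 2L,
                                            "II-A-coherent" = 2L,
                                            "II-A-incoherent" = 2L,
                                            "II-B-coherent" = 2L,
                                            "II-B-incoherent" = 2L,
                                            "III" = 2L),
                              n_decoy_loops = 30L,
                              predictor_range = c(2L, 5L), seed = 1L) {
  stopifnot(n_genes > 0, n_mirnas > 0, n_per_condition >= 2,
            n_de_genes >= 0, n_de_mirnas >= 0, is.finite(effect),
            noise_sd > 0, batch_alignment >= 0, batch_alignment <= 1,
            all(names(n_planted) %in% loop_groups()))
  structure(list(n_genes = as.integer(n_genes),
                 n_mirnas = as.integer(n_mirnas),
                 n_per_condition = as.integer(n_per_condition),
                 n_de_genes = as.integer(n_de_genes),
                 n_de_mirnas = as.integer(n_de_mirnas),
                 effect = effect, noise_sd = noise_sd,
                 batch_effect = batch_effect,
                 batch_feature_frac = batch_feature_frac,
                 batch_alignment = batch_alignment,
                 n_planted = n_planted,
                 n_decoy_loops = as.integer(n_decoy_loops),
                 predictor_range = as.integer(predictor_range),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate two-condition expression data with hidden structure
#'
#' Draws baseline log2 levels per feature, adds the planted condition effect
#' (+/- `effect` in tumor for the DE features), the hidden subtype/batch
#' effect on a random fraction of gene features, and i.i.d. Gaussian noise.
#' Deterministic under `config$seed`.
#'
#' @param config A [simulation_config()].
#' @return A list with `mrna` and `mirna` expression matrices, `design`
#'   (the subtype column records the hidden batch label), and `truth`
#'   (ground-truth DE tables with true directions and the batch vector).
#' @export
simulate_expression <- function(config) {
  with_seed(config$seed, {
    np <- config$n_per_condition
    samples <- c(sprintf("N%02d", seq_len(np)), sprintf("T%02d", seq_len(np)))
    cond <- rep(c("normal", "tumor"), each = np)
    genes <- sprintf("g%04d", seq_len(config$n_genes))
    mirnas <- sprintf("mir%03d", seq_len(config$n_mirnas))

    de_genes <- sort(sample(genes, config$n_de_genes))
    de_gene_dir <- sample(c(1L, -1L), config$n_de_genes, replace = TRUE)
    de_mirnas <- sort(sample(mirnas, config$n_de_mirnas))
    de_mirna_dir <- sample(c(1L, -1L), config$n_de_mirnas, replace = TRUE)

    batch <- ifelse(stats::runif(2 * np) < config$batch_alignment,
                    cond == "tumor", cond != "tumor")
    batch <- as.integer(batch)

    make_matrix <- function(features, de_ids, de_dir, kind, with_batch) {
      base <- stats::runif(length(features), 4, 12)
      vals <- matrix(stats::rnorm(length(features) * length(samples),
                                  sd = config$noise_sd),
                     nrow = length(features),
                     dimnames = list(features, samples))
      vals <- vals + base
      idx <- match(de_ids, features)
      vals[idx, cond == "tumor"] <- vals[idx, cond == "tumor"] +
        de_dir * config$effect
      if (with_batch && config$batch_effect != 0) {
        nb <- round(config$batch_feature_frac * length(features))
        bfeat <- sample(seq_along(features), nb)
        bsign <- sample(c(1, -1), nb, replace = TRUE)
        vals[bfeat, batch == 1L] <- vals[bfeat, batch == 1L] +
          bsign * config$batch_effect
        attr(vals, "batch_features") <- features[bfeat]
      }
      expression_matrix(vals, kind)
    }

    mrna <- make_matrix(genes, de_genes, de_gene_dir, "mRNA", TRUE)
    mirna <- make_matrix(mirnas, de_mirnas, de_mirna_dir, "miRNA", FALSE)

    design <- data.frame(
      sample_id = samples, condition = cond,
      subtype = ifelse(batch == 1L, "subtype-pos", "subtype-neg"),
      pair_id = rep(sprintf("p%02d", seq_len(np)), 2),
      stringsAsFactors = FALSE
    )
    truth <- list(
      de_genes = data.frame(feature_id = de_genes, direction = de_gene_dir,
                            stringsAsFactors = FALSE),
      de_mirnas = data.frame(feature_id = de_mirnas, direction = de_mirna_dir,
                             stringsAsFactors = FALSE),
      batch = stats::setNames(batch, samples),
      batch_features = attr(unclass(mrna), "batch_features")
    )
    list(mrna = mrna, mirna = mirna, design = design, truth = truth)
  })
}

# Edge-sign table per planted group: s1 = TF->mRNA, s2 = TF->miRNA (Type II).
planted_sign_table <- function(group) {
  switch(group,
         "I-coherent" = list(type = "I", s1 = "activation", s2 = NA),
         "I-incoherent" = list(type = "I", s1 = "repression", s2 = NA),
         "II-A-coherent" = list(type = "II", s1 = "activation", s2 = "repression"),
         "II-A-incoherent" = list(type = "II", s1 = "activation", s2 = "activation"),
         "II-B-coherent" = list(type = "II", s1 = "repression", s2 = "activation"),
         "II-B-incoherent" = list(type = "II", s1 = "repression", s2 = "repression"),
         "III" = list(type = "III", s1 = NA, s2 = NA),
         stop("unknown loop group: ", group))
}

#' Plant a regulatory prior around the simulated ground truth
#'
#' Builds the four prior tables, gene-set families, pathway graph and miRNA
#' whitelist so that the configured number of loops of each subtype is
#' planted among differentially expressed regulators with edge signs
#' matching the subtype's sign table. Within each subtype, alternating
#' loops are designated consistent/inconsistent: regulator directions are
#' chosen to satisfy the regulator-pair relation, and the target mRNA is a
#' DE gene anti-correlated with the miRNA when the loop is designated
#' consistent (correlated when inconsistent). Planted miRNA-target edges
#' cycle through the evidence states (`both`, `predicted`, `validated`).
#' Decoy loop skeletons with the same edge structure are added among non-DE
#' features, plus under-supported predicted edges (1 predictor) that the
#' minimum-predictor filter must drop.
#'
#' @param config A [simulation_config()].
#' @param truth Ground truth from [simulate_expression()].
#' @return A list: `priordb` (a `"prior_db"`), `tf_sets` and `pathway_sets`
#'   (GMT-style lists), `pathway_edges` (data.frame), `whitelist`
#'   (character), `pred_table`/`valid_table` (the raw miRNA-target tables as
#'   written to disk), and `truth` with a `planted_loops` data.frame added.
#' @export
simulate_priors <- function(config, truth) {
  with_seed(config$seed + 1000L, {
    genes <- sprintf("g%04d", seq_len(config$n_genes))
    mirnas <- sprintf("mir%03d", seq_len(config$n_mirnas))
    de_g <- truth$de_genes
    de_m <- truth$de_mirnas
    null_genes <- setdiff(genes, de_g$feature_id)
    null_mirnas <- setdiff(mirnas, de_m$feature_id)

    tf_gene <- tf_mirna <- NULL
    pred <- valid <- NULL
    planted <- NULL
    evidence_cycle <- c("both", "predicted", "validated")
    ev_i <- 0L
    used_tf <- character(0)
    used_targets <- character(0)

    pick_gene <- function(direction, exclude) {
      pool <- de_g$feature_id[de_g$direction == direction &
                                !de_g$feature_id %in% exclude]
      if (length(pool) == 0L) stop("no DE gene with required direction available")
      pool[sample.int(length(pool), 1L)]
    }
    add_target_edge <- function(mirna, gene, evidence) {
      if (evidence %in% c("both", "predicted"))
        pred <<- rbind(pred, data.frame(
          mirna_id = mirna, target_gene = gene,
          n_predictors = sample(seq(config$predictor_range[1L],
                                    config$predictor_range[2L]), 1L),
          stringsAsFactors = FALSE))
      if (evidence %in% c("both", "validated"))
        valid <<- rbind(valid, data.frame(
          mirna_id = mirna, target_gene = gene, stringsAsFactors = FALSE))
    }

    ffl_groups <- setdiff(names(config$n_planted), "III")
    for (grp in ffl_groups) {
      signs <- planted_sign_table(grp)
      for (j in seq_len(config$n_planted[[grp]])) {
        consistent <- j %% 2L == 1L
        mi <- de_m[sample.int(nrow(de_m), 1L), ]
        d_m <- mi$direction
        d_t <- if (signs$type == "I") -d_m else sign_of(signs$s2) * d_m
        tf <- pick_gene(d_t, used_tf)
        used_tf <- c(used_tf, tf)
        d_g <- if (consistent) -d_m else d_m
        g <- pick_gene(d_g, c(tf, used_tf, used_targets))
        used_targets <- c(used_targets, g)
        ev_i <- ev_i + 1L
        ev <- evidence_cycle[(ev_i - 1L) %% 3L + 1L]
        tf_gene <- rbind(tf_gene, data.frame(
          tf_id = tf, target_gene = g, regulation = signs$s1,
          stringsAsFactors = FALSE))
        add_target_edge(mi$feature_id, g, ev)
        if (signs$type == "I") {
          add_target_edge(mi$feature_id, tf, "predicted")
        } else {
          tf_mirna <- rbind(tf_mirna, data.frame(
            tf_id = tf, target_mirna = mi$feature_id, regulation = signs$s2,
            stringsAsFactors = FALSE))
        }
        planted <- rbind(planted, data.frame(
          group = grp, loop_type = signs$type,
          mirna = mi$feature_id, tf_or_gene1 = tf, mrna_or_gene2 = g,
          tf_mrna_sign = signs$s1,
          tf_mirna_sign = ifelse(is.na(signs$s2), "", signs$s2),
          consistent = consistent, evidence = ev,
          pathway_id = "", stringsAsFactors = FALSE))
      }
    }

    # Type III: a "significant" pathway whose member genes are DE, with
    # direct interaction edges both targeted by a DE miRNA.
    pathway_edges <- NULL
    pathway_sets <- list()
    n3 <- if ("III" %in% names(config$n_planted)) config$n_planted[["III"]] else 0L
    if (n3 > 0L) {
      pw <- "PW_PLANTED"
      pw_members <- character(0)
      for (j in seq_len(n3)) {
        mi <- de_m[sample.int(nrow(de_m), 1L), ]
        g1 <- pick_gene(1L, c(used_tf, used_targets))
        g2 <- pick_gene(-1L, c(g1, used_tf, used_targets))
        used_targets <- c(used_targets, g1, g2)
        pair <- sort(c(g1, g2))
        pathway_edges <- rbind(pathway_edges, data.frame(
          pathway_id = pw, gene1 = pair[1L], gene2 = pair[2L],
          effect = "direct", stringsAsFactors = FALSE))
        add_target_edge(mi$feature_id, g1, "both")
        add_target_edge(mi$feature_id, g2, "both")
        pw_members <- union(pw_members, pair)
        planted <- rbind(planted, data.frame(
          group = "III", loop_type = "III", mirna = mi$feature_id,
          tf_or_gene1 = pair[1L], mrna_or_gene2 = pair[2L],
          tf_mrna_sign = "", tf_mirna_sign = "", consistent = NA,
          evidence = "both", pathway_id = pw, stringsAsFactors = FALSE))
      }
      # enrich the pathway set with further DE genes so the rank-sum test
      # flags it, plus an indirect edge that Type III construction must skip
      extra <- setdiff(de_g$feature_id, pw_members)
      pw_members <- union(pw_members, extra[seq_len(min(20L, length(extra)))])
      pathway_sets[[pw]] <- sort(pw_members)
      ind <- sort(sample(null_genes, 2L))
      pathway_edges <- rbind(pathway_edges, data.frame(
        pathway_id = pw, gene1 = ind[1L], gene2 = ind[2L],
        effect = "indirect", stringsAsFactors = FALSE))
      # a decoy pathway of null genes
      dg <- sample(null_genes, 12L)
      pathway_sets[["PW_DECOY"]] <- sort(dg)
      pathway_edges <- rbind(pathway_edges, data.frame(
        pathway_id = "PW_DECOY",
        gene1 = pmin(dg[1:6], dg[7:12]), gene2 = pmax(dg[1:6], dg[7:12]),
        effect = "direct", stringsAsFactors = FALSE))
    }

    # Decoy loop skeletons among null features (full edge structure, so any
    # false-positive regulator pair yields a competing loop).
    for (j in seq_len(config$n_decoy_loops)) {
      m <- null_mirnas[(j - 1L) %% length(null_mirnas) + 1L]
      tf <- sample(null_genes, 1L)
      g <- sample(setdiff(null_genes, tf), 1L)
      s1 <- sample(.regulation_levels, 1L)
      tf_gene <- rbind(tf_gene, data.frame(
        tf_id = tf, target_gene = g, regulation = s1, stringsAsFactors = FALSE))
      add_target_edge(m, g, "predicted")
      if (j %% 2L == 0L) {
        tf_mirna <- rbind(tf_mirna, data.frame(
          tf_id = tf, target_mirna = m,
          regulation = sample(.regulation_levels, 1L),
          stringsAsFactors = FALSE))
      } else {
        add_target_edge(m, tf, "predicted")
      }
    }
    # under-supported predictions that the min-predictor filter must drop
    for (j in seq_len(5L)) {
      pred <- rbind(pred, data.frame(
        mirna_id = sample(mirnas, 1L), target_gene = sample(null_genes, 1L),
        n_predictors = 1L, stringsAsFactors = FALSE))
    }
    if (is.null(pred))
      pred <- data.frame(mirna_id = character(0), target_gene = character(0),
                         n_predictors = integer(0), stringsAsFactors = FALSE)
    if (is.null(valid))
      valid <- data.frame(mirna_id = character(0), target_gene = character(0),
                          stringsAsFactors = FALSE)
    if (is.null(tf_gene))
      tf_gene <- data.frame(tf_id = character(0), target_gene = character(0),
                            regulation = character(0), stringsAsFactors = FALSE)
    if (is.null(tf_mirna))
      tf_mirna <- data.frame(tf_id = character(0), target_mirna = character(0),
                             regulation = character(0), stringsAsFactors = FALSE)
    pred <- pred[!duplicated(pred[, c("mirna_id", "target_gene")]), , drop = FALSE]
    valid <- unique(valid)
    tf_gene <- tf_gene[!duplicated(tf_gene[, c("tf_id", "target_gene")]), , drop = FALSE]
    tf_mirna <- tf_mirna[!duplicated(tf_mirna[, c("tf_id", "target_mirna")]), , drop = FALSE]

    priordb <- prior_db(
      tf_gene = data.frame(regulator = tf_gene$tf_id,
                           target = tf_gene$target_gene,
                           regulation = tf_gene$regulation,
                           evidence = "curated", n_predictors = 0L,
                           stringsAsFactors = FALSE),
      tf_mirna = data.frame(regulator = tf_mirna$tf_id,
                            target = tf_mirna$target_mirna,
                            regulation = tf_mirna$regulation,
                            evidence = "curated", n_predictors = 0L,
                            stringsAsFactors = FALSE),
      mirna_gene = merge_mirna_targets(pred$mirna_id, pred$target_gene,
                                       pred$n_predictors, valid$mirna_id,
                                       valid$target_gene,
                                       min_predictors = 2L)
    )
    # TF target sets (for the GSEA TF family): one per decoy TF
    tfs <- unique(tf_gene$tf_id)
    tf_sets <- lapply(tfs, function(tf)
      sort(unique(tf_gene$target_gene[tf_gene$tf_id == tf])))
    names(tf_sets) <- tfs
    whitelist <- sort(unique(c(de_m$feature_id, sample(null_mirnas,
                                                       min(5L, length(null_mirnas))))))
    truth$planted_loops <- planted
    list(priordb = priordb, tf_sets = tf_sets, pathway_sets = pathway_sets,
         pathway_edges = pathway_edges, whitelist = whitelist,
         pred_table = pred, valid_table = valid,
         tf_gene_table = tf_gene, tf_mirna_table = tf_mirna, truth = truth)
  })
}

#' Write a complete simulated input bundle to disk
#'
#' Generates expression, design, prior, gene-set, pathway and whitelist
#' files (plus the ground truth as JSON) in `dir`, in the exact schemas the
#' readers expect, so a full pipeline run can start from files alone.
#'
#' @param config A [simulation_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the written paths plus the in-memory
#'   simulation objects.
#' @export
write_simulation_bundle <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_expression(config)
  pri <- simulate_priors(config, sim$truth)
  paths <- list(
    mrna = file.path(dir, "mrna_expression.tsv"),
    mirna = file.path(dir, "mirna_expression.tsv"),
    design = file.path(dir, "design.tsv"),
    tf_gene = file.path(dir, "tf_gene.tsv"),
    tf_mirna = file.path(dir, "tf_mirna.tsv"),
    mirna_pred = file.path(dir, "mirna_targets_predicted.tsv"),
    mirna_valid = file.path(dir, "mirna_targets_validated.tsv"),
    tf_sets = file.path(dir, "tf_sets.gmt"),
    pathway_sets = file.path(dir, "pathway_sets.gmt"),
    pathway_edges = file.path(dir, "pathway_edges.tsv"),
    whitelist = file.path(dir, "mirna_whitelist.txt"),
    truth = file.path(dir, "ground_truth.json")
  )
  write_expression(sim$mrna, paths$mrna)
  write_expression(sim$mirna, paths$mirna)
  write_design(sim$design, paths$design)
  utils::write.table(pri$tf_gene_table, paths$tf_gene, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tm <- pri$tf_mirna_table
  if (is.null(tm)) tm <- data.frame(tf_id = character(0),
                                    target_mirna = character(0),
                                    regulation = character(0))
  utils::write.table(tm, paths$tf_mirna, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(pri$pred_table, paths$mirna_pred, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(pri$valid_table, paths$mirna_valid, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_gmt(pri$tf_sets, paths$tf_sets)
  if (length(pri$pathway_sets) > 0L)
    write_gmt(pri$pathway_sets, paths$pathway_sets)
  if (!is.null(pri$pathway_edges))
    write_pathway_edges(pri$pathway_edges, paths$pathway_edges)
  writeLines(pri$whitelist, paths$whitelist)
  truth <- pri$truth
  truth$batch <- as.list(truth$batch)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, list(sim = sim, priors = pri)))
}
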