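# Shared fixtures and independent oracles, all built in code.

tiny_expression_file <- function(path = tempfile(fileext = ".tsv"),
                                 body = NULL) {
  if (is.null(body)) {
    body <- c("feature_id\ts1\ts2\ts3\ts4",
              "g1\t1.0\t2.0\t3.0\t4.0",
              "g2\t2.5\t2.5\t2.5\t2.5",
              "g3\t0.1\t-0.2\t0.3\t-0.4")
  }
  writeLines(body, path)
  path
}

make_design <- function(n_normal, n_tumor, subtype = "unknown") {
  data.frame(
    sample_id = c(sprintf("N%02d", seq_len(n_normal)),
                  sprintf("T%02d", seq_len(n_tumor))),
    condition = rep(c("normal", "tumor"), c(n_normal, n_tumor)),
    subtype = subtype, pair_id = "", stringsAsFactors = FALSE
  )
}

make_expr <- function(values, kind = "mRNA") {
  expression_matrix(values, kind)
}

# de_result-shaped table for unit tests of downstream stages
make_de <- function(ids, p = NULL, t = NULL, delta = NULL, fdr = NULL) {
  n <- length(ids)
  if (is.null(t)) t <- rep(1, n)
  if (is.null(p)) p <- rep(0.5, n)
  if (is.null(delta)) delta <- t
  if (is.null(fdr)) fdr <- p
  structure(data.frame(feature_id = ids, delta = delta, t_mod = t, p = p,
                       fdr = fdr, direction = ifelse(t >= 0, 1L, -1L),
                       stringsAsFactors = FALSE),
            class = c("de_result", "data.frame"))
}

edge_df <- function(regulator, target, regulation = "repression",
                    evidence = "predicted", n_predictors = 2L) {
  data.frame(regulator = regulator, target = target, regulation = regulation,
             evidence = evidence, n_predictors = n_predictors,
             stringsAsFactors = FALSE)
}

# Independent O(n^3) join oracle for Type I loops
brute_type1 <- function(tf_gene, mirna_gene) {
  out <- NULL
  for (i in seq_len(nrow(mirna_gene))) for (j in seq_len(nrow(tf_gene))) {
    m <- mirna_gene$regulator[i]
    if (mirna_gene$target[i] != tf_gene$regulator[j]) next
    if (tf_gene$regulator[j] == tf_gene$target[j]) next
    hit <- mirna_gene$regulator == m & mirna_gene$target == tf_gene$target[j]
    if (any(hit))
      out <- rbind(out, data.frame(mirna = m, tf = tf_gene$regulator[j],
                                   mrna = tf_gene$target[j],
                                   stringsAsFactors = FALSE))
  }
  if (is.null(out)) out <- data.frame(mirna = character(0), tf = character(0),
                                      mrna = character(0))
  unique(out[order(out$mirna, out$tf, out$mrna), , drop = FALSE])
}

brute_type2 <- function(tf_mirna, tf_gene, mirna_gene) {
  out <- NULL
  for (i in seq_len(nrow(tf_mirna))) for (j in seq_len(nrow(tf_gene))) {
    if (tf_mirna$regulator[i] != tf_gene$regulator[j]) next
    if (tf_gene$regulator[j] == tf_gene$target[j]) next
    m <- tf_mirna$target[i]
    hit <- mirna_gene$regulator == m & mirna_gene$target == tf_gene$target[j]
    if (any(hit))
      out <- rbind(out, data.frame(mirna = m, tf = tf_gene$regulator[j],
                                   mrna = tf_gene$target[j],
                                   stringsAsFactors = FALSE))
  }
  if (is.null(out)) out <- data.frame(mirna = character(0), tf = character(0),
                                      mrna = character(0))
  unique(out[order(out$mirna, out$tf, out$mrna), , drop = FALSE])
}

# Path-sign oracle for coherence: product of edge signs along the two
# regulator-to-target paths must agree for a coherent loop.
oracle_coherence <- function(loop_type, s1, s2 = NA) {
  sgn <- function(x) ifelse(x == "activation", 1L, -1L)
  if (loop_type == "I") {
    direct <- -1L                    # miRNA -| mRNA
    indirect <- -1L * sgn(s1)        # miRNA -| TF -> mRNA
  } else {
    direct <- sgn(s1)                # TF -> mRNA
    indirect <- sgn(s2) * -1L        # TF -> miRNA -| mRNA
  }
  if (direct == indirect) "coherent" else "incoherent"
}

# All-edges consistency oracle: every edge relation must hold
# (activation => correlated, repression => anti-correlated).
oracle_all_edges_consistent <- function(loop_type, s1, s2, dm, dt, dg) {
  sgn <- function(x) ifelse(x == "activation", 1L, -1L)
  ok <- dm * dg == -1L                          # miRNA -| mRNA
  if (loop_type == "I") {
    ok <- ok && dm * dt == -1L                  # miRNA -| TF
  } else {
    ok <- ok && dt * dm == sgn(s2)              # TF -> miRNA
  }
  ok && dt * dg == sgn(s1)                      # TF -> mRNA
}

# One full synthetic-bundle pipeline run; returns results plus ground truth.
run_bundle <- function(seed, dir = tempfile("bundle"), ...) {
  cfg <- simulation_config(seed = seed, ...)
  b <- write_simulation_bundle(cfg, dir)
  res <- suppressMessages(run_pipeline(list(
    mrna = b$mrna, mirna = b$mirna, design = b$design,
    tf_gene = b$tf_gene, tf_mirna = b$tf_mirna,
    mirna_pred = b$mirna_pred, mirna_valid = b$mirna_valid,
    tf_sets_gmt = b$tf_sets, pathway_sets_gmt = b$pathway_sets,
    pathway_edges = b$pathway_edges, whitelist = b$whitelist,
    out_dir = file.path(dir, "out"), seed = seed)))
  list(res = res, truth = b$priors$truth, bundle = b)
}

loop_key <- function(d) paste(d$loop_type, d$mirna, d$tf_or_gene1,
                              d$mrna_or_gene2)
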