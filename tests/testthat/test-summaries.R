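# Post-hoc summaries: fractions, attribution, overlaps, pairs, queries.

make_loops <- function(n_per_group) {
  rows <- NULL
  i <- 0L
  for (g in names(n_per_group)) for (j in seq_len(n_per_group[[g]])) {
    i <- i + 1L
    parts <- strsplit(g, "-")[[1]]
    type <- parts[1]
    rows <- rbind(rows, data.frame(
      loop_type = type,
      subtype = if (type == "II") parts[2] else "none",
      coherence = if (type == "III") "none" else parts[length(parts)],
      mirna = sprintf("m%02d", i %% 4 + 1), tf_or_gene1 = sprintf("tf%02d", i),
      mrna_or_gene2 = sprintf("g%02d", i), tf_mrna_sign = "activation",
      tf_mirna_sign = if (type == "II") "activation" else "",
      pathway_id = if (type == "III") "P1" else "",
      evidence = "predicted",
      consistent = if (type == "III") "" else
        c("consistent", "inconsistent")[j %% 2 + 1],
      score = if (type == "III") NA_real_ else 0.01 * i,
      stringsAsFactors = FALSE))
  }
  rows
}

test_that("subtype fractions count the consistent/inconsistent cells", {
  one <- make_loops(c("I-coherent" = 1))
  one$consistent <- "consistent"
  sf <- subtype_fractions(one)
  expect_equal(sum(sf$fraction), 1)
  expect_equal(sf$fraction[sf$group == "I-coherent" &
                             sf$consistency == "consistent"], 1)
  expect_equal(sum(sf$count), 1L)

  ten <- make_loops(c("I-coherent" = 4, "II-A-incoherent" = 6))
  ten$consistent <- rep("inconsistent", 10)
  ten$consistent[ten$loop_type == "I"] <- "consistent"
  sf <- subtype_fractions(ten)
  expect_equal(sf$fraction[sf$group == "I-coherent" &
                             sf$consistency == "consistent"], 0.4)
  expect_equal(sum(sf$fraction), 1, tolerance = 1e-12)
  expect_error(subtype_fractions(make_loops(c("III" = 2))), "no Type I/II")
})

test_that("miRNA attribution splits consistent and inconsistent targets", {
  # 10 DE mRNAs; m1 is up and hits 2 DE mRNAs that are both down
  de <- make_de(sprintf("g%02d", 1:10), t = c(-1, -1, rep(1, 8)))
  loops <- data.frame(
    loop_type = "I", subtype = "none", coherence = "coherent",
    mirna = "m1", tf_or_gene1 = "tfX", mrna_or_gene2 = c("g01", "g02"),
    tf_mrna_sign = "activation", tf_mirna_sign = "", pathway_id = "",
    evidence = "predicted", consistent = "consistent",
    score = 0.01, stringsAsFactors = FALSE)
  att <- mirna_attribution(loops, de, mirna_directions = c(m1 = 1L))
  expect_equal(att$per_mirna$pct_consistent, 20)
  expect_equal(att$per_mirna$pct_inconsistent, 0)
  expect_equal(att$cumulative$cumulative_pct, 20)
  # flipping the miRNA direction makes the same targets inconsistent
  att2 <- mirna_attribution(loops, de, mirna_directions = c(m1 = -1L))
  expect_equal(att2$per_mirna$pct_consistent, 0)
  expect_equal(att2$per_mirna$pct_inconsistent, 20)
  # consistent + inconsistent = total, always
  expect_equal(att$per_mirna$pct_consistent + att$per_mirna$pct_inconsistent,
               att$per_mirna$pct_total)
})

test_that("the cumulative attribution curve is monotone and counts each mRNA once", {
  de <- make_de(sprintf("g%02d", 1:10), t = rep(-1, 10))
  loops <- NULL
  for (m in c("m1", "m2", "m3")) {
    tg <- switch(m, m1 = c("g01", "g02", "g03"), m2 = c("g02", "g03"),
                 m3 = c("g04"))
    loops <- rbind(loops, data.frame(
      loop_type = "I", subtype = "none", coherence = "coherent", mirna = m,
      tf_or_gene1 = "tfX", mrna_or_gene2 = tg, tf_mrna_sign = "activation",
      tf_mirna_sign = "", pathway_id = "", evidence = "predicted",
      consistent = "consistent", score = 0.01, stringsAsFactors = FALSE))
  }
  att <- mirna_attribution(loops, de,
                           mirna_directions = c(m1 = 1L, m2 = 1L, m3 = 1L))
  cum <- att$cumulative$cumulative_pct
  expect_true(all(diff(cum) >= 0))
  expect_lte(max(cum), 100)
  # overlap of m1 and m2 targets is not double counted: 4 distinct of 10
  expect_equal(max(cum), 40)
})

test_that("co-targeting overlaps equal brute-force region enumeration", {
  loops <- data.frame(
    loop_type = "I", subtype = "none", coherence = "coherent",
    mirna = c("m1", "m1", "m2", "m2"), tf_or_gene1 = "tfX",
    mrna_or_gene2 = c("a", "b", "b", "c"), tf_mrna_sign = "activation",
    tf_mirna_sign = "", pathway_id = "", evidence = "predicted",
    consistent = "consistent", score = 0.01, stringsAsFactors = FALSE)
  ov <- cotargeting_overlap(c("m1", "m2"), loops)
  expect_equal(ov$count[ov$region == "m1"], 1L)       # only a
  expect_equal(ov$count[ov$region == "m2"], 1L)       # only c
  expect_equal(ov$count[ov$region == "m1&m2"], 1L)    # b
  expect_equal(sum(ov$count), 3L)                     # size of the union

  # random sets against a bitmask oracle
  set.seed(800)
  for (rep in 1:5) {
    k <- sample(2:4, 1)
    mirnas <- sprintf("m%d", seq_len(k))
    rows <- NULL
    for (m in mirnas) {
      tg <- sample(letters[1:12], sample(3:8, 1))
      rows <- rbind(rows, data.frame(
        loop_type = "I", subtype = "none", coherence = "coherent", mirna = m,
        tf_or_gene1 = "tfX", mrna_or_gene2 = tg, tf_mrna_sign = "activation",
        tf_mirna_sign = "", pathway_id = "", evidence = "predicted",
        consistent = "consistent", score = 0.01, stringsAsFactors = FALSE))
    }
    ov <- cotargeting_overlap(mirnas, rows)
    sets <- lapply(mirnas, function(m) unique(rows$mrna_or_gene2[rows$mirna == m]))
    union_all <- unique(unlist(sets))
    mask <- vapply(union_all, function(g)
      sum(2^(which(vapply(sets, function(s) g %in% s, logical(1))) - 1)),
      numeric(1))
    for (i in seq_len(nrow(ov))) {
      members <- strsplit(ov$region[i], "&", fixed = TRUE)[[1]]
      bit <- sum(2^(match(members, mirnas) - 1))
      expect_equal(ov$count[i], sum(mask == bit))
    }
    expect_equal(sum(ov$count), length(union_all))
  }
})

test_that("miRNA-TF pairs are deduplicated and categorized by edge type", {
  de_mrna <- make_de(c("tfA", "tfB"), t = c(-2, 2))
  de_mirna <- make_de(c("m1", "m2"), t = c(2, 2))
  loops <- data.frame(
    loop_type = c("I", "I", "II"), subtype = c("none", "none", "A"),
    coherence = "coherent", mirna = c("m1", "m1", "m2"),
    tf_or_gene1 = c("tfA", "tfA", "tfB"),
    mrna_or_gene2 = c("g1", "g2", "g3"),
    tf_mrna_sign = "activation",
    tf_mirna_sign = c("", "", "activation"), pathway_id = "",
    evidence = "predicted", consistent = "consistent", score = 0.01,
    stringsAsFactors = FALSE)
  pairs <- extract_mirna_tf_pairs(loops, de_mrna, de_mirna)
  expect_equal(nrow(pairs), 2L)
  p1 <- pairs[pairs$mirna == "m1", ]
  expect_equal(p1$interaction, "miRNA-|TF")
  expect_equal(p1$n_loops, 2L)              # two loops, one pair entry
  expect_true(p1$pair_consistent)           # m1 up, tfA down, repressing edge
  p2 <- pairs[pairs$mirna == "m2", ]
  expect_equal(p2$interaction, "TF->miRNA") # activation passthrough
  expect_true(p2$pair_consistent)           # both up under activation
})

test_that("loop queries filter by node sets and are idempotent", {
  loops <- make_loops(c("I-coherent" = 3, "II-B-incoherent" = 2, "III" = 1))
  q <- query_loops(loops, mirna = loops$mirna[1],
                   tf_or_gene1 = loops$tf_or_gene1[1])
  expect_equal(nrow(q), 1L)
  expect_equal(query_loops(loops), loops)   # empty filter = identity
  f <- function(x) query_loops(x, loop_type = "I", consistency = "consistent")
  expect_equal(f(f(loops)), f(loops))
  # closed node list reproduces species-of-interest extraction
  keep <- c(loops$mirna[2], loops$tf_or_gene1[2], loops$mrna_or_gene2[2])
  q2 <- query_loops(loops, nodes = keep)
  expect_equal(nrow(q2), 1L)
  expect_equal(q2$tf_or_gene1, loops$tf_or_gene1[2])
})
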