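# Moderated t-statistics, variance-prior estimation, BH adjustment and
# surrogate-variable estimation.

test_that("moderated t reduces to the ordinary two-sample t when d0 = 0", {
  set.seed(101)
  n <- 6L
  Y <- matrix(rnorm(50 * 2 * n), nrow = 50,
              dimnames = list(sprintf("g%02d", 1:50),
                              c(sprintf("N%02d", 1:n), sprintf("T%02d", 1:n))))
  design <- make_design(n, n)
  fit <- fit_moderated_t(make_expr(Y), design, prior_df = 0)
  # independent oracle: classical pooled-variance two-sample t per feature
  for (i in c(1, 17, 50)) {
    tt <- stats::t.test(Y[i, design$condition == "tumor"],
                        Y[i, design$condition == "normal"], var.equal = TRUE)
    expect_equal(fit$t_mod[i], unname(tt$statistic), tolerance = 1e-9)
    expect_equal(fit$p[i], tt$p.value, tolerance = 1e-9)
    expect_equal(fit$delta[i], unname(diff(rev(tt$estimate))), tolerance = 1e-9)
  }
  expect_equal(fit$direction, ifelse(fit$t_mod >= 0, 1L, -1L))
})

test_that("d0 = Inf pools every posterior variance to s0^2", {
  set.seed(102)
  Y <- matrix(rnorm(40 * 10), nrow = 40,
              dimnames = list(sprintf("g%02d", 1:40),
                              c(sprintf("N%02d", 1:5), sprintf("T%02d", 1:5))))
  design <- make_design(5, 5)
  fit <- fit_moderated_t(make_expr(Y), design, prior_df = Inf)
  s0 <- attr(fit, "s0_sq")
  # all t statistics then share one variance: t proportional to delta
  expect_equal(fit$t_mod, fit$delta / (sqrt(s0) * sqrt(2 / 5)),
               tolerance = 1e-9)
})

test_that("variance-prior hyperparameters are recovered under the model", {
  set.seed(3)
  d0 <- 4; s0_sq <- 0.25; dg <- 18L; m <- 5000L
  sigma2 <- d0 * s0_sq / rchisq(m, df = d0)       # scaled inverse chi-square
  s2 <- sigma2 * rchisq(m, df = dg) / dg          # sampling distribution
  est <- estimate_variance_prior(s2, dg)
  expect_gt(est$d0, 3); expect_lt(est$d0, 5)
  expect_gt(est$s0_sq, 0.2); expect_lt(est$s0_sq, 0.3)
  # cross-check against the reference empirical-Bayes implementation
  sq <- limma::squeezeVar(s2, df = dg)
  expect_equal(est$d0, sq$df.prior, tolerance = 0.05)
  expect_equal(est$s0_sq, sq$var.prior, tolerance = 0.01)
})

test_that("full moderated fit agrees with the reference implementation", {
  set.seed(103)
  n <- 8L
  Y <- matrix(rnorm(300 * 2 * n, sd = rep(sqrt(0.5 / rchisq(300, 5) * 5), 2 * n)),
              nrow = 300,
              dimnames = list(sprintf("g%03d", 1:300),
                              c(sprintf("N%02d", 1:n), sprintf("T%02d", 1:n))))
  design <- make_design(n, n)
  fit <- fit_moderated_t(make_expr(Y), design)
  X <- cbind(1, design$condition == "tumor")
  lfit <- limma::eBayes(limma::lmFit(Y, X))
  expect_equal(fit$t_mod, lfit$t[, 2], tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(fit$p, lfit$p.value[, 2], tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(attr(fit, "d0"), lfit$df.prior, tolerance = 1e-4)
})

test_that("BH adjustment equals the naive step-up oracle", {
  naive_bh <- function(p) {
    m <- length(p)
    o <- order(p)
    ps <- p[o]
    adj <- vapply(seq_len(m), function(i)
      min(1, min(m * ps[i:m] / (i:m))), numeric(1))
    out <- numeric(m); out[o] <- adj
    out
  }
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(0.2, 7)), rep(0.2, 7))
  expect_identical(bh_adjust(numeric(0)), numeric(0))
  set.seed(104)
  for (i in 1:1000) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), naive_bh(p))
  }
})

test_that("differential calls and the fold-change filter apply inclusive thresholds", {
  de <- make_de(c("a", "b", "c", "d"), p = c(0.001, 0.01, 0.2, 0.9),
                fdr = c(0.004, 0.05, 0.4, 0.9),
                t = c(3, -2, 1, 0.1), delta = c(1.0, -1.0, 0.5, 0.05))
  called <- call_differential(de, 0.05)
  expect_equal(called$feature_id, c("a", "b"))   # fdr exactly 0.05 included
  expect_equal(nrow(call_differential(make_de("x", fdr = 1), 0.05)), 0L)
  kept <- fold_change_filter(called, 2)
  expect_equal(kept$feature_id, c("a", "b"))      # 2^1 = 2 and 2^-1 = 0.5
  expect_equal(fold_change_filter(de, 2)$feature_id, c("a", "b"))
  expect_equal(nrow(fold_change_filter(de, 1)), 4L)  # degenerate threshold
})

test_that("planted differential expression is recovered at controlled FDR", {
  cfg <- simulation_config(seed = 4L)
  sim <- simulate_expression(cfg)
  fit <- fit_moderated_t(sim$mrna, sim$design)
  called <- call_differential(fit, 0.05)$feature_id
  truth <- sim$truth$de_genes$feature_id
  expect_gte(mean(truth %in% called), 0.95)
  fdp <- sum(!called %in% truth) / max(1, length(called))
  expect_lte(fdp, 0.10)
  # directions of recovered features match the planted signs
  hit <- fit$feature_id %in% truth & fit$feature_id %in% called
  planted_dir <- sim$truth$de_genes$direction[
    match(fit$feature_id[hit], sim$truth$de_genes$feature_id)]
  expect_equal(fit$direction[hit], planted_dir)
})

test_that("type-I error is calibrated under the global null", {
  set.seed(105)
  hits <- 0L; total <- 0L
  for (s in 1:5) {
    Y <- matrix(rnorm(400 * 12), nrow = 400,
                dimnames = list(sprintf("g%03d", 1:400),
                                c(sprintf("N%02d", 1:6), sprintf("T%02d", 1:6))))
    fit <- fit_moderated_t(make_expr(Y), make_design(6, 6))
    hits <- hits + sum(fit$p < 0.05)
    total <- total + nrow(fit)
  }
  # binomial 99% bounds around alpha = 0.05
  bounds <- qbinom(c(0.005, 0.995), total, 0.05)
  expect_gte(hits, bounds[1]); expect_lte(hits, bounds[2])
})

test_that("surrogate variables capture a planted batch factor", {
  cfg <- simulation_config(n_genes = 800L, n_per_condition = 10L,
                           n_de_genes = 40L, effect = 2, noise_sd = 0.5,
                           batch_effect = 2.0, batch_feature_frac = 0.5,
                           batch_alignment = 0.5, seed = 1L)
  sim <- simulate_expression(cfg)
  sv <- estimate_surrogate_variables(sim$mrna, sim$design,
                                     n_permutations = 50, seed = 1L)
  expect_gte(ncol(sv), 1L)
  batch <- sim$truth$batch[colnames(sim$mrna)]
  expect_gt(abs(cor(sv[, 1], batch)), 0.9)
  # columns are orthonormal
  expect_equal(crossprod(sv), diag(ncol(sv)), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("surrogate-variable count is calibrated under unstructured noise", {
  # under pure i.i.d. noise, a component is retained with probability ~alpha,
  # so the k = 0 rate should sit near 1 - alpha = 0.90 up to Monte Carlo
  # error: check it against the 99% binomial band around 0.90 over 200 draws
  k0 <- 0L
  n_draws <- 200L
  for (s in seq_len(n_draws)) {
    set.seed(200 + s)
    Y <- matrix(rnorm(250 * 12), nrow = 250,
                dimnames = list(sprintf("g%03d", 1:250),
                                c(sprintf("N%02d", 1:6), sprintf("T%02d", 1:6))))
    sv <- estimate_surrogate_variables(make_expr(Y), make_design(6, 6),
                                       n_permutations = 50, alpha = 0.10,
                                       seed = s)
    if (ncol(sv) == 0L) k0 <- k0 + 1L
  }
  bounds <- qbinom(c(0.005, 0.995), n_draws, 0.90)
  expect_gte(k0, bounds[1]); expect_lte(k0, bounds[2])
})

test_that("forcing zero surrogate variables reproduces the unadjusted model", {
  set.seed(106)
  Y <- matrix(rnorm(100 * 12), nrow = 100,
              dimnames = list(sprintf("g%03d", 1:100),
                              c(sprintf("N%02d", 1:6), sprintf("T%02d", 1:6))))
  design <- make_design(6, 6)
  sv <- estimate_surrogate_variables(make_expr(Y), design, n_sv = 0)
  expect_equal(ncol(sv), 0L)
  f0 <- fit_moderated_t(make_expr(Y), design)
  f1 <- fit_moderated_t(make_expr(Y), design, covariates = sv)
  expect_equal(f0$t_mod, f1$t_mod)
  Y2 <- matrix(rnorm(50 * 12), nrow = 50,
               dimnames = list(sprintf("g%03d", 1:50),
                               c(sprintf("N%02d", 1:2), sprintf("T%02d", 1:10))))
  expect_error(estimate_surrogate_variables(make_expr(Y2), make_design(2, 10)),
               "at least 3 samples")
})

test_that("zero-variance features are dropped with a warning", {
  Y <- matrix(rnorm(20), nrow = 5,
              dimnames = list(paste0("g", 1:5),
                              c("N01", "N02", "T01", "T02")))
  Y[3, ] <- 7
  d <- make_design(2, 2)
  expect_warning(fit <- fit_moderated_t(make_expr(Y), d), "zero variance")
  expect_false("g3" %in% fit$feature_id)
})
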