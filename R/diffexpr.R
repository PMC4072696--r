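# Two-condition differential expression: ordinary least squares per feature,
# empirical-Bayes variance moderation (scaled-F prior on the residual
# variances, hyperparameters by closed-form moment matching on log s^2),
# optional surrogate-variable adjustment, Benjamini-Hochberg FDR control.

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

condition_indicator <- function(design) {
  as.numeric(design$condition == "tumor")
}

#' Estimate surrogate variables from the residual expression space
#'
#' Captures unmodeled structured heterogeneity (molecular subtype, batch) as
#' orthonormal covariates. The estimator is the two-step SVD/permutation
#' procedure: (1) regress every feature on the condition indicator and take
#' the residual matrix; (2) the candidate surrogate variables are its right
#' singular vectors, and the number retained is chosen by a permutation test
#' that compares each normalized singular value against its null distribution
#' obtained by permuting every feature's residuals independently
#' (`n_permutations` draws); leading components are kept while their
#' permutation p-value is at most `alpha`, stopping at the first
#' non-significant component.
#'
#' @param mat An [expression_matrix()] (features x samples).
#' @param design Sample design table (see [read_design()]).
#' @param n_permutations Number of permutation draws (default 100).
#' @param alpha Significance level for retaining a component (default 0.10).
#' @param seed Optional integer seed for the permutations.
#' @param n_sv Optional integer forcing the number of surrogate variables;
#'   when supplied the permutation test is skipped (`n_sv = 0` returns an
#'   empty covariate set and downstream fits equal the unadjusted model).
#' @return A samples x k numeric matrix of surrogate variables (k >= 0) with
#'   orthonormal columns.
#' @export
estimate_surrogate_variables <- function(mat, design, n_permutations = 100L,
                                         alpha = 0.10, seed = NULL,
                                         n_sv = NULL) {
  design <- align_design(mat, design)
  tab <- table(design$condition)
  if (any(tab < 3L))
    stop("surrogate variable estimation needs at least 3 samples per condition (got ",
         paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), ")")
  Y <- unclass(mat)
  X0 <- cbind(1, condition_indicator(design))
  fit <- lm.fit(X0, t(Y))
  R <- t(fit$residuals)                      # features x samples
  max_k <- min(dim(R)) - ncol(X0)
  if (max_k < 1L) return(matrix(numeric(0), nrow = ncol(Y), ncol = 0L))
  sv <- svd(R, nu = 0, nv = max_k)
  if (!is.null(n_sv)) {
    k <- min(as.integer(n_sv), max_k)
    return(sv$v[, seq_len(k), drop = FALSE])
  }
  d2 <- sv$d^2 / sum(sv$d^2)
  n_perm <- as.integer(n_permutations)
  if (n_perm < 1L) return(matrix(numeric(0), nrow = ncol(Y), ncol = 0L))
  exceed <- integer(max_k)
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      Rp <- t(apply(R, 1L, sample))
      fitp <- lm.fit(X0, t(Rp))
      Rp <- t(fitp$residuals)
      dp <- svd(Rp, nu = 0, nv = 0)$d^2
      dp <- dp / sum(dp)
      exceed <- exceed + (dp[seq_len(max_k)] >= d2[seq_len(max_k)])
    }
  })
  pvals <- (exceed + 1) / (n_perm + 1)
  k <- 0L
  for (i in seq_len(max_k)) {
    if (pvals[i] <= alpha) k <- i else break
  }
  sv$v[, seq_len(k), drop = FALSE]
}

#' Invert the trigamma function
#'
#' Solves `trigamma(y) = x` for `y > 0` by Newton iteration on `1/trigamma`,
#' which is nearly linear. Used by the moment-matching estimator of the
#' variance-prior degrees of freedom.
#'
#' @param x Positive numeric vector.
#' @return `y` with `trigamma(y) = x` (element-wise); `Inf` for `x <= 0`.
#' @keywords internal
trigamma_inverse <- function(x) {
  out <- numeric(length(x))
  out[x <= 0] <- Inf
  pos <- which(x > 0)
  if (length(pos) == 0L) return(out)
  xx <- x[pos]
  y <- 0.5 + 1 / xx
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / xx) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (max(abs(dif / y)) < 1e-10) break
  }
  out[pos] <- y
  out
}

#' Estimate the scaled-F prior on residual variances
#'
#' Given per-feature residual variances `s2` on `df` residual degrees of
#' freedom, assumes `s2 ~ s0^2 * F(df, d0)` and recovers the prior degrees of
#' freedom `d0` and prior variance `s0^2` by matching the first two moments
#' of `log(s2)`: with `e = log(s2) - digamma(df/2) + log(df/2)`,
#' `var(e) - trigamma(df/2) = trigamma(d0/2)` (solved by trigamma inversion)
#' and `mean(e) = log(s0^2) + digamma(d0/2) - log(d0/2)`. A non-positive
#' moment estimate yields `d0 = Inf` (all variances equal a priori).
#'
#' @param s2 Per-feature residual variances (positive).
#' @param df Residual degrees of freedom (scalar).
#' @return A list with elements `d0` and `s0_sq`.
#' @export
estimate_variance_prior <- function(s2, df) {
  stopifnot(length(df) == 1L, df > 0, all(s2 > 0))
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  n <- length(e)
  evar <- sum((e - emean)^2) / (n - 1L) - trigamma(df / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_sq <- exp(emean)
  }
  list(d0 = d0, s0_sq = s0_sq)
}

#' Moderated t-test for two-condition differential expression
#'
#' Fits, for every feature, the linear model
#' `expression ~ intercept + condition (+ surrogate variables)` by ordinary
#' least squares, shrinks the residual variances toward the empirical-Bayes
#' scaled-F prior estimated by [estimate_variance_prior()], and tests the
#' condition coefficient (`delta` = mean tumor minus mean normal, log2 units)
#' with the moderated t-statistic
#' `t = delta / (c * s_tilde)` where
#' `s_tilde^2 = (d0 * s0^2 + df * s2) / (d0 + df)` and `c` is the
#' coefficient's unscaled standard error. Two-sided p-values use a
#' t-distribution with `df + d0` degrees of freedom and are floored at
#' 1e-300. In the `d0 = 0` limit the statistic equals the ordinary
#' equal-variance t for the same model; with `d0 = Inf` every posterior
#' variance equals `s0^2`.
#'
#' Features with zero variance across all samples are dropped with a warning
#' rather than producing undefined statistics.
#'
#' @param mat An [expression_matrix()] (log2 values).
#' @param design Sample design table.
#' @param covariates Optional samples x k matrix of additional covariates
#'   (e.g. from [estimate_surrogate_variables()]).
#' @param prior_df Optional override for the prior degrees of freedom `d0`
#'   (e.g. `0` for no moderation, `Inf` for complete pooling); by default
#'   `d0` is estimated from the data.
#' @return A data.frame of class `"de_result"` with columns `feature_id`,
#'   `delta`, `t_mod`, `p`, `fdr` (Benjamini-Hochberg), `direction`
#'   (+1/-1, the sign of the moderated t), plus attributes `d0`, `s0_sq`,
#'   `df_residual`, `df_total`.
#' @export
fit_moderated_t <- function(mat, design, covariates = NULL, prior_df = NULL) {
  design <- align_design(mat, design)
  Y <- unclass(mat)
  zero_var <- apply(Y, 1L, function(r) max(r) == min(r))
  if (any(zero_var)) {
    warning(sum(zero_var), " feature(s) with zero variance dropped")
    Y <- Y[!zero_var, , drop = FALSE]
  }
  if (nrow(Y) == 0L) stop("no features with non-zero variance")
  X <- cbind(`(Intercept)` = 1, condition = condition_indicator(design))
  if (!is.null(covariates) && NCOL(covariates) > 0L) {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == ncol(Y))
    X <- cbind(X, covariates)
  }
  df <- ncol(Y) - ncol(X)
  if (df <= 0L) stop("non-positive residual degrees of freedom")
  fit <- lm.fit(X, t(Y))
  coefs <- t(fit$coefficients)
  delta <- coefs[, "condition"]
  res <- t(fit$residuals)
  s2 <- rowSums(res^2) / df
  if (all(s2 <= 0)) stop("all features have zero residual variance; degenerate input")
  s2 <- pmax(s2, .Machine$double.xmin)
  xtxinv <- chol2inv(qr.R(fit$qr))
  c_se <- sqrt(xtxinv[2L, 2L])
  if (is.null(prior_df)) {
    prior <- estimate_variance_prior(s2, df)
  } else if (prior_df == 0) {
    prior <- list(d0 = 0, s0_sq = mean(s2))
  } else {
    prior <- list(d0 = prior_df,
                  s0_sq = estimate_variance_prior(s2, df)$s0_sq)
  }
  d0 <- prior$d0
  s2_post <- if (is.infinite(d0)) rep(prior$s0_sq, length(s2)) else
    (d0 * prior$s0_sq + df * s2) / (d0 + df)
  t_mod <- delta / (sqrt(s2_post) * c_se)
  df_total <- df + d0
  p <- 2 * stats::pt(abs(t_mod), df = df_total, lower.tail = FALSE)
  p <- pmax(p, 1e-300)
  out <- data.frame(
    feature_id = rownames(Y),
    delta = unname(delta),
    t_mod = unname(t_mod),
    p = unname(p),
    fdr = bh_adjust(unname(p)),
    direction = ifelse(t_mod >= 0, 1L, -1L),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "d0") <- d0
  attr(out, "s0_sq") <- prior$s0_sq
  attr(out, "df_residual") <- df
  attr(out, "df_total") <- df_total
  class(out) <- c("de_result", "data.frame")
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Monotone step-up FDR-adjusted values, capped at 1; a thin wrapper around
#' [stats::p.adjust()] with `method = "BH"` kept as the module's single point
#' of adjustment.
#'
#' @param pvalues Numeric vector of p-values in (0, 1].
#' @return Adjusted values of the same length (empty input gives empty
#'   output).
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  stopifnot(all(pvalues > 0 & pvalues <= 1))
  stats::p.adjust(pvalues, method = "BH")
}

#' Call differentially expressed features
#'
#' Subsets a moderated-t result table to features with `fdr <= threshold`
#' (inclusive), retaining the direction of deregulation.
#'
#' @param results A `"de_result"` data.frame from [fit_moderated_t()].
#' @param threshold FDR threshold (default 0.05).
#' @return The significant subset, same columns.
#' @export
call_differential <- function(results, threshold = 0.05) {
  out <- results[results$fdr <= threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fold-change reporting filter
#'
#' Keeps features overexpressed by a linear fold change of at least
#' `fc_threshold` or repressed by at least its reciprocal, i.e.
#' `2^delta >= fc_threshold` or `2^delta <= 1/fc_threshold` (`delta` is on
#' the log2 scale). `fc_threshold = 1` passes everything.
#'
#' @param results A `"de_result"` data.frame.
#' @param fc_threshold Linear fold-change threshold (default 2).
#' @return The filtered subset.
#' @export
fold_change_filter <- function(results, fc_threshold = 2) {
  fc <- 2^results$delta
  out <- results[fc >= fc_threshold | fc <= 1 / fc_threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a differential-expression result table
#'
#' @param results A `"de_result"` data.frame.
#' @param path Output TSV path.
#' @export
write_de_results <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
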