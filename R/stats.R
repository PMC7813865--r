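#' @title Statistical primitives
#' @name stats_core
#' @description Empirical-Bayes moderated t-statistics, Bartlett's
#'   variance-homogeneity test, two-sample t-tests, Benjamini-Hochberg FDR,
#'   Fisher-exact 2x2 enrichment and covariate association checks. Row-wise
#'   vectorized variants are provided for probe-level matrices.
NULL

# Row variances with NA handling; denominator n_i - 1 per row.
row_vars <- function(mat) {
  n <- rowSums(!is.na(mat))
  mu <- rowMeans(mat, na.rm = TRUE)
  ss <- rowSums((mat - mu)^2, na.rm = TRUE)
  out <- ss / (n - 1)
  out[n < 2L] <- NA_real_
  out
}

#' Invert the trigamma function
#'
#' Solves trigamma(x) = y by Newton iteration; used when moment-matching
#' the scaled log-F prior of the empirical-Bayes variance model. Returns
#' `Inf` for y <= 0 (the near-constant log-variance limit).
#'
#' @param y Positive numeric vector.
#' @return x with trigamma(x) = y, elementwise.
#' @export
trigamma_inverse <- function(y) {
  out <- rep(NA_real_, length(y))
  out[!is.na(y) & y <= 0] <- Inf
  todo <- which(!is.na(y) & y > 0)
  if (length(todo) == 0L) return(out)
  yy <- y[todo]
  # trigamma(x) ~ 1/x + 1/(2x^2) for large x gives a good starting point
  x <- 0.5 + 1 / yy
  for (iter in 1:50) {
    tri <- trigamma(x)
    dif <- (tri - yy) / psigamma(x, deriv = 2L)
    x <- x - dif
    x[x <= 0] <- 1e-8
    if (max(abs(dif) / x) < 1e-10) break
  }
  out[todo] <- x
  out
}

#' Empirical-Bayes moderated t fit
#'
#' Fits a per-feature ordinary least-squares linear model on the M-value
#' (or log-expression) scale and moderates the residual variances by
#' shrinking towards a common prior. The prior (d0, s0^2) is estimated by
#' moment-matching the distribution of log residual variances to a scaled
#' log-F via digamma/trigamma inversion; the posterior variance is
#' s2_post = (d0 * s0^2 + d * s2) / (d0 + d) and the moderated t uses
#' d0 + d degrees of freedom.
#'
#' @param M Feature-by-sample numeric matrix (M-values or log expression).
#' @param design Sample-by-covariate design matrix, full column rank.
#' @param coef Column of `design` to test (index or name); default 2.
#' @param block Optional per-sample pairing factor; pair indicator columns
#'   are appended to the design (fixed-effect pairing).
#' @param prior_df Force the prior degrees of freedom d0 instead of
#'   estimating them; `0` recovers the classical per-feature t exactly.
#' @return An object of class `"moderated_fit"`: a list with per-feature
#'   `coefficients`, `stdev_unscaled`, `sigma2`, `df_residual`, and the
#'   shared `df_prior`, `s2_prior`, plus `s2_post`, `t` and `p.value`.
#' @export
moderated_t_fit <- function(M, design, coef = 2L, block = NULL,
                            prior_df = NULL) {
  M <- as.matrix(M)
  design <- as.matrix(design)
  if (!is.null(block)) {
    block <- factor(block)
    if (nlevels(block) > 1L) {
      pair_cols <- stats::model.matrix(~block)[, -1L, drop = FALSE]
      colnames(pair_cols) <- paste0("pair_", levels(block)[-1L])
      design <- cbind(design, pair_cols)
    }
  }
  n <- ncol(M)
  p <- ncol(design)
  if (nrow(design) != n)
    stop("design rows must match the number of samples", call. = FALSE)
  if (qr(design)$rank < p)
    stop("rank-deficient design: drop collinear covariates", call. = FALSE)
  d_full <- n - p
  if (d_full < 1L)
    stop("no residual degrees of freedom: drop covariates or add samples",
         call. = FALSE)
  if (is.character(coef)) coef <- match(coef, colnames(design))

  complete <- !anyNA(M)
  if (complete) {
    qr_d <- qr(design)
    bhat <- t(qr.coef(qr_d, t(M)))
    resid <- t(qr.resid(qr_d, t(M)))
    sigma2 <- rowSums(resid^2) / d_full
    xtxi <- chol2inv(chol(crossprod(design)))
    v <- xtxi[coef, coef]
    coefficients <- bhat[, coef]
    stdev_unscaled <- rep(sqrt(v), nrow(M))
    df_residual <- rep(d_full, nrow(M))
  } else {
    # per-feature fits on the available samples
    nf <- nrow(M)
    coefficients <- sigma2 <- stdev_unscaled <- rep(NA_real_, nf)
    df_residual <- rep(NA_real_, nf)
    for (i in seq_len(nf)) {
      ok <- !is.na(M[i, ])
      di <- sum(ok) - p
      if (di < 1L) next
      Xi <- design[ok, , drop = FALSE]
      if (qr(Xi)$rank < p) next
      fit <- stats::lm.fit(Xi, M[i, ok])
      coefficients[i] <- fit$coefficients[coef]
      sigma2[i] <- sum(fit$residuals^2) / di
      stdev_unscaled[i] <- sqrt(chol2inv(chol(crossprod(Xi)))[coef, coef])
      df_residual[i] <- di
    }
  }

  # prior estimation on features with positive variance and df >= 1
  usable <- which(!is.na(sigma2) & sigma2 > 0 & df_residual >= 1)
  if (length(usable) < 2L && is.null(prior_df))
    stop("too few features with positive residual variance to estimate the prior",
         call. = FALSE)
  if (!is.null(prior_df)) {
    d0 <- prior_df
    if (d0 > 0) {
      z <- log(sigma2[usable])
      d <- df_residual[usable]
      e <- z - digamma(d / 2) + log(d / 2)
      s0_2 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    } else {
      s0_2 <- NA_real_
    }
  } else {
    z <- log(sigma2[usable])
    d <- df_residual[usable]
    e <- z - digamma(d / 2) + log(d / 2)
    ebar <- mean(e)
    nuse <- length(e)
    target <- mean((e - ebar)^2 * nuse / (nuse - 1) - trigamma(d / 2))
    if (is.finite(target) && target > 0) {
      d0 <- 2 * trigamma_inverse(target)
      s0_2 <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
    } else {
      # log-variances (after df correction) near-constant: infinite
      # shrinkage; the prior collapses onto the mean observed variance
      d0 <- Inf
      s0_2 <- mean(sigma2[usable])
    }
  }

  if (is.infinite(d0)) {
    s2_post <- rep(s0_2, length(sigma2))
    s2_post[is.na(sigma2)] <- NA_real_
    df_total <- rep(Inf, length(sigma2))
  } else if (d0 == 0) {
    s2_post <- sigma2
    df_total <- df_residual
  } else {
    s2_post <- (d0 * s0_2 + df_residual * sigma2) / (d0 + df_residual)
    df_total <- d0 + df_residual
  }
  tstat <- coefficients / (sqrt(s2_post) * stdev_unscaled)
  pval <- 2 * stats::pt(-abs(tstat), df = df_total)

  structure(list(
    feature_ids = rownames(M),
    coefficients = coefficients,
    stdev_unscaled = stdev_unscaled,
    sigma2 = sigma2,
    df_residual = df_residual,
    df_prior = d0,
    s2_prior = s0_2,
    s2_post = s2_post,
    t = tstat,
    p.value = pval
  ), class = "moderated_fit")
}

#' @export
print.moderated_fit <- function(x, ...) {
  cat("Moderated t fit:", length(x$coefficients), "features\n")
  cat("  prior df d0 =", format(x$df_prior, digits = 4),
      " prior variance s0^2 =", format(x$s2_prior, digits = 4), "\n")
  invisible(x)
}

#' Row-wise Bartlett test between two sample groups
#'
#' Computes Bartlett's variance-homogeneity statistic
#' T = \[(N - k) ln s_p^2 - sum (n_i - 1) ln s_i^2\] / C with k = 2 groups
#' and the standard correction factor C, with p from a chi-square on 1 df.
#' Rows with a zero-variance or undersized group get `NA` with a logged
#' count.
#'
#' @param mat Probe-by-sample matrix (beta scale for DVP calling).
#' @param idx1,idx2 Column indices (or names) of the two groups.
#' @return data.frame with `statistic` and `p.value`, one row per probe.
#' @export
row_bartlett <- function(mat, idx1, idx2) {
  x1 <- mat[, idx1, drop = FALSE]
  x2 <- mat[, idx2, drop = FALSE]
  n1 <- rowSums(!is.na(x1)); n2 <- rowSums(!is.na(x2))
  s1 <- row_vars(x1); s2 <- row_vars(x2)
  N <- n1 + n2
  sp2 <- ((n1 - 1) * s1 + (n2 - 1) * s2) / (N - 2)
  C <- 1 + (1 / 3) * (1 / (n1 - 1) + 1 / (n2 - 1) - 1 / (N - 2))
  stat <- ((N - 2) * log(sp2) - ((n1 - 1) * log(s1) + (n2 - 1) * log(s2))) / C
  bad <- n1 < 2 | n2 < 2 | is.na(s1) | is.na(s2) | s1 <= 0 | s2 <= 0
  stat[bad] <- NA_real_
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  if (any(bad))
    message("row_bartlett: ", sum(bad),
            " probe(s) with zero variance or <2 values set to NA")
  data.frame(statistic = stat, p.value = p, row.names = rownames(mat))
}

#' Bartlett's test for two samples
#'
#' @param x,y Numeric vectors.
#' @return List with `statistic`, `p.value` and `method`.
#' @export
bartlett_test <- function(x, y) {
  res <- suppressMessages(
    row_bartlett(rbind(c(x, y)), seq_along(x), length(x) + seq_along(y))
  )
  list(statistic = res$statistic[1L], p.value = res$p.value[1L],
       method = "Bartlett test of homogeneity of variances (k = 2)")
}

#' Row-wise two-sample t-test
#'
#' @param mat Probe-by-sample matrix.
#' @param idx1,idx2 Column indices (or names) of the two groups.
#' @param variant `"welch"` (default; unequal variances) or `"student"`
#'   (pooled variance).
#' @return data.frame with `statistic`, `p.value`, `df` and `mean_diff`
#'   (group 1 minus group 2).
#' @export
row_t <- function(mat, idx1, idx2, variant = c("welch", "student")) {
  variant <- match.arg(variant)
  x1 <- mat[, idx1, drop = FALSE]
  x2 <- mat[, idx2, drop = FALSE]
  n1 <- rowSums(!is.na(x1)); n2 <- rowSums(!is.na(x2))
  m1 <- rowMeans(x1, na.rm = TRUE); m2 <- rowMeans(x2, na.rm = TRUE)
  s1 <- row_vars(x1); s2 <- row_vars(x2)
  diff <- m1 - m2
  if (variant == "student") {
    sp2 <- ((n1 - 1) * s1 + (n2 - 1) * s2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    a <- s1 / n1; b <- s2 / n2
    se <- sqrt(a + b)
    df <- (a + b)^2 / (a^2 / (n1 - 1) + b^2 / (n2 - 1))
  }
  stat <- diff / se
  bad <- n1 < 2 | n2 < 2 | !is.finite(se) | se <= 0
  stat[bad] <- NA_real_
  df[bad] <- NA_real_
  p <- 2 * stats::pt(-abs(stat), df = df)
  data.frame(statistic = stat, p.value = p, df = df, mean_diff = diff,
             row.names = rownames(mat))
}

#' Two-sample t-test
#'
#' @param x,y Numeric vectors (each with >= 2 values).
#' @param variant `"welch"` or `"student"`.
#' @return List with `statistic`, `p.value`, `df` and `direction`
#'   (sign of mean(x) - mean(y)).
#' @export
two_sample_t <- function(x, y, variant = c("welch", "student")) {
  variant <- match.arg(variant)
  res <- row_t(rbind(c(x, y)), seq_along(x), length(x) + seq_along(y),
               variant = variant)
  list(statistic = res$statistic[1L], p.value = res$p.value[1L],
       df = res$df[1L], direction = sign(res$mean_diff[1L]))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment; missing p-values are excluded from the number of
#' tests and returned as `NA` in place.
#'
#' @param p Numeric vector of p-values in \[0, 1\], `NA` allowed.
#' @return q-values in the input order.
#' @export
bh_fdr <- function(p) {
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  q
}

#' Fisher-exact 2x2 enrichment
#'
#' Odds ratio for a disjoint 2x2 table (query in/out of category vs
#' background-minus-query in/out of category). The odds ratio is the sample
#' OR = (a d)/(b c), with the Haldane-Anscombe +0.5 correction applied to
#' all cells when any cell is zero; the two-sided p-value is Fisher's exact
#' test (sum of hypergeometric point masses no larger than the observed).
#'
#' @param in_set_in_cat,in_set_out_cat Query counts inside/outside the
#'   category.
#' @param bg_in_cat,bg_out_cat Background (excluding the query) counts
#'   inside/outside the category.
#' @return List with `odds_ratio`, `log_odds_ratio` and `p.value`.
#' @export
enrichment_2x2 <- function(in_set_in_cat, in_set_out_cat, bg_in_cat,
                           bg_out_cat) {
  counts <- c(in_set_in_cat, in_set_out_cat, bg_in_cat, bg_out_cat)
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  a <- in_set_in_cat; b <- in_set_out_cat
  c_ <- bg_in_cat; d <- bg_out_cat
  if (any(counts == 0)) {
    a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5
  }
  or <- (a * d) / (b * c_)
  tab <- matrix(counts, nrow = 2L, byrow = TRUE)
  p <- stats::fisher.test(tab)$p.value
  list(odds_ratio = or, log_odds_ratio = log(or), p.value = p)
}

#' Covariate association with per-sample summaries
#'
#' Tests whether a per-sample summary statistic (for instance the
#' sample-wise mean methylation or a principal component score) associates
#' with a covariate: Pearson correlation for continuous covariates, a
#' rank-sum comparison between the two levels for categorical ones. A
#' covariate is flagged as contributing when p < 0.05.
#'
#' @param summaries Numeric vector, one value per sample.
#' @param covariate Per-sample covariate values (numeric or 2-level).
#' @param kind `"continuous"` or `"categorical"`.
#' @return List with `statistic`, `p.value` and `significant`.
#' @export
covariate_association <- function(summaries,
                                  covariate,
                                  kind = c("continuous", "categorical")) {
  kind <- match.arg(kind)
  ok <- !is.na(summaries) & !is.na(covariate)
  if (sum(ok) < 3L) stop("need at least 3 complete samples", call. = FALSE)
  s <- summaries[ok]; cv <- covariate[ok]
  if (length(unique(cv)) < 2L) {
    message("covariate_association: constant covariate, p set to NA")
    return(list(statistic = NA_real_, p.value = NA_real_, significant = NA))
  }
  if (kind == "continuous") {
    res <- stats::cor.test(s, as.numeric(cv), method = "pearson")
    out <- list(statistic = unname(res$estimate), p.value = res$p.value)
  } else {
    lv <- unique(cv)
    if (length(lv) != 2L)
      stop("categorical covariate must have exactly 2 levels", call. = FALSE)
    res <- suppressWarnings(stats::wilcox.test(s[cv == lv[1L]],
                                               s[cv == lv[2L]],
                                               exact = FALSE))
    out <- list(statistic = unname(res$statistic), p.value = res$p.value)
  }
  out$significant <- !is.na(out$p.value) && out$p.value < 0.05
  out
}
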