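test_that("moderated t with d0 = 0 equals the classical per-feature t", {
  set.seed(101)
  M <- matrix(rnorm(40 * 8), 40, 8,
              dimnames = list(paste0("f", 1:40), paste0("s", 1:8)))
  design <- cbind(intercept = 1, group = rep(0:1, each = 4))
  fit <- moderated_t_fit(M, design, coef = "group", prior_df = 0)
  classical <- apply(M, 1, function(y) {
    s <- summary(stats::lm(y ~ design[, "group"]))
    s$coefficients[2, c("t value", "Pr(>|t|)")]
  })
  expect_equal(unname(fit$t), unname(classical[1, ]), tolerance = 1e-10)
  expect_equal(unname(fit$p.value), unname(classical[2, ]), tolerance = 1e-10)
})

test_that("constant sample variances give s0^2 = s^2 and inflated df", {
  # build features with identical residual variance by scaling residuals
  set.seed(102)
  n <- 8
  design <- cbind(intercept = 1, group = rep(0:1, each = 4))
  M <- t(vapply(1:30, function(i) {
    y <- rnorm(n)
    r <- stats::lm.fit(design, y)$residuals
    r <- r / sqrt(sum(r^2) / (n - 2))          # force s^2 = 1
    r + 0.5 * design[, "group"]
  }, numeric(n)))
  fit <- moderated_t_fit(M, design, coef = "group")
  expect_true(is.infinite(fit$df_prior))
  # infinite-shrinkage limit: prior collapses onto the common variance
  s0_expected <- 1
  expect_equal(fit$s2_prior, s0_expected, tolerance = 1e-8)
  expect_equal(unname(fit$s2_post), rep(s0_expected, 30), tolerance = 1e-8)
  # infinite shrinkage: moderated t is the ordinary t with the common
  # posterior variance and normal reference
  expect_equal(unname(fit$t),
               unname(fit$coefficients / (sqrt(s0_expected) *
                                          fit$stdev_unscaled)),
               tolerance = 1e-10)
  lf <- limma::eBayes(limma::lmFit(M, design))
  expect_equal(unname(fit$s2_post), unname(lf$s2.post), tolerance = 1e-8)
})

test_that("moderated fit matches the limma reference within 1e-8", {
  # heterogeneous true variances -> finite, modest prior df
  set.seed(103)
  for (dims in list(c(50, 6), c(200, 20))) {
    nf <- dims[1]; n <- dims[2]
    sd_true <- sqrt(1 / stats::rchisq(nf, df = 4) * 4)
    M <- matrix(rnorm(nf * n), nf, n) * sd_true
    dimnames(M) <- list(paste0("f", 1:nf), paste0("s", 1:n))
    design <- cbind(1, rep(0:1, length.out = n), rnorm(n))
    colnames(design) <- c("intercept", "group", "age")
    fit <- moderated_t_fit(M, design, coef = "group")
    lf <- limma::eBayes(limma::lmFit(M, design))
    expect_equal(fit$df_prior, lf$df.prior, tolerance = 1e-8)
    expect_equal(fit$s2_prior, lf$s2.prior, tolerance = 1e-8)
    expect_equal(unname(fit$s2_post), unname(lf$s2.post), tolerance = 1e-8)
    expect_equal(unname(fit$t), unname(lf$t[, "group"]), tolerance = 1e-8)
    expect_equal(unname(fit$p.value), unname(lf$p.value[, "group"]),
                 tolerance = 1e-8)
  }
})

test_that("moderated p-values are uniform under the null", {
  set.seed(104)
  M <- matrix(rnorm(200 * 8), 200, 8)
  design <- cbind(intercept = 1, group = rep(0:1, each = 4))
  fit <- moderated_t_fit(M, design, coef = "group")
  ks <- suppressWarnings(stats::ks.test(fit$p.value, "punif"))
  # critical value of the KS statistic at alpha = 0.01 for n = 200
  expect_lt(unname(ks$statistic), 1.63 / sqrt(200))
})

test_that("rank-deficient designs and zero residual df are rejected", {
  M <- matrix(rnorm(20), 5, 4)
  bad <- cbind(1, c(0, 0, 1, 1), c(0, 0, 2, 2))
  expect_error(moderated_t_fit(M, bad), "rank-deficient")
  full <- cbind(1, c(0, 0, 1, 1), c(1, 0, 1, 0), c(0, 1, 1, 0))
  expect_error(moderated_t_fit(M, full), "degrees of freedom")
})

test_that("Bartlett statistic matches the base-R oracle", {
  # homogeneous case: T = 0, p = 1
  x <- c(1, 2, 3, 4); y <- c(11, 12, 13, 14)
  res <- bartlett_test(x, y)
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p.value, 1)

  set.seed(105)
  for (i in 1:20) {
    a <- rnorm(sample(4:12, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(4:12, 1), sd = runif(1, 0.5, 3))
    ours <- bartlett_test(a, b)
    ref <- stats::bartlett.test(list(a, b))
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$p.value, ref$p.value, tolerance = 1e-10)
    # symmetry and scale invariance
    expect_equal(bartlett_test(b, a)$statistic, ours$statistic)
    expect_equal(bartlett_test(3.7 * a, 3.7 * b)$p.value, ours$p.value,
                 tolerance = 1e-10)
  }

  # zero variance -> NA with a log, not an error
  expect_message(z <- row_bartlett(rbind(c(1, 1, 1, 2, 3, 4)), 1:3, 4:6),
                 "zero variance")
  expect_true(is.na(z$p.value))
})

test_that("two-sample t matches its closed form and t.test", {
  idn <- two_sample_t(c(1, 2, 3), c(1, 2, 3), "student")
  expect_equal(idn$statistic, 0)
  expect_equal(idn$p.value, 1)

  res <- two_sample_t(c(1, 2, 3), c(4, 5, 6), "student")
  # pooled s^2 = 1, se = sqrt(2/3), t = -3 * sqrt(3/2)
  expect_equal(res$statistic, -3 * sqrt(3 / 2), tolerance = 1e-12)
  ref <- stats::t.test(c(1, 2, 3), c(4, 5, 6), var.equal = TRUE)
  expect_equal(res$p.value, ref$p.value, tolerance = 1e-12)

  set.seed(106)
  for (variant in c("welch", "student")) {
    a <- rnorm(7); b <- rnorm(9, sd = 2)
    ours <- two_sample_t(a, b, variant)
    ref <- stats::t.test(a, b, var.equal = variant == "student")
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$p.value, ref$p.value, tolerance = 1e-10)
    # antisymmetry
    swap <- two_sample_t(b, a, variant)
    expect_equal(swap$statistic, -ours$statistic)
    expect_equal(swap$p.value, ours$p.value)
  }
})

test_that("BH q-values follow the step-up rule", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_fdr(0.7), 0.7)
  # NA excluded from m, returned in place
  q <- bh_fdr(c(0.01, NA, 0.02, 0.04))
  expect_true(is.na(q[2]))
  expect_equal(q[-2], c(0.03, 0.03, 0.04))

  set.seed(107)
  for (i in 1:10) {
    p <- runif(sample(5:50, 1))
    q <- bh_fdr(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-12))
    # monotone along sorted p
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
})

test_that("2x2 enrichment matches exhaustive hypergeometric enumeration", {
  flat <- enrichment_2x2(5, 5, 5, 5)
  expect_equal(flat$odds_ratio, 1)
  expect_equal(flat$p.value, 1)

  res <- enrichment_2x2(3, 1, 1, 3)
  expect_equal(res$odds_ratio, 9)
  expect_equal(res$p.value, fisher_oracle(3, 1, 1, 3), tolerance = 1e-12)

  set.seed(108)
  for (i in 1:25) {
    cells <- as.integer(rmultinom(1, sample(10:60, 1), rep(0.25, 4)))
    res <- enrichment_2x2(cells[1], cells[2], cells[3], cells[4])
    expect_equal(res$p.value,
                 fisher_oracle(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-9)
  }

  # zero cell: Haldane-Anscombe correction keeps the OR finite
  z <- enrichment_2x2(4, 0, 2, 6)
  expect_equal(z$odds_ratio, (4.5 * 6.5) / (0.5 * 2.5))
  expect_true(is.finite(z$log_odds_ratio))
  expect_error(enrichment_2x2(-1, 2, 3, 4), "negative")
})

test_that("covariate association handles both covariate kinds", {
  age <- c(50, 55, 60, 65, 70, 75)
  lin <- covariate_association(0.2 + 0.001 * age, age, "continuous")
  expect_equal(abs(lin$statistic), 1, tolerance = 1e-10)
  expect_lt(lin$p.value, 1e-10)
  expect_true(lin$significant)

  same <- covariate_association(rep(c(0.4, 0.5, 0.6), 2),
                                rep(c("F", "M"), each = 3), "categorical")
  expect_gt(same$p.value, 0.9)

  expect_message(res <- covariate_association(rnorm(5), rep(1, 5),
                                              "continuous"),
                 "constant covariate")
  expect_true(is.na(res$p.value))

  # independent covariate: p roughly uniform over seeded replicates
  set.seed(109)
  ps <- replicate(200, covariate_association(rnorm(10), rnorm(10),
                                             "continuous")$p.value)
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)
  expect_lt(mean(ps < 0.05), 0.12)
})

test_that("trigamma inversion is a true inverse", {
  y <- c(1e-4, 0.01, 0.5, 2, 50)
  expect_equal(trigamma(trigamma_inverse(y)), y, tolerance = 1e-8)
  expect_true(is.infinite(trigamma_inverse(0)))
})
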