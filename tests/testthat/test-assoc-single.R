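# Rank-inverse normalization, single-variant OLS, log-space P values,
# LD, conditional-joint selection and variance explained.

test_that("rank-inverse normalization matches the Blom closed form", {
  x <- c(3.2, -1, 0.5, 10, 7)
  out <- rank_inverse_normalize(x)
  expected <- qnorm((rank(x) - 0.375) / 5.25)
  expect_equal(out, expected, tolerance = 1e-12)
  # odd n, distinct values: the middle value maps to exactly 0
  expect_equal(out[order(x)][3L], 0)
  # symmetry of the output multiset
  expect_equal(sort(out), -rev(sort(out)), tolerance = 1e-12)
  expect_error(rank_inverse_normalize(rep(1, 10)), "identical")
  expect_error(rank_inverse_normalize(c(1, 2)), "at least 3")
})

test_that("single-variant OLS equals the multiple-regression oracle", {
  set.seed(5)
  n <- 50L
  G <- hwe_genotypes(n, c(0.3, 0.1, 0.45), seed = 6L)
  X <- data.frame(age = rnorm(n), sex = rbinom(n, 1, 0.5))
  y <- rank_inverse_normalize(0.5 * G[, 1L] + 0.3 * X$age + rnorm(n))
  res <- single_variant_assoc(G, y, X, min_mac = 1)
  for (j in 1:3) {
    fit <- summary(lm(y ~ G[, j] + X$age + X$sex))$coefficients
    expect_equal(res$beta[j], fit[2L, 1L], tolerance = 1e-10)
    expect_equal(res$se[j], fit[2L, 2L], tolerance = 1e-10)
    expect_equal(res$p[j], fit[2L, 4L], tolerance = 1e-10)
  }
})

test_that("variants below the MAC floor are skipped", {
  n <- 100L
  G <- cbind(v1 = carrier_column(n, 4L, seed = 1L),
             v2 = carrier_column(n, 5L, seed = 2L))
  y <- rank_inverse_normalize(rnorm(n))
  res <- single_variant_assoc(G, y, min_mac = 5)
  expect_identical(res$vid, "v2")
})

test_that("rank-deficient covariates raise a named error", {
  n <- 30L
  X <- data.frame(a = rnorm(n))
  X$b <- 2 * X$a
  G <- hwe_genotypes(n, 0.3)
  expect_error(single_variant_assoc(G, rnorm(n), X), "collinear.*b")
})

test_that("log-space P matches an incomplete-beta oracle and never underflows", {
  # independent oracle: two-sided t survival via pbeta in log space,
  # P = I_{nu/(nu+t^2)}(nu/2, 1/2)
  log10p_beta <- function(t, nu)
    (log(0.5) + pbeta(nu / (nu + t^2), nu / 2, 0.5, log.p = TRUE) +
       log(2)) / log(10)
  for (t in c(1, 10, 50, 300)) {
    got <- log10p_from_t(beta = t, se = 1, n = 100)
    want <- log10p_beta(t, 98)
    expect_lt(abs(got / want - 1), 1e-6)
  }
  big <- log10p_from_t(beta = 300, se = 1, n = 50000)
  expect_true(is.finite(big))
  expect_lt(big, -1000)
  expect_equal(log10p_from_t(0, 1, 100), 0)
  ts <- c(1, 5, 20, 100, 300)
  lps <- vapply(ts, function(t) log10p_from_t(t, 1, 5000), 0)
  expect_true(all(diff(lps) < 0))
  # covariate-adjusted degrees of freedom switch
  expect_equal(log10p_from_t(2, 1, 100, df = "nk2", k = 10),
               log10(2 * pt(-2, 88)), tolerance = 1e-12)
  expect_error(log10p_from_t(1, 0, 100), "se")
})

test_that("ld_r2: identity, hand computation, monomorphic error, null pairs", {
  g <- c(0, 1, 2, 1, 0, 2)
  expect_equal(ld_r2(g, g), 1.0)
  h <- c(1, 1, 0, 2, 0, 1)
  expect_equal(ld_r2(g, h), cor(g, h)^2, tolerance = 1e-12)
  expect_error(ld_r2(rep(0, 6), g), "monomorphic")
  set.seed(9)
  G <- hwe_genotypes(10000L, rep(0.2, 20), seed = 10L)
  r2 <- combn(20L, 2L, function(ij) ld_r2(G[, ij[1L]], G[, ij[2L]]))
  expect_gte(mean(r2 < 0.01), 0.99)
})

test_that("cojo with one causal independent variant returns it with marginal beta", {
  set.seed(11)
  n <- 2000L
  G <- hwe_genotypes(n, c(0.2, 0.3, 0.1, 0.25), seed = 12L)
  y <- rank_inverse_normalize(0.4 * G[, 2L] + rnorm(n))
  j <- cojo_select(G, y, p_threshold = 1e-6)
  expect_identical(j$signals$vid, "v2")
  expect_equal(j$signals$beta_joint, j$signals$beta_marginal,
               tolerance = 1e-8)
  expect_lt(j$max_abs_beta_discrepancy, 1e-8)
})

test_that("cojo joint estimates equal the normal-equations oracle", {
  set.seed(13)
  n <- 3000L
  G <- hwe_genotypes(n, c(0.2, 0.35, 0.15, 0.3, 0.25), seed = 14L)
  expect_lt(ld_r2(G[, 1L], G[, 4L]), 0.01)
  y <- rank_inverse_normalize(0.3 * G[, 1L] - 0.25 * G[, 4L] + rnorm(n))
  j <- cojo_select(G, y, p_threshold = 1e-6)
  expect_setequal(j$signals$vid, c("v1", "v4"))
  fit <- lm(y ~ G[, "v1"] + G[, "v4"])
  expect_equal(sort(j$signals$beta_joint),
               sort(unname(coef(fit)[2:3])), tolerance = 1e-8)
  se_or <- summary(fit)$coefficients[2:3, 2L]
  expect_equal(sort(j$signals$se_joint), sort(unname(se_or)),
               tolerance = 1e-8)
})

test_that("duplicated variants yield exactly one selected signal", {
  set.seed(15)
  n <- 1500L
  g <- rbinom(n, 2L, 0.2)
  G <- cbind(dup1 = g, dup2 = g)
  y <- rank_inverse_normalize(0.5 * g + rnorm(n))
  j <- cojo_select(G, y, p_threshold = 1e-6)
  expect_identical(nrow(j$signals), 1L)
})

test_that("no variant below threshold gives an empty signal set, not an error", {
  set.seed(16)
  G <- hwe_genotypes(300L, c(0.2, 0.3), seed = 17L)
  y <- rank_inverse_normalize(rnorm(300L))
  j <- cojo_select(G, y)
  expect_identical(nrow(j$signals), 0L)
  expect_equal(variance_explained(j, G, y), 0)
})

test_that("variance explained recovers the analytic value on a planted architecture", {
  set.seed(18)
  n <- 5000L
  freqs <- c(0.3, 0.1)
  betas <- c(0.4, -0.5)
  G <- hwe_genotypes(n, freqs, seed = 19L)
  noise_sd <- 1
  y <- as.numeric(G %*% betas) + rnorm(n, 0, noise_sd)
  analytic_num <- sum(2 * freqs * (1 - freqs) * betas^2)
  analytic <- analytic_num / (analytic_num + noise_sd^2)
  got <- variance_explained(colnames(G), G, y)
  expect_lt(abs(got / analytic - 1), 0.20)
  # limit: noise -> 0 with one causal variant drives R^2 -> 1
  y0 <- as.numeric(G[, 1L] * 0.5) + rnorm(n, 0, 1e-4)
  expect_gt(variance_explained("v1", G, y0), 0.999)
})
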