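# Aggregate tests: Cauchy combinations, burden/SKAT reductions,
# conditioning machinery and the stepwise independence procedure.

test_that("ACAT-V matches the closed-form Cauchy oracle", {
  # oracle: upper-tail probability of the weighted Cauchy statistic
  acat_oracle <- function(p, w = rep(1, length(p))) {
    w <- w / sum(w)
    pcauchy(sum(w * tan((0.5 - p) * pi)), lower.tail = FALSE)
  }
  expect_equal(acat_v(rep(0.5, 7)), 0.5, tolerance = 1e-14)
  expect_equal(acat_v(0.0371), 0.0371, tolerance = 1e-12)
  p <- c(1e-6, 0.5, 0.5)
  expect_equal(acat_v(p), acat_oracle(p), tolerance = 1e-12)
  set.seed(101)
  for (i in 1:25) {
    k <- sample(2:12, 1L)
    p <- runif(k)^sample(1:4, 1L)
    w <- runif(k)
    expect_equal(acat_v(p, w), acat_oracle(p, w), tolerance = 1e-12)
  }
  expect_error(acat_v(numeric(0)), "empty")
  expect_error(acat_v(0.5, weights = 0), "weights")
})

test_that("ACAT-O is the equal-weight combination with fixed points", {
  expect_equal(acat_o(0.2, 0.2, 0.2), 0.2, tolerance = 1e-12)
  expect_equal(acat_o(1e-8, 0.4, 0.6), acat_v(c(1e-8, 0.4, 0.6)),
               tolerance = 1e-14)
  expect_equal(acat_o(0.1, NA, 0.3), acat_v(c(0.1, 0.3)),
               tolerance = 1e-14)
  expect_true(is.na(acat_o(NA, NA, NA)))
})

test_that("all-mask combination refuses to mix coding and noncoding", {
  expect_equal(all_mask_combine(c(m = 0.2)), 0.2, tolerance = 1e-12)
  expect_equal(all_mask_combine(c(a = 1e-9, b = 0.5)),
               acat_v(c(1e-9, 0.5)), tolerance = 1e-14)
  expect_error(all_mask_combine(c(a = 0.1, b = 0.2),
                                c("coding", "noncoding")),
               "coding and noncoding")
})

test_that("residualize projects out covariates and conditioning dosages", {
  set.seed(31)
  n <- 200L
  X <- data.frame(age = rnorm(n), sex = rbinom(n, 1, 0.5))
  C <- hwe_genotypes(n, c(0.2, 0.1), seed = 32L)
  y <- rnorm(n)
  adj <- residualize(y, X, C)
  expect_lt(max(abs(cor(adj$y, C))), 1e-10)
  expect_lt(max(abs(cor(adj$y, X$age))), 1e-10)
  adj0 <- residualize(y, X, NULL)
  expect_equal(adj0$y, unname(resid(lm(y ~ X$age + X$sex))),
               tolerance = 1e-12)
  expect_error(residualize(rnorm(5), NULL, matrix(rnorm(25), 5L)),
               "conditioning columns")
})

test_that("conditioning set = common leads plus all cognate coding variants", {
  variants <- data.frame(
    vid = c("lead_common", "lead_rare", "coding_ns", "coding_other",
            "noncoding"),
    maf = c(0.05, 0.0005, 0.3, 0.2, 0.01),
    classification = c("intergenic_regulatory", "proximal_regulatory",
                       "coding", "coding", "proximal_regulatory"),
    annotated_gene = c(NA, NA, "G1", "G2", "G1"),
    stringsAsFactors = FALSE)
  joint <- structure(list(signals = data.frame(
    vid = c("lead_common", "lead_rare"), maf = c(0.05, 0.0005))),
    class = "joint_signal_set")
  cs <- build_conditioning_set(joint, variants, "G1")
  expect_setequal(cs, c("lead_common", "coding_ns"))
  # non-significant cognate coding variants are included regardless;
  # a lead below the frequency floor is not
  expect_false("lead_rare" %in% cs)
  empty <- build_conditioning_set(NULL, variants[5L, , drop = FALSE],
                                  "G1")
  expect_length(empty, 0L)
})

test_that("single-variant units reduce to the single-variant tests", {
  set.seed(41)
  n <- 500L
  g <- carrier_column(n, 12L)
  G <- cbind(v1 = g)
  y <- rnorm(n)
  X <- data.frame(age = rnorm(n))
  adj <- residualize(y, X, NULL)
  w <- 1
  bt <- burden_test(G, adj, w)
  fit <- summary(lm(adj$y ~ qr.resid(adj$qr, g) - 1))
  sv <- single_variant_assoc(G, rank_inverse_normalize(y), X,
                             min_mac = 1)
  # burden on one variant == that variant's regression on adjusted y
  direct <- summary(lm(y ~ g + X$age))$coefficients[2L, ]
  expect_equal(bt$beta, unname(direct[1L]), tolerance = 1e-10)
  expect_equal(bt$p, unname(direct[4L]), tolerance = 1e-10)
  # SKAT on one variant == two-sided score test
  st <- skat_test(G, adj, w)
  gp <- qr.resid(adj$qr, g)
  z2 <- sum(gp * adj$y)^2 / (sum(gp^2) * sum(adj$y^2) / (adj$n - adj$rank))
  expect_equal(st$p, pchisq(z2, 1, lower.tail = FALSE),
               tolerance = 1e-8)
  # singleton test is the burden test on the MAC = 1 subset
  G3 <- cbind(s1 = carrier_column(n, 1L, seed = 5L),
              s2 = carrier_column(n, 1L, seed = 6L),
              c3 = carrier_column(n, 3L, seed = 7L))
  stn <- singleton_test(G3, adj, weights = rep(1, 3))
  expect_identical(stn$n_variants, 2L)
  btn <- burden_test(G3[, 1:2], adj, rep(1, 2))
  expect_equal(stn$p, btn$p, tolerance = 1e-12)
})

test_that("SKAT mixture p agrees with permutation in the body of the null", {
  set.seed(51)
  n <- 300L
  G <- hwe_genotypes(n, runif(8, 0.01, 0.05), seed = 52L)
  y <- rnorm(n)
  adj <- residualize(y, NULL, NULL)
  st <- skat_test(G, adj)
  pm <- skat_permutation(G, adj, n_perm = 4000L, seed = 53L)
  se <- sqrt(pm$p * (1 - pm$p) / 4000)
  expect_lt(abs(st$p - pm$p), 3 * se + 1e-3)
})

test_that("burden wins under shared-direction effects, SKAT under mixed signs", {
  n <- 1000L
  wins_burden <- wins_skat <- 0L
  n_seeds <- 30L
  for (s in seq_len(n_seeds)) {
    set.seed(600 + s)
    G <- hwe_genotypes(n, rep(0.008, 8), seed = 700 + s)
    same <- as.numeric(G %*% rep(-0.6, 8))
    mixed <- as.numeric(G %*% (c(1, -1, 1, -1, 1, -1, 1, -1) * 0.8))
    adj_same <- residualize(same + rnorm(n), NULL, NULL)
    adj_mixed <- residualize(mixed + rnorm(n), NULL, NULL)
    w <- beta_weights(rarecis:::allele_summary(G)$maf)
    if (burden_test(G, adj_same, w)$p < skat_test(G, adj_same, w)$p)
      wins_burden <- wins_burden + 1L
    if (skat_test(G, adj_mixed, w)$p < burden_test(G, adj_mixed, w)$p)
      wins_skat <- wins_skat + 1L
  }
  expect_gte(wins_burden / n_seeds, 0.8)
  expect_gte(wins_skat / n_seeds, 0.8)
})

test_that("conditioning on a unit's causal variants nulls its signal", {
  n <- 1000L
  rej <- 0L
  n_seeds <- 40L
  for (s in seq_len(n_seeds)) {
    set.seed(800 + s)
    G <- hwe_genotypes(n, rep(0.01, 6), seed = 900 + s)
    y <- as.numeric(G[, 1:3] %*% rep(1, 3)) + rnorm(n)
    adj <- residualize(y, NULL, G[, 1:3])
    p <- burden_test(G, adj)$p
    if (!is.na(p) && p < 0.05) rej <- rej + 1L
  }
  expect_lt(abs(rej / n_seeds - 0.05),
            3 * sqrt(0.05 * 0.95 / n_seeds) + 0.02)
})

test_that("stepwise procedure recovers disjoint planted aggregates and collapses overlapping ones", {
  n <- 2500L
  set.seed(61)
  win <- list(chrom = "chr1", start = 0L, end = 12000L)
  pos <- sort(sample(1:12000, 60L))
  G <- vapply(seq_len(60L), function(j) carrier_column(n, 8L),
              numeric(n))
  colnames(G) <- paste0("chr1:", pos, ":A:G")
  v <- data.frame(vid = colnames(G), chrom = "chr1", pos = pos,
                  mac = 8, maf = 8 / (2 * n),
                  classification = "intergenic_regulatory",
                  stringsAsFactors = FALSE)
  units <- build_sliding_windows(win, v, max_maf = 0.01)
  in_iv <- function(lo, hi) which(pos > lo & pos <= hi)
  c1 <- in_iv(500, 1500); c2 <- in_iv(8200, 9200)
  y <- as.numeric(G[, c1, drop = FALSE] %*% rep(1.4, length(c1))) +
    as.numeric(G[, c2, drop = FALSE] %*% rep(-1.4, length(c2))) +
    rnorm(n)
  y <- rank_inverse_normalize(y)
  res <- stepwise_aggregate_conditioning(units, G, y,
                                         threshold = 1e-6,
                                         config = test_config(max_maf =
                                                                0.01))
  expect_gte(nrow(res), 2L)
  # the first two recorded signals land on the two planted intervals,
  # and overlapping windows sharing the causal variants collapse to one
  hit1 <- any(res$start < 1500 & res$end > 500)
  hit2 <- any(res$start < 9200 & res$end > 8200)
  expect_true(hit1 && hit2)
  n_near1 <- sum(res$start < 2500 & res$end > 0)
  expect_lte(n_near1, 2L)
  # nothing significant -> empty frame, no iterations
  y0 <- rank_inverse_normalize(rnorm(n))
  res0 <- stepwise_aggregate_conditioning(units, G, y0,
                                          threshold = 1e-6,
                                          config = test_config(max_maf =
                                                                 0.01))
  expect_identical(nrow(res0), 0L)
})

test_that("lead-variant flags match hand enumeration", {
  agg <- data.frame(unit_id = c("u1", "u2", "u3"),
                    members = c("a,b", "a,c,d", "e"),
                    p = c(1e-10, 1e-10, 1e-10),
                    stringsAsFactors = FALSE)
  sv <- data.frame(vid = c("a", "b", "c", "d", "e"),
                   p = c(1e-12, 0.5, 1e-11, 1e-11, 0.2))
  out <- flag_single_lead_aggregates(agg, lead_vids = c("a", "c", "d"),
                                     sv_results = sv)
  expect_identical(out$lead_category, c("1", ">1", "0"))
  expect_identical(out$contains_studywide_variant, c(TRUE, TRUE, FALSE))
})

test_that("sensitivity step with an empty extra set reproduces the p values", {
  n <- 1500L
  set.seed(71)
  G <- hwe_genotypes(n, rep(0.01, 10), seed = 72L)
  colnames(G) <- paste0("chr1:", 1:10 * 100, ":A:G")
  v <- toy_variant_table(G, pos = 1:10 * 100)
  win <- list(chrom = "chr1", start = 0L, end = 1000L)
  units <- build_sliding_windows(win, v, size = 1000L, step = 500L,
                                 max_maf = 0.05)
  y <- rank_inverse_normalize(
    as.numeric(G[, 1:4] %*% rep(1.2, 4)) + rnorm(n))
  res <- stepwise_aggregate_conditioning(units, G, y, threshold = 1e-5,
                                         config = test_config(max_maf =
                                                                0.05))
  sens <- sensitivity_condition_all_pqtls(res, units, G, y,
                                          config = test_config(max_maf =
                                                                 0.05))
  expect_equal(sens$p_after[1L], sens$p_before[1L], tolerance = 1e-10)
})
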