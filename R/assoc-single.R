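# Single-variant association and conditional-joint signal selection.
#
# All regressions are ordinary least squares on rank-inverse-normalized
# phenotypes. Covariates are projected out of the phenotype and the dosages
# once (Frisch-Waugh), which is exactly equivalent to including them in
# every per-variant model; the equivalence is asserted in the test suite.

#' Rank-inverse normalization
#'
#' Maps values to normal quantiles of their ranks,
#' `qnorm((rank - c) / (n - 2c + 1))` with the Blom offset `c = 3/8`.
#' Ties receive their average rank; missing values propagate.
#'
#' @param x numeric vector (at least 3 non-missing, not all identical).
#' @param offset rank offset `c` (default 3/8).
#' @return normalized vector, mean approximately 0.
#' @export
rank_inverse_normalize <- function(x, offset = 3 / 8) {
  ok <- !is.na(x)
  n <- sum(ok)
  assert_that(n >= 3, "need at least 3 non-missing values")
  assert_that(length(unique(x[ok])) > 1,
              "all values identical; ranks carry no information")
  r <- rank(x[ok], ties.method = "average")
  out <- rep(NA_real_, length(x))
  out[ok] <- stats::qnorm((r - offset) / (n - 2 * offset + 1))
  out
}

# Build the covariate design matrix (intercept always included) and check
# for rank deficiency, naming the offending columns.
#' @noRd
covariate_matrix <- function(X, n) {
  if (is.null(X)) return(matrix(1, n, 1, dimnames = list(NULL, "intercept")))
  if (is.data.frame(X)) {
    X <- X[, setdiff(names(X), "sample_id"), drop = FALSE]
    X <- stats::model.matrix(~ ., X)
    colnames(X)[1L] <- "intercept"
  } else {
    X <- cbind(intercept = 1, X)
  }
  q <- qr(X)
  if (q$rank < ncol(X)) {
    bad <- colnames(X)[q$pivot[(q$rank + 1L):ncol(X)]]
    stop("rank-deficient covariates; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  X
}

#' Two-sided log10 P from a t statistic, computed in log space
#'
#' `log10(P) = log10(e) * (pt(-|beta/se|, df, log = TRUE) + log(2))`, which
#' never underflows to -Inf for finite statistics. Degrees of freedom
#' default to `N - 2`; `df = "nk2"` uses `N - k - 2` to account for `k`
#' covariates.
#'
#' @param beta,se effect estimate and standard error (`se > 0`).
#' @param n sample size (`> 2`).
#' @param df `"n2"` (default) or `"nk2"`.
#' @param k number of covariates (used only for `df = "nk2"`).
#' @return log10 of the two-sided P value (<= 0, finite).
#' @export
log10p_from_t <- function(beta, se, n, df = c("n2", "nk2"), k = 0) {
  assert_that(all(se > 0), "se must be > 0")
  assert_that(all(n > 2), "n must be > 2")
  df <- match.arg(df)
  nu <- if (df == "n2") n - 2 else n - k - 2
  log10(exp(1)) * (stats::pt(-abs(beta / se), df = nu, log.p = TRUE) +
                     log(2))
}

#' @noRd
log10p_df <- function(t, nu) {
  log10(exp(1)) * (stats::pt(-abs(t), df = nu, log.p = TRUE) + log(2))
}

#' Single-variant association scan
#'
#' Per-variant OLS of the (already rank-inverse normalized) phenotype on
#' dosage plus covariates. Variants with minor allele count below `min_mac`
#' are skipped. Missing dosages are mean-imputed for regression only;
#' MAC/MAF are computed on observed calls.
#'
#' @param G samples x variants dosage matrix.
#' @param y normalized phenotype vector.
#' @param X covariate data.frame or matrix (intercept added internally).
#' @param min_mac minimum minor allele count (default 5).
#' @return data.frame: `vid`, `n`, `mac`, `maf`, `beta`, `se`, `t`, `p`,
#'   `log10p` (P values use residual degrees of freedom `n - k - 2`).
#' @export
single_variant_assoc <- function(G, y, X = NULL, min_mac = 5) {
  n <- length(y)
  stopifnot(nrow(G) == n)
  Xm <- covariate_matrix(X, n)
  s <- allele_summary(G)
  keep <- which(s$mac >= min_mac)
  Gk <- impute_dosage(G[, keep, drop = FALSE])
  qx <- qr(Xm)
  ry <- qr.resid(qx, y)
  RG <- qr.resid(qx, Gk)
  sg2 <- colSums(RG^2)
  sg2[sg2 <= 0] <- NA
  beta <- colSums(RG * ry) / sg2
  nu <- n - ncol(Xm) - 1
  rss <- pmax(sum(ry^2) - beta^2 * sg2, 0)
  se <- sqrt(rss / nu / sg2)
  tstat <- beta / se
  data.frame(vid = colnames(G)[keep] %||% as.character(keep),
             n = n, mac = s$mac[keep], maf = s$maf[keep],
             beta = beta, se = se, t = tstat,
             p = 2 * stats::pt(-abs(tstat), nu),
             log10p = log10p_df(tstat, nu),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Squared Pearson correlation between two dosage vectors
#'
#' Pairwise-complete observations; errors on monomorphic input.
#'
#' @param a,b dosage vectors.
#' @return r-squared in `[0, 1]`.
#' @export
ld_r2 <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  assert_that(stats::var(a[ok]) > 0 && stats::var(b[ok]) > 0,
              "monomorphic input: LD undefined")
  stats::cor(a[ok], b[ok])^2
}

#' Conditional-joint selection of independent signals
#'
#' Forward-backward stepwise selection of jointly significant variants,
#' performed on individual-level data: because the LD reference equals the
#' discovery sample, residualizing the phenotype and candidate dosages on
#' the selected set is exactly equivalent to summary-statistic
#' conditional-joint algebra, and the final joint estimates equal a direct
#' multiple regression on the selected dosages. There is no
#' collinearity-ratio filter on variance-explained (it removes genuine
#' large-effect signals when the LD panel matches the sample); instead a
#' candidate is skipped if its dosage r-squared with any selected variant
#' exceeds `r2_guard`, which keeps joint fits non-singular.
#'
#' Forward ties are broken by smaller P, then larger MAC, then position.
#'
#' @param G dosage matrix (columns named by vid).
#' @param y normalized phenotype.
#' @param X covariates.
#' @param p_threshold selection threshold (default 2.95e-10).
#' @param r2_guard pairwise r-squared guard (default 0.99).
#' @param diff_freq retained for interface compatibility with
#'   summary-statistic implementations; a no-op here since the allele
#'   frequencies of panel and sample are identical by construction.
#' @param min_mac minimum MAC for candidacy (default 5).
#' @param variants optional data.frame with `vid` and `pos` for tie-breaks.
#' @param max_iter safety cap on outer iterations.
#' @return object of class `joint_signal_set`: list with `signals`
#'   (data.frame of vid, mac, maf, beta_marginal, beta_joint, se_joint,
#'   p_joint, log10p_joint), `max_abs_beta_discrepancy`, `p_threshold`,
#'   `n`.
#' @export
cojo_select <- function(G, y, X = NULL, p_threshold = 2.95e-10,
                        r2_guard = 0.99, diff_freq = 0.2, min_mac = 5,
                        variants = NULL, max_iter = 100L) {
  n <- length(y)
  Xm <- covariate_matrix(X, n)
  s <- allele_summary(G)
  cand <- which(s$mac >= min_mac)
  vids <- colnames(G) %||% as.character(seq_len(ncol(G)))
  pos <- if (!is.null(variants))
    variants$pos[match(vids, variants$vid)] else seq_along(vids)

  Gi <- impute_dosage(G)
  qx <- qr(Xm)
  ry <- qr.resid(qx, y)
  RG <- qr.resid(qx, Gi)
  kX <- ncol(Xm)
  base_sg2 <- colSums(RG^2)

  marginal <- single_variant_assoc(G, y, X, min_mac = min_mac)

  sel <- integer(0)
  log10_thr <- log10(p_threshold)

  joint_fit <- function(sel) {
    S <- RG[, sel, drop = FALSE]
    qs <- qr(S)
    coef <- qr.coef(qs, ry)
    res <- qr.resid(qs, ry)
    nu <- n - kX - length(sel)
    sigma2 <- sum(res^2) / nu
    XtXinv <- chol2inv(qr.R(qs))
    se <- sqrt(sigma2 * diag(XtXinv))
    t <- coef / se
    list(beta = coef, se = se, t = t, nu = nu,
         log10p = log10p_df(t, nu), rss = sum(res^2))
  }

  backward <- function(sel) {
    while (length(sel) > 0) {
      jf <- joint_fit(sel)
      if (all(jf$log10p < log10_thr)) break
      worst <- which.max(jf$log10p)
      sel <- sel[-worst]
    }
    sel
  }

  for (iter in seq_len(max_iter)) {
    pool <- setdiff(cand, sel)
    if (length(pool) == 0L) break
    # r2 guard against already-selected variants
    if (length(sel) > 0) {
      r2max <- apply(stats::cor(Gi[, pool, drop = FALSE],
                                Gi[, sel, drop = FALSE])^2, 1L, max)
      pool <- pool[!is.na(r2max) & r2max <= r2_guard]
      if (length(pool) == 0L) break
    }
    if (length(sel) > 0) {
      qs <- qr(RG[, sel, drop = FALSE])
      ry2 <- qr.resid(qs, ry)
      RC <- qr.resid(qs, RG[, pool, drop = FALSE])
    } else {
      ry2 <- ry
      RC <- RG[, pool, drop = FALSE]
    }
    sg2 <- colSums(RC^2)
    ok <- sg2 > 1e-8 * base_sg2[pool]
    if (!any(ok)) break
    nu <- n - kX - length(sel) - 1
    beta <- ifelse(ok, colSums(RC * ry2) / sg2, NA)
    rssv <- pmax(sum(ry2^2) - beta^2 * sg2, 0)
    tstat <- beta / sqrt(rssv / nu / sg2)
    lp <- ifelse(ok, log10p_df(tstat, nu), 0)
    ord <- order(lp, -s$mac[pool], pos[pool])
    best <- ord[1L]
    if (lp[best] >= log10_thr) break
    newly <- pool[best]
    sel <- backward(c(sel, newly))
    # if the backward step immediately rejects the new variant, bar it from
    # re-entry so the loop cannot cycle
    if (!(newly %in% sel)) cand <- setdiff(cand, newly)
  }

  if (length(sel) == 0L) {
    return(structure(list(
      signals = data.frame(vid = character(0), pos = numeric(0),
                           mac = numeric(0), maf = numeric(0),
                           beta_marginal = numeric(0),
                           beta_joint = numeric(0), se_joint = numeric(0),
                           p_joint = numeric(0), log10p_joint = numeric(0)),
      max_abs_beta_discrepancy = 0, p_threshold = p_threshold,
      diff_freq = diff_freq, n = n), class = "joint_signal_set"))
  }

  jf <- joint_fit(sel)
  bm <- marginal$beta[match(vids[sel], marginal$vid)]
  sig <- data.frame(vid = vids[sel], pos = pos[sel], mac = s$mac[sel],
                    maf = s$maf[sel], beta_marginal = bm,
                    beta_joint = as.numeric(jf$beta),
                    se_joint = as.numeric(jf$se),
                    p_joint = 2 * stats::pt(-abs(jf$t), jf$nu),
                    log10p_joint = as.numeric(jf$log10p),
                    stringsAsFactors = FALSE)
  sig <- sig[order(sig$pos), , drop = FALSE]
  rownames(sig) <- NULL
  structure(list(signals = sig,
                 max_abs_beta_discrepancy =
                   max(abs(sig$beta_marginal - sig$beta_joint)),
                 p_threshold = p_threshold, diff_freq = diff_freq, n = n),
            class = "joint_signal_set")
}

#' Variance explained by the joint signal set
#'
#' R-squared increment of the selected dosages over the covariate-only
#' model, relative to the total phenotype variance.
#'
#' @param signals a [cojo_select()] result (or character vector of vids).
#' @param G dosage matrix.
#' @param y normalized phenotype.
#' @param X covariates.
#' @return proportion in `[0, 1]` (0 for an empty set).
#' @export
variance_explained <- function(signals, G, y, X = NULL) {
  vids <- if (inherits(signals, "joint_signal_set"))
    signals$signals$vid else signals
  if (length(vids) == 0L) return(0)
  n <- length(y)
  Xm <- covariate_matrix(X, n)
  qx <- qr(Xm)
  ry <- qr.resid(qx, y)
  RG <- qr.resid(qx, impute_dosage(G[, vids, drop = FALSE]))
  rss_cov <- sum(ry^2)
  rss_full <- sum(qr.resid(qr(RG), ry)^2)
  (rss_cov - rss_full) / sum((y - mean(y))^2)
}
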