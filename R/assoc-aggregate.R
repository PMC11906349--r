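# Rare-variant aggregate association tests under layered conditioning.
#
# The conditioning contract is implemented by projection: the phenotype is
# residualized on covariates plus the conditioning dosages once, and every
# aggregate statistic is computed on genotypes projected onto the same
# orthogonal complement, so aggregate tests are exactly conditional.

#' Aggregate-test configuration
#'
#' @param max_maf rare-variant threshold for membership (default 0.001).
#' @param a1,a2 Beta-density MAF weight parameters (defaults 1 and 25, the
#'   usual up-weighting of the rarest variants).
#' @param skat_method p-value method for the SKAT mixture null
#'   (see [pchisqsum()]).
#' @param tests which tests to run in a scan.
#' @return list of class `test_config`.
#' @export
test_config <- function(max_maf = 0.001, a1 = 1, a2 = 25,
                        skat_method = "auto",
                        tests = c("BURDEN", "SKAT", "ACAT_V", "ACAT_O",
                                  "SINGLETON")) {
  assert_that(a1 > 0 && a2 > 0, "weight parameters must be > 0")
  assert_that(max_maf > 0 && max_maf <= 0.5, "max_maf must be in (0, 0.5]")
  structure(list(max_maf = max_maf, a1 = a1, a2 = a2,
                 skat_method = skat_method, tests = tests),
            class = "test_config")
}

#' Beta-density MAF weights
#' @param maf minor allele frequencies.
#' @param a1,a2 Beta parameters.
#' @return numeric weights.
#' @export
beta_weights <- function(maf, a1 = 1, a2 = 25) {
  stats::dbeta(pmin(pmax(maf, 1e-12), 1 - 1e-12), a1, a2)
}

#' Build the step-1 conditioning set
#'
#' The primary noncoding discovery adjustment: common lead variants from
#' the conditional-joint analysis (MAF above `maf_min`) together with every
#' variant annotated as coding for the cognate gene, regardless of its
#' association P value.
#'
#' @param joint a [cojo_select()] result.
#' @param variants variant data.frame (`vid`, `maf`, `classification`,
#'   `annotated_gene`).
#' @param cognate_gene gene id of the measured protein.
#' @param maf_min lead-variant frequency floor (default 0.001; the
#'   common-variant convention 0.01 is available by argument).
#' @return character vector of vids (possibly empty).
#' @export
build_conditioning_set <- function(joint, variants, cognate_gene,
                                   maf_min = 0.001) {
  leads <- character(0)
  if (!is.null(joint) && nrow(joint$signals) > 0)
    leads <- joint$signals$vid[joint$signals$maf > maf_min]
  coding <- variants$vid[variants$classification == "coding" &
                           !is.na(variants$annotated_gene) &
                           variants$annotated_gene == cognate_gene]
  union(leads, coding)
}

#' Residualize a phenotype on covariates and conditioning dosages
#'
#' @param y phenotype vector (normalized).
#' @param X covariates (intercept added internally).
#' @param C optional conditioning dosage matrix (duplicated/collinear
#'   columns are dropped before projection).
#' @return object of class `adjusted_pheno`: residual `y`, the projection
#'   `qr`, `rank`, `n`.
#' @export
residualize <- function(y, X = NULL, C = NULL) {
  n <- length(y)
  Xm <- covariate_matrix(X, n)
  if (!is.null(C) && ncol(C) > 0) {
    assert_that(ncol(C) < n - ncol(Xm),
                "more conditioning columns than samples allow")
    C <- impute_dosage(C)
    M <- cbind(Xm, C)
    q0 <- qr(M)
    if (q0$rank < ncol(M)) M <- M[, q0$pivot[seq_len(q0$rank)], drop = FALSE]
  } else {
    M <- Xm
  }
  qx <- qr(M)
  structure(list(y = qr.resid(qx, y), qr = qx, rank = qx$rank, n = n),
            class = "adjusted_pheno")
}

#' @noRd
project_genotypes <- function(adj, G) {
  qr.resid(adj$qr, impute_dosage(G))
}

#' @noRd
agg_row <- function(test, p, log10p, beta = NA_real_, se = NA_real_,
                    n_variants = NA_integer_, cum_mac = NA_real_,
                    untestable = FALSE) {
  data.frame(test = test, n_variants = n_variants, cum_mac = cum_mac,
             beta = beta, se = se, p = p, log10p = log10p,
             untestable = untestable, stringsAsFactors = FALSE)
}

#' Burden test
#'
#' Collapses the unit to a weighted carrier score `b_i = sum_j w_j g_ij`
#' and regresses the adjusted phenotype on it; assumes all member variants
#' share direction and magnitude of effect.
#'
#' @param G dosage matrix of the unit's member variants.
#' @param adj an [residualize()] result.
#' @param weights per-variant weights (default Beta(1,25) on MAF).
#' @return one-row data.frame (`p = NA`, `untestable = TRUE` when the unit
#'   has no carriers).
#' @export
burden_test <- function(G, adj, weights = NULL) {
  s <- allele_summary(G)
  if (is.null(weights)) weights <- beta_weights(s$maf)
  raw_nonzero <- sum(abs(impute_dosage(G) %*% weights)) > 0
  Gp <- project_genotypes(adj, G)
  burden_core(Gp %*% weights, adj, ncol(G), sum(s$mac),
              raw_nonzero = raw_nonzero)
}

# Burden regression on an already-projected carrier score.
#' @noRd
burden_core <- function(bp, adj, n_variants, cum_mac, test = "BURDEN",
                        raw_nonzero = TRUE) {
  sb2 <- sum(bp^2)
  if (!raw_nonzero || sb2 <= 0)
    return(agg_row(test, NA, NA, n_variants = n_variants,
                   cum_mac = cum_mac, untestable = TRUE))
  beta <- sum(bp * adj$y) / sb2
  nu <- adj$n - adj$rank - 1
  rss <- max(sum(adj$y^2) - beta^2 * sb2, 0)
  se <- sqrt(rss / nu / sb2)
  t <- beta / se
  agg_row(test, 2 * stats::pt(-abs(t), nu), log10p_df(t, nu),
          beta = beta, se = se, n_variants = n_variants,
          cum_mac = cum_mac)
}

#' SKAT variance-component test
#'
#' `Q = sum_j w_j^2 S_j^2` with `S_j` the score of variant `j` on the
#' adjusted phenotype; the null is the matching mixture of chi-squares
#' whose weights are the eigenvalues of the weighted, projection-adjusted
#' genotype cross-product scaled by the residual variance.
#'
#' For multi-variant kernels the statistic is first rescaled so that the
#' null matches the exact permutation mean and variance of `Q` given the
#' observed phenotype (closed-form for a double-centred kernel); with few
#' carriers per variant the Gaussian mixture otherwise overstates the
#' null variance by O(1/n). Single-variant units skip the adjustment so
#' that they reduce exactly to the standard two-sided score test.
#'
#' @inheritParams burden_test
#' @param method p-value method passed to [pchisqsum()].
#' @param moment_adjust apply the exact permutation-moment rescaling
#'   (default TRUE; only active for units of two or more variants).
#' @return one-row data.frame.
#' @export
skat_test <- function(G, adj, weights = NULL, method = "auto",
                      moment_adjust = TRUE) {
  s <- allele_summary(G)
  if (is.null(weights)) weights <- beta_weights(s$maf)
  Gp <- project_genotypes(adj, G)
  skat_core(sweep(Gp, 2L, weights, "*"), adj, ncol(G), sum(s$mac),
            method = method, moment_adjust = moment_adjust)
}

#' @noRd
skat_core <- function(Gw, adj, n_variants, cum_mac, method = "auto",
                      moment_adjust = TRUE) {
  if (all(abs(Gw) < 1e-12))
    return(agg_row("SKAT", NA, NA, n_variants = n_variants,
                   cum_mac = cum_mac, untestable = TRUE))
  Q <- sum(crossprod(Gw, adj$y)^2)
  n <- adj$n
  sigma2 <- sum(adj$y^2) / (n - adj$rank)
  lam0 <- eigen(crossprod(Gw), symmetric = TRUE,
                only.values = TRUE)$values
  lam0 <- lam0[lam0 > 0]
  lambda <- lam0 * sigma2
  if (moment_adjust && n_variants >= 2L) {
    mom <- skat_perm_moments(Gw, adj$y, lam0)
    if (is.finite(mom$var) && mom$var > 0) {
      eq_mix <- sum(lambda)
      scl <- sqrt(2 * sum(lambda^2) / mom$var)
      Q <- eq_mix + (Q - mom$mean) * scl
      if (Q <= 0)
        return(agg_row("SKAT", 1, 0, n_variants = n_variants,
                       cum_mac = cum_mac))
    }
  }
  pv <- pchisqsum(Q, lambda, method = method)
  agg_row("SKAT", pv$p, pv$log10p, n_variants = n_variants,
          cum_mac = cum_mac)
}

# Exact mean and variance of Q = y_pi' A y_pi over permutations pi, for
# the double-centred kernel A = Gw Gw' and centred y (both hold after
# projection on a design containing the intercept).
#' @noRd
skat_perm_moments <- function(Gw, y, lam0) {
  n <- length(y)
  p2 <- sum(y^2); p4 <- sum(y^4)
  diagA <- rowSums(Gw^2)
  t1 <- sum(lam0); t2 <- sum(lam0^2); d2 <- sum(diagA^2)
  n2 <- n * (n - 1); n3 <- n2 * (n - 2); n4 <- n3 * (n - 3)
  S22 <- p2^2 - p4
  S31 <- -p4
  S211 <- 2 * p4 - p2^2
  S1111 <- 3 * p2^2 - 6 * p4
  eq <- t1 * p2 / (n - 1)
  eq2 <- d2 * p4 / n + (t1^2 - d2) * S22 / n2 + 2 * (t2 - d2) * S22 / n2 +
    4 * (-d2) * S31 / n2 +
    (2 * (-t1^2 + 2 * d2) + 4 * (2 * d2 - t2)) * S211 / n3 +
    (t1^2 + 2 * t2 - 6 * d2) * S1111 / n4
  list(mean = eq, var = eq2 - eq^2)
}

#' Permutation reference for the SKAT statistic
#'
#' Monte-Carlo p-value from permutations of the adjusted phenotype; used
#' as an independent check of the mixture-of-chi-squares null, and as a
#' last-resort fallback when its numerics fail.
#'
#' @inheritParams skat_test
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return one-row data.frame (plus-one-corrected empirical p).
#' @export
skat_permutation <- function(G, adj, weights = NULL, n_perm = 2000L,
                             seed = 1L) {
  s <- allele_summary(G)
  if (is.null(weights)) weights <- beta_weights(s$maf)
  Gp <- project_genotypes(adj, G)
  Gw <- sweep(Gp, 2L, weights, "*")
  Q_obs <- sum(crossprod(Gw, adj$y)^2)
  set.seed(seed)
  Yp <- vapply(seq_len(n_perm), function(i) sample(adj$y), adj$y)
  Qp <- colSums(crossprod(Gw, Yp)^2)
  p <- (1 + sum(Qp >= Q_obs)) / (1 + n_perm)
  agg_row("SKAT_PERM", p, log10(p), n_variants = ncol(G),
          cum_mac = sum(s$mac))
}

#' Cauchy combination (ACAT-V) of per-variant p-values
#'
#' `T = sum_j w_j tan((0.5 - p_j) pi)` with normalized weights; the
#' combined p is the standard-Cauchy upper-tail probability of `T`.
#' Input p-values are clipped to `[1e-300, 1 - 1e-16]` to keep the tangent
#' finite at float precision.
#'
#' @param p per-variant p-values in (0, 1).
#' @param weights non-negative weights, not all zero (equal by default).
#' @return combined p-value.
#' @export
acat_v <- function(p, weights = NULL) {
  assert_that(length(p) > 0, "empty p-value input")
  p <- p[!is.na(p)]
  assert_that(length(p) > 0, "all p-values missing")
  if (is.null(weights)) weights <- rep(1, length(p))
  assert_that(all(weights >= 0) && sum(weights) > 0,
              "weights must be non-negative and not all zero")
  w <- weights / sum(weights)
  pc <- pmin(pmax(p, 1e-300), 1 - 1e-16)
  T <- sum(w * tan((0.5 - pc) * pi))
  # 0.5 - atan(T)/pi, via atan(1/T)/pi for T > 0 to keep full relative
  # precision in the tail (the two forms are identical analytically)
  if (T >= 0) atan(1 / T) / pi else 0.5 - atan(T) / pi
}

#' Omnibus (ACAT-O) combination of burden, SKAT and ACAT-V p-values
#'
#' Equal-weight Cauchy combination over the available component tests;
#' missing components are skipped.
#'
#' @param p_burden,p_skat,p_acat_v component p-values (NA to skip).
#' @return combined p-value, or `NA` if all components are missing.
#' @export
acat_o <- function(p_burden, p_skat, p_acat_v) {
  ps <- c(p_burden, p_skat, p_acat_v)
  ps <- ps[!is.na(ps)]
  if (length(ps) == 0L) return(NA_real_)
  acat_v(ps)
}

#' Singleton-only burden test
#'
#' Burden test restricted to the unit's MAC = 1 members.
#'
#' @inheritParams burden_test
#' @param mac per-variant minor allele counts (computed if missing).
#' @return one-row data.frame (`untestable` when the unit has no
#'   singletons).
#' @export
singleton_test <- function(G, adj, weights = NULL, mac = NULL) {
  if (is.null(mac)) mac <- allele_summary(G)$mac
  keep <- which(mac == 1)
  if (length(keep) == 0L)
    return(agg_row("SINGLETON", NA, NA, n_variants = 0L, cum_mac = 0,
                   untestable = TRUE))
  out <- burden_test(G[, keep, drop = FALSE], adj,
                     weights = weights[keep])
  out$test <- "SINGLETON"
  out
}

#' Combine per-mask p-values into an all-mask unit statistic
#'
#' Cauchy combination over mask-level (ACAT-O) p-values for one genome
#' unit. Coding and noncoding masks are never combined: passing a coding
#' mask into a noncoding combination is an error.
#'
#' @param p named vector of per-mask p-values.
#' @param mask_kind character vector, `"coding"` or `"noncoding"` per mask.
#' @return combined p-value.
#' @export
all_mask_combine <- function(p, mask_kind = rep("noncoding", length(p))) {
  assert_that(length(p) == length(mask_kind),
              "p and mask_kind lengths differ")
  kinds <- unique(mask_kind[!is.na(p)])
  assert_that(length(kinds) <= 1,
              "refusing to combine coding and noncoding masks in one all-mask statistic")
  acat_v(p[!is.na(p)])
}

# Per-variant two-sided p-values on the adjusted phenotype (vectorized
# marginal OLS in the projected space); feeds ACAT-V.
#' @noRd
per_variant_p <- function(G, adj) {
  per_variant_p_core(project_genotypes(adj, G), adj)
}

#' @noRd
per_variant_p_core <- function(Gp, adj) {
  sg2 <- colSums(Gp^2)
  nu <- adj$n - adj$rank - 1
  beta <- ifelse(sg2 > 0, colSums(Gp * adj$y) / sg2, NA)
  rss <- pmax(sum(adj$y^2) - beta^2 * sg2, 0)
  t <- beta / sqrt(rss / nu / sg2)
  2 * stats::pt(-abs(t), nu)
}

#' Run the aggregate test battery over a unit catalogue
#'
#' For each testable unit and each of its masks with at least one rare
#' member: burden, SKAT, ACAT-V, ACAT-O and the singleton test, followed
#' by a per-unit all-mask combination (noncoding masks only; coding-unit
#' masks are combined separately).
#'
#' @param units list of aggregate units (see [build_aggregate_units()]).
#' @param G full dosage matrix (columns named by vid).
#' @param adj an [residualize()] result.
#' @param config a [test_config()].
#' @param mask_kinds named character vector mapping mask name to
#'   `"coding"`/`"noncoding"` (defaults to the [default_masks()]
#'   catalogue; unknown masks are treated as noncoding).
#' @return data.frame of aggregate results, one row per unit x mask x test
#'   plus `ALL_MASK` rows.
#' @export
aggregate_scan <- function(units, G, adj, config = test_config(),
                           mask_kinds = NULL) {
  if (is.null(mask_kinds)) {
    dm <- default_masks()
    mask_kinds <- vapply(dm, `[[`, "", "kind")
    names(mask_kinds) <- names(dm)
  }
  out <- vector("list", length(units))
  for (i in seq_along(units)) {
    u <- units[[i]]
    masks <- u$masks %||% stats::setNames(list(u$members), u$mask)
    masks <- masks[vapply(masks, length, 0L) > 0]
    if (length(masks) == 0L) next
    rows <- list()
    for (mn in names(masks)) {
      vids <- intersect(masks[[mn]], colnames(G))
      if (length(vids) == 0L) next
      Gu <- G[, vids, drop = FALSE]
      s <- allele_summary(Gu)
      w <- beta_weights(s$maf, config$a1, config$a2)
      # one projection per unit-mask, shared by every test
      Gp <- project_genotypes(adj, Gu)
      rb <- if ("BURDEN" %in% config$tests)
        burden_core(Gp %*% w, adj, ncol(Gu), sum(s$mac)) else NULL
      rs <- if ("SKAT" %in% config$tests)
        skat_core(sweep(Gp, 2L, w, "*"), adj, ncol(Gu), sum(s$mac),
                  method = config$skat_method) else NULL
      pa <- if ("ACAT_V" %in% config$tests) {
        pj <- per_variant_p_core(Gp, adj)
        ok <- !is.na(pj)
        if (any(ok)) acat_v(pj[ok], (w^2 * s$maf * (1 - s$maf))[ok])
        else NA_real_
      } else NA_real_
      ra <- agg_row("ACAT_V", pa, ifelse(is.na(pa), NA, log10(pa)),
                    n_variants = ncol(Gu), cum_mac = sum(s$mac),
                    untestable = is.na(pa))
      po <- acat_o(rb$p, rs$p, pa)
      ro <- agg_row("ACAT_O", po, ifelse(is.na(po), NA, log10(po)),
                    n_variants = ncol(Gu), cum_mac = sum(s$mac),
                    untestable = is.na(po))
      rg <- if ("SINGLETON" %in% config$tests) {
        keep <- which(s$mac == 1)
        if (length(keep) == 0L)
          agg_row("SINGLETON", NA, NA, n_variants = 0L, cum_mac = 0,
                  untestable = TRUE)
        else
          burden_core(Gp[, keep, drop = FALSE] %*% w[keep], adj,
                      length(keep), length(keep), test = "SINGLETON")
      } else NULL
      mrows <- rbind(rb, rs, ra, ro, rg)
      mrows$mask <- mn
      rows[[length(rows) + 1L]] <- mrows
    }
    if (length(rows) == 0L) next
    rows <- do.call(rbind, rows)
    oc <- rows[rows$test == "ACAT_O" & !rows$untestable, , drop = FALSE]
    if (nrow(oc) > 0) {
      kinds <- unname(mask_kinds[oc$mask])
      kinds[is.na(kinds)] <- "noncoding"
      for (kd in unique(kinds)) {
        sel <- kinds == kd
        pall <- all_mask_combine(stats::setNames(oc$p[sel], oc$mask[sel]),
                                 rep(kd, sum(sel)))
        ar <- agg_row("ALL_MASK", pall, log10(pall),
                      n_variants = max(oc$n_variants[sel]),
                      cum_mac = max(oc$cum_mac[sel]))
        ar$mask <- paste0("all_", kd)
        rows <- rbind(rows, ar)
      }
    }
    rows$unit_id <- u$unit_id
    rows$unit_kind <- u$unit_kind
    rows$start <- u$start
    rows$end <- u$end
    out[[i]] <- rows
  }
  out <- do.call(rbind, out)
  if (is.null(out)) return(NULL)
  rownames(out) <- NULL
  out[, c("unit_id", "unit_kind", "start", "end", "mask", "test",
          "n_variants", "cum_mac", "beta", "se", "p", "log10p",
          "untestable")]
}

# Unit-level ranking statistic for the stepwise procedure: the noncoding
# all-mask p where present, else the best mask-level ACAT-O.
#' @noRd
unit_level_p <- function(scan) {
  am <- scan[scan$test == "ALL_MASK" & scan$mask == "all_noncoding" &
               !is.na(scan$p), , drop = FALSE]
  oc <- scan[scan$test == "ACAT_O" & !is.na(scan$p), , drop = FALSE]
  ids <- unique(scan$unit_id)
  p <- vapply(ids, function(id) {
    a <- am$p[am$unit_id == id]
    if (length(a) > 0) return(min(a))
    o <- oc$p[oc$unit_id == id]
    if (length(o) > 0) return(min(o)) else return(NA_real_)
  }, 0)
  data.frame(unit_id = ids, p = p, stringsAsFactors = FALSE)
}

#' Forward stepwise aggregate-independence procedure
#'
#' Starting from the most strongly associated noncoding aggregate, adds
#' all of its member variants to the conditioning set and re-tests the
#' remaining significant aggregates, repeating until none passes the
#' aggregate threshold. Ranking uses the unit-level omnibus p; ties break
#' by smaller unit span, then position.
#'
#' @param units aggregate-unit catalogue (noncoding units are used).
#' @param G dosage matrix.
#' @param y normalized phenotype.
#' @param X covariates.
#' @param base_conditioning vids of the step-1 conditioning set.
#' @param threshold aggregate significance threshold (default 8.71e-9).
#' @param config a [test_config()].
#' @param max_iter iteration cap; exceeding it raises an error of class
#'   `rarecis_nonconvergence` carrying the partial result.
#' @return data.frame of conditionally independent aggregates with
#'   `iteration`, unit columns, `p`, `log10p`, `members` (comma-joined)
#'   and `conditioning_set_size`; zero rows when nothing is significant.
#' @export
stepwise_aggregate_conditioning <- function(units, G, y, X = NULL,
                                            base_conditioning = character(0),
                                            threshold = 8.71e-9,
                                            config = test_config(),
                                            max_iter = 25L) {
  units <- Filter(function(u) length(u$members %||% character(0)) > 0 &&
                    !identical(u$unit_kind, "gene_coding"), units)
  empty <- data.frame(iteration = integer(0), unit_id = character(0),
                      unit_kind = character(0), start = numeric(0),
                      end = numeric(0), p = numeric(0),
                      log10p = numeric(0), n_variants = integer(0),
                      members = character(0),
                      conditioning_set_size = integer(0),
                      stringsAsFactors = FALSE)
  if (length(units) == 0L) return(empty)
  cond <- intersect(base_conditioning, colnames(G))
  active <- units
  recorded <- list()
  for (iter in seq_len(max_iter + 1L)) {
    if (length(active) == 0L) break
    adj <- residualize(y, X, if (length(cond) > 0)
      G[, cond, drop = FALSE] else NULL)
    scan <- aggregate_scan(active, G, adj, config)
    if (is.null(scan)) break
    up <- unit_level_p(scan)
    up <- up[!is.na(up$p) & up$p < threshold, , drop = FALSE]
    if (nrow(up) == 0L) break
    if (iter > max_iter) {
      partial <- do.call(rbind, recorded)
      cnd <- structure(
        class = c("rarecis_nonconvergence", "error", "condition"),
        list(message = sprintf(
          "stepwise aggregate conditioning did not converge in %d iterations",
          max_iter), call = sys.call(-1L), partial = partial))
      stop(cnd)
    }
    info <- lapply(up$unit_id, function(id)
      active[[which(vapply(active, `[[`, "", "unit_id") == id)]])
    span <- vapply(info, function(u) u$end - u$start, 0)
    pos0 <- vapply(info, `[[`, 0, "start")
    ord <- order(up$p, span, pos0)
    top <- info[[ord[1L]]]
    top_p <- up$p[ord[1L]]
    recorded[[length(recorded) + 1L]] <- data.frame(
      iteration = length(recorded) + 1L, unit_id = top$unit_id,
      unit_kind = top$unit_kind, start = top$start, end = top$end,
      p = top_p, log10p = log10(top_p),
      n_variants = length(top$members),
      members = paste(top$members, collapse = ","),
      conditioning_set_size = length(cond), stringsAsFactors = FALSE)
    cond <- union(cond, intersect(top$members, colnames(G)))
    keep_ids <- setdiff(up$unit_id, top$unit_id)
    active <- Filter(function(u) u$unit_id %in% keep_ids, active)
  }
  if (length(recorded) == 0L) return(empty)
  out <- do.call(rbind, recorded)
  rownames(out) <- NULL
  out
}

#' Annotate independent aggregates by lead-variant content
#'
#' Counts, per aggregate, how many of its members are lead (jointly
#' selected) variants and whether any member reaches study-wide
#' single-variant significance.
#'
#' @param aggregates result of [stepwise_aggregate_conditioning()].
#' @param lead_vids lead variant ids from the joint analysis.
#' @param sv_results single-variant results (`vid`, `p`).
#' @param sv_threshold study-wide single-variant threshold.
#' @return the input with `n_leads`, `lead_category`
#'   (`"0"`, `"1"`, `">1"`) and `contains_studywide_variant` columns.
#' @export
flag_single_lead_aggregates <- function(aggregates, lead_vids,
                                        sv_results = NULL,
                                        sv_threshold = 2.95e-10) {
  if (nrow(aggregates) == 0L) {
    aggregates$n_leads <- integer(0)
    aggregates$lead_category <- character(0)
    aggregates$contains_studywide_variant <- logical(0)
    return(aggregates)
  }
  mem <- strsplit(aggregates$members, ",", fixed = TRUE)
  nl <- vapply(mem, function(v) length(intersect(v, lead_vids)), 0L)
  aggregates$n_leads <- nl
  aggregates$lead_category <- ifelse(nl == 0L, "0",
                                     ifelse(nl == 1L, "1", ">1"))
  aggregates$contains_studywide_variant <- vapply(mem, function(v) {
    if (is.null(sv_results)) return(NA)
    any(sv_results$p[match(v, sv_results$vid)] < sv_threshold,
        na.rm = TRUE)
  }, NA)
  aggregates
}

#' Sensitivity re-test conditioning on all identified pQTLs
#'
#' Re-tests the independent aggregates with the conditioning set expanded
#' by every identified single-variant pQTL, reporting p before and after.
#'
#' @param aggregates result of [stepwise_aggregate_conditioning()].
#' @param units the unit catalogue used for discovery.
#' @param G dosage matrix.
#' @param y normalized phenotype.
#' @param X covariates.
#' @param base_conditioning the step-1 conditioning vids.
#' @param pqtl_vids all identified pQTL single-variant ids.
#' @param config a [test_config()].
#' @return data.frame `unit_id`, `p_before`, `p_after`.
#' @export
sensitivity_condition_all_pqtls <- function(aggregates, units, G, y,
                                            X = NULL,
                                            base_conditioning = character(0),
                                            pqtl_vids = character(0),
                                            config = test_config()) {
  if (nrow(aggregates) == 0L)
    return(data.frame(unit_id = character(0), p_before = numeric(0),
                      p_after = numeric(0), stringsAsFactors = FALSE))
  ids <- aggregates$unit_id
  sel <- Filter(function(u) u$unit_id %in% ids, units)
  cond <- intersect(union(base_conditioning, pqtl_vids), colnames(G))
  adj <- residualize(y, X, if (length(cond) > 0)
    G[, cond, drop = FALSE] else NULL)
  scan <- aggregate_scan(sel, G, adj, config)
  up <- unit_level_p(scan)
  data.frame(unit_id = ids, p_before = aggregates$p,
             p_after = up$p[match(ids, up$unit_id)],
             stringsAsFactors = FALSE)
}
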