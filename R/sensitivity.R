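#' MR-PRESSO global heterogeneity and outlier test
#'
#' Simulation-based residual test for horizontal pleiotropy. The observed
#' global statistic is the weighted residual sum of squares
#' `RSS = sum_j w_j (beta_outcome_j - b_(-j) * beta_exposure_j)^2` with
#' `w_j = 1 / se_outcome_j^2`, where `b_(-j)` is the IVW slope (weighted
#' regression through the origin of outcome on exposure effects) computed
#' with instrument j left out. The null distribution is built by drawing,
#' `n_sim` times, outcome effects from
#' `Normal(b_(-j) * beta_exposure_j, se_outcome_j^2)` and recomputing the
#' RSS; the global p-value uses the add-one rule
#' `(1 + #\{RSS_sim >= RSS_obs\}) / (n_sim + 1)`, so its floor is
#' `1 / (n_sim + 1)`. Each instrument's observed weighted residual is
#' compared with its simulated counterparts the same way, and instruments
#' with a Bonferroni-significant per-SNP p-value
#' (`p < outlier_alpha / n`) are reported as outliers.
#'
#' @param pairs Harmonised pairs with at least 4 usable instruments.
#' @param n_sim Number of null simulations (default 1000).
#' @param seed Integer seed.
#' @param outlier_alpha Family-wise level for outlier calling
#'   (default 0.05, Bonferroni-corrected across instruments).
#' @return List of class `mr_presso`: `global_rss_obs`, `global_pval`,
#'   `outlier_ids`, `per_snp_pvals` (named), `n_sim`, `seed`.
#' @export
mr_presso <- function(pairs, n_sim = 1000, seed = 1L,
                      outlier_alpha = 0.05) {
  p <- usable_pairs(pairs)
  n <- nrow(p)
  if (n < 4) stop("MR-PRESSO needs at least 4 instruments", call. = FALSE)
  bx <- p$beta_exposure
  by <- p$beta_outcome
  se <- p$se_outcome
  w <- 1 / se^2

  # leave-one-out IVW slopes from full sums
  s_xy <- sum(w * bx * by)
  s_xx <- sum(w * bx^2)
  b_loo <- (s_xy - w * bx * by) / (s_xx - w * bx^2)
  resid_obs <- w * (by - b_loo * bx)^2
  rss_obs <- sum(resid_obs)

  rng <- local_rng(seed)
  mu <- b_loo * bx
  by_sim <- matrix(stats::rnorm(n * n_sim, mu, se), nrow = n)
  s_xy_sim <- colSums(w * bx * by_sim)
  # per-simulation leave-one-out slopes: (n x n_sim) matrix
  b_loo_sim <- (matrix(s_xy_sim, n, n_sim, byrow = TRUE) -
                  (w * bx) * by_sim) / (s_xx - w * bx^2)
  resid_sim <- w * (by_sim - b_loo_sim * bx)^2
  rss_sim <- colSums(resid_sim)

  global_pval <- (1 + sum(rss_sim >= rss_obs)) / (n_sim + 1)
  per_snp <- (1 + rowSums(resid_sim >= resid_obs)) / (n_sim + 1)
  names(per_snp) <- p$snp_id
  outliers <- p$snp_id[per_snp < outlier_alpha / n]

  structure(
    list(global_rss_obs = rss_obs, global_pval = global_pval,
         outlier_ids = outliers, per_snp_pvals = per_snp,
         n_sim = n_sim, seed = seed),
    class = "mr_presso"
  )
}

#' @export
print.mr_presso <- function(x, ...) {
  cat(sprintf("MR-PRESSO global RSS = %.3f, p = %.4g (%d simulations)\n",
              x$global_rss_obs, x$global_pval, x$n_sim))
  if (length(x$outlier_ids) > 0) {
    cat("outliers:", paste(x$outlier_ids, collapse = ", "), "\n")
  } else {
    cat("no outliers detected\n")
  }
  invisible(x)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values: with order statistics `p_(1) <= ... <= p_(m)`
#' the adjusted value of `p_(i)` is
#' `min over j >= i of min(1, m p_(j) / j)`, mapped back to input order.
#' Delegates to [stats::p.adjust()] after validating the input range.
#'
#' @param pvals Numeric vector of p-values in (0, 1\].
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  if (any(!is.finite(pvals) | pvals <= 0 | pvals > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Horizontal-pleiotropy exclusion gate
#'
#' An exposure is excluded from causal calling when either pleiotropy
#' diagnostic fires: the MR-Egger intercept test at level `alpha`, or the
#' MR-PRESSO global test at level `alpha` with at least one outlier left
#' unresolved. Exposures with too few instruments for the diagnostics pass
#' the gate and are flagged untested.
#'
#' @param results Screen-result tibble with columns
#'   `egger_intercept_pval` and `presso_global_pval`, `presso_n_outliers`
#'   (NA where not applicable).
#' @param alpha Gate significance level (default 0.05).
#' @return The tibble with logical columns `pleiotropy_excluded` and
#'   `pleiotropy_tested` set.
#' @export
pleiotropy_gate <- function(results, alpha = 0.05) {
  egger_fire <- !is.na(results$egger_intercept_pval) &
    results$egger_intercept_pval < alpha
  presso_fire <- !is.na(results$presso_global_pval) &
    results$presso_global_pval < alpha &
    !is.na(results$presso_n_outliers) & results$presso_n_outliers >= 1
  results$pleiotropy_tested <- !is.na(results$egger_intercept_pval) |
    !is.na(results$presso_global_pval)
  results$pleiotropy_excluded <- egger_fire | presso_fire
  results
}

#' Two-tier significance calling with FDR within family
#'
#' Applies Benjamini-Hochberg correction to the primary MR p-values of all
#' non-excluded exposures (within each `family` separately when present)
#' and assigns a tier: `"significant"` when both raw and FDR-adjusted
#' p-values fall below `alpha`; `"potential"` when the raw p-value does
#' but the adjusted one does not; `"null"` otherwise;
#' `"excluded_pleiotropy"` for gated-out exposures, which take no part in
#' the FDR family.
#'
#' @param results Screen-result tibble with `pval_raw`,
#'   `pleiotropy_excluded` and optionally `family`.
#' @param alpha Significance level (default 0.05).
#' @return The tibble with `pval_fdr` and `tier` columns filled in.
#' @export
tier_results <- function(results, alpha = 0.05) {
  results$pval_fdr <- NA_real_
  fam <- if ("family" %in% names(results)) results$family else
    rep("all", nrow(results))
  eligible <- !results$pleiotropy_excluded & !is.na(results$pval_raw)
  for (f in unique(fam)) {
    sel <- eligible & fam == f
    if (any(sel)) results$pval_fdr[sel] <- bh_adjust(results$pval_raw[sel])
  }
  results$tier <- dplyr::case_when(
    results$pleiotropy_excluded ~ "excluded_pleiotropy",
    is.na(results$pval_raw) ~ "not_analyzable",
    results$pval_raw < alpha & results$pval_fdr < alpha ~ "significant",
    results$pval_raw < alpha ~ "potential",
    TRUE ~ "null"
  )
  results
}
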