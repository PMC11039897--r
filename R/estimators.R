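ci_z <- function() stats::qnorm(0.975)

#' Per-instrument Wald ratios and their standard errors
#'
#' Computes `ratio_j = beta_outcome / beta_exposure` for each usable pair,
#' with the first-order delta-method standard error
#' `se_outcome / |beta_exposure|`; the second-order expansion adds the
#' exposure-noise term `beta_outcome^2 se_exposure^2 / beta_exposure^4`
#' under the square root.
#'
#' @param pairs Harmonised pairs ([harmonise()] output); removed rows are
#'   ignored.
#' @param second_order Use the second-order delta-method SE.
#' @return Tibble with `snp_id`, `ratio`, `se_ratio` and the originating
#'   effect columns.
#' @export
per_snp_ratios <- function(pairs, second_order = FALSE) {
  p <- usable_pairs(pairs)
  if (any(p$beta_exposure == 0)) {
    stop("degenerate instrument with beta_exposure = 0", call. = FALSE)
  }
  se_ratio <- if (second_order) {
    sqrt(p$se_outcome^2 / p$beta_exposure^2 +
           p$beta_outcome^2 * p$se_exposure^2 / p$beta_exposure^4)
  } else {
    p$se_outcome / abs(p$beta_exposure)
  }
  tibble(
    snp_id = p$snp_id,
    beta_exposure = p$beta_exposure, se_exposure = p$se_exposure,
    beta_outcome = p$beta_outcome, se_outcome = p$se_outcome,
    ratio = p$beta_outcome / p$beta_exposure,
    se_ratio = se_ratio
  )
}

mr_estimate_row <- function(method, beta, se, pval, n_snps,
                            effects_model = "not_applicable") {
  z <- ci_z()
  tibble(
    method = method, beta = beta, se = se, pval = pval,
    or_ = exp(beta), ci_low = exp(beta - z * se),
    ci_high = exp(beta + z * se),
    n_snps = as.integer(n_snps), effects_model = effects_model
  )
}

#' Wald ratio estimate from a single instrument
#'
#' The causal estimate for a one-instrument exposure:
#' `beta_outcome / beta_exposure`, with first-order delta-method SE and a
#' two-sided normal p-value. Effects are reported as OR with 95% CI.
#'
#' @param pair A one-row harmonised pair (or a table whose single usable
#'   row is taken).
#' @return One-row estimate tibble (`method = "wald_ratio"`).
#' @export
wald_ratio <- function(pair) {
  r <- per_snp_ratios(pair)
  if (nrow(r) != 1) {
    stop("wald_ratio expects exactly one usable instrument, got ", nrow(r),
         call. = FALSE)
  }
  beta <- r$ratio
  se <- r$se_ratio
  mr_estimate_row("wald_ratio", beta, se, two_sided_p(beta / se), 1L)
}

#' Cochran's Q heterogeneity test over per-instrument ratios
#'
#' `Q = sum_j w_j (ratio_j - beta_ivw)^2` with inverse-variance weights
#' `w_j = 1 / se_ratio_j^2` and the fixed-effects IVW estimate as centre;
#' the p-value comes from a chi-square distribution with `n - 1` degrees of
#' freedom.
#'
#' @param pairs Harmonised pairs with at least 2 usable instruments.
#' @return List with `q_stat`, `df`, `pval`.
#' @export
cochran_q <- function(pairs) {
  r <- per_snp_ratios(pairs)
  if (nrow(r) < 2) {
    stop("Cochran's Q needs at least 2 instruments", call. = FALSE)
  }
  w <- 1 / r$se_ratio^2
  b_fixed <- sum(w * r$ratio) / sum(w)
  q <- sum(w * (r$ratio - b_fixed)^2)
  df <- nrow(r) - 1L
  list(q_stat = q, df = df,
       pval = stats::pchisq(q, df, lower.tail = FALSE))
}

#' Inverse-variance-weighted estimate with the fixed/random rule
#'
#' The primary MR estimator: the inverse-variance-weighted mean of the
#' per-instrument Wald ratios. Heterogeneity is assessed with Cochran's Q;
#' if its p-value falls below `het_alpha` a multiplicative random-effects
#' model is used, inflating the standard error by
#' `sqrt(max(1, Q / (n - 1)))`, otherwise the fixed-effects SE
#' `sqrt(1 / sum(w_j))` is reported unchanged.
#'
#' @param pairs Harmonised pairs with at least 2 usable instruments.
#' @param het_alpha Q-test significance level that switches to the
#'   random-effects model (default 0.05).
#' @return List with `estimate` (one-row tibble, `method = "ivw"`) and
#'   `heterogeneity` (as from [cochran_q()]).
#' @export
ivw <- function(pairs, het_alpha = 0.05) {
  r <- per_snp_ratios(pairs)
  if (nrow(r) < 2) {
    stop("IVW needs at least 2 instruments; use wald_ratio for one",
         call. = FALSE)
  }
  w <- 1 / r$se_ratio^2
  beta <- sum(w * r$ratio) / sum(w)
  se_fixed <- sqrt(1 / sum(w))
  het <- cochran_q(pairs)
  if (het$pval < het_alpha) {
    se <- se_fixed * sqrt(max(1, het$q_stat / het$df))
    model <- "random"
  } else {
    se <- se_fixed
    model <- "fixed"
  }
  est <- mr_estimate_row("ivw", beta, se, two_sided_p(beta / se),
                         nrow(r), model)
  list(estimate = est, heterogeneity = het)
}

#' MR-Egger regression
#'
#' Weighted least squares of the outcome effects on the exposure effects
#' with a free intercept, weights `1 / se_outcome^2`, after orienting every
#' pair so the exposure effect is non-negative. The slope estimates the
#' causal effect; the intercept estimates the average directional
#' pleiotropy, and its test is the pleiotropy diagnostic. Standard errors
#' follow the multiplicative error model (weighted-regression SEs scaled by
#' the residual standard deviation), and p-values come from a t
#' distribution with `n - 2` degrees of freedom, so the intercept test is
#' exactly calibrated when instruments are valid.
#'
#' @param pairs Harmonised pairs with at least 3 usable instruments and
#'   non-constant exposure effects.
#' @return List with `estimate` (slope as a one-row tibble,
#'   `method = "mr_egger"`), `intercept`, `intercept_se`,
#'   `intercept_pval`.
#' @export
mr_egger <- function(pairs) {
  r <- per_snp_ratios(pairs)
  n <- nrow(r)
  if (n < 3) stop("MR-Egger needs at least 3 instruments", call. = FALSE)
  flip <- sign(r$beta_exposure)
  bx <- r$beta_exposure * flip
  by <- r$beta_outcome * flip
  if (stats::sd(bx) == 0) {
    stop("exposure effects are constant; Egger regression is rank-deficient",
         call. = FALSE)
  }
  w <- 1 / r$se_outcome^2
  fit <- stats::lm(by ~ bx, weights = w)
  sm <- summary(fit)
  coefs <- sm$coefficients
  slope <- coefs["bx", "Estimate"]
  slope_se <- coefs["bx", "Std. Error"]
  intercept <- coefs["(Intercept)", "Estimate"]
  intercept_se <- coefs["(Intercept)", "Std. Error"]
  pt2 <- function(est, se) {
    2 * stats::pt(abs(est / se), df = n - 2, lower.tail = FALSE)
  }
  est <- mr_estimate_row("mr_egger", slope, slope_se,
                         pt2(slope, slope_se), n, "random")
  list(estimate = est, intercept = intercept, intercept_se = intercept_se,
       intercept_pval = pt2(intercept, intercept_se))
}

weighted_median_point <- function(ratio, w) {
  ord <- order(ratio)
  ratio <- ratio[ord]
  w <- w[ord] / sum(w)
  # cumulative weight at each order statistic, centred on its mass
  cw <- cumsum(w) - w / 2
  if (cw[1] >= 0.5) return(ratio[1])
  if (cw[length(cw)] <= 0.5) return(ratio[length(ratio)])
  stats::approx(cw, ratio, xout = 0.5, ties = "ordered")$y
}

#' Weighted-median estimate
#'
#' Orders the per-instrument ratios and takes the value at cumulative
#' normalized inverse-variance weight 0.5, interpolating linearly between
#' adjacent order statistics. Consistent when instruments carrying at
#' least half the weight are valid. The standard error comes from a seeded
#' parametric bootstrap: each ratio is resampled from
#' `Normal(ratio_j, se_ratio_j^2)` and the weighted median recomputed.
#'
#' @param pairs Harmonised pairs with at least 3 usable instruments.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Integer seed for the bootstrap.
#' @return One-row estimate tibble (`method = "weighted_median"`).
#' @export
weighted_median <- function(pairs, n_boot = 1000, seed = 1L) {
  r <- per_snp_ratios(pairs)
  n <- nrow(r)
  if (n < 3) {
    stop("weighted median needs at least 3 instruments", call. = FALSE)
  }
  w <- 1 / r$se_ratio^2
  beta <- weighted_median_point(r$ratio, w)
  rng <- local_rng(seed)
  boots <- vapply(seq_len(n_boot), function(b) {
    weighted_median_point(stats::rnorm(n, r$ratio, r$se_ratio), w)
  }, numeric(1))
  se <- stats::sd(boots)
  mr_estimate_row("weighted_median", beta, se, two_sided_p(beta / se), n)
}

#' Run every applicable MR estimator on one exposure-outcome pair
#'
#' Dispatch follows the number of usable instruments: one instrument gives
#' the Wald ratio only; two give IVW with Cochran's Q; three or more give
#' IVW (the primary estimate), MR-Egger and the weighted median. Returns a
#' fitted object with [tidy()], [glance()] and [ggplot2::autoplot()]
#' methods.
#'
#' @param pairs Harmonised pairs.
#' @param seed Seed for the weighted-median bootstrap.
#' @param n_boot Bootstrap replicates for the weighted-median SE.
#' @param het_alpha Significance level of the Q test used for the IVW
#'   fixed/random switch.
#' @return An object of class `mr_fit`: a list with `estimates` (tibble,
#'   one row per method, primary first), `primary` (the primary method
#'   name), `heterogeneity`, `egger` (intercept diagnostics or `NULL`) and
#'   `pairs` (the usable pairs analysed).
#' @export
estimate_all <- function(pairs, seed = 1L, n_boot = 1000,
                         het_alpha = 0.05) {
  p <- usable_pairs(pairs)
  n <- nrow(p)
  if (n == 0) stop("no usable harmonised pairs", call. = FALSE)
  het <- NULL
  egger <- NULL
  if (n == 1) {
    est <- wald_ratio(p)
    primary <- "wald_ratio"
  } else {
    fit <- ivw(p, het_alpha = het_alpha)
    est <- fit$estimate
    het <- fit$heterogeneity
    primary <- "ivw"
    if (n >= 3) {
      eg <- mr_egger(p)
      wm <- weighted_median(p, n_boot = n_boot, seed = seed)
      est <- dplyr::bind_rows(est, eg$estimate, wm)
      egger <- eg[c("intercept", "intercept_se", "intercept_pval")]
    }
  }
  structure(
    list(estimates = est, primary = primary, heterogeneity = het,
         egger = egger, pairs = p),
    class = "mr_fit"
  )
}

#' @export
print.mr_fit <- function(x, ...) {
  cat("Two-sample MR fit (", nrow(x$pairs), " instruments, primary: ",
      x$primary, ")\n", sep = "")
  print(x$estimates)
  if (!is.null(x$heterogeneity)) {
    cat(sprintf("Cochran's Q = %.3f (df = %d), p = %.3g\n",
                x$heterogeneity$q_stat, x$heterogeneity$df,
                x$heterogeneity$pval))
  }
  if (!is.null(x$egger)) {
    cat(sprintf("Egger intercept = %.4f (se %.4f), p = %.3g\n",
                x$egger$intercept, x$egger$intercept_se,
                x$egger$intercept_pval))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an MR fit into one row per estimator
#'
#' @param x An `mr_fit` object.
#' @param ... Unused.
#' @return The estimates tibble (method, beta, se, pval, OR and CI,
#'   n_snps, effects model).
#' @method tidy mr_fit
#' @export
tidy.mr_fit <- function(x, ...) x$estimates

#' One-row summary of an MR fit
#'
#' @param x An `mr_fit` object.
#' @param ... Unused.
#' @return A tibble with the primary estimate, heterogeneity and
#'   pleiotropy diagnostics.
#' @method glance mr_fit
#' @export
glance.mr_fit <- function(x, ...) {
  prim <- x$estimates[x$estimates$method == x$primary, ]
  tibble(
    method = x$primary,
    beta = prim$beta, se = prim$se, pval = prim$pval,
    or_ = prim$or_, ci_low = prim$ci_low, ci_high = prim$ci_high,
    n_snps = prim$n_snps, effects_model = prim$effects_model,
    q_stat = if (is.null(x$heterogeneity)) NA_real_ else
      x$heterogeneity$q_stat,
    q_pval = if (is.null(x$heterogeneity)) NA_real_ else
      x$heterogeneity$pval,
    egger_intercept = if (is.null(x$egger)) NA_real_ else
      x$egger$intercept,
    egger_intercept_pval = if (is.null(x$egger)) NA_real_ else
      x$egger$intercept_pval
  )
}

#' Scatter plot of an MR fit
#'
#' Instrument exposure effects against outcome effects with one fitted
#' line per estimator (through the origin except MR-Egger).
#'
#' @param object An `mr_fit` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mr_fit
#' @export
autoplot.mr_fit <- function(object, ...) {
  p <- object$pairs
  flip <- sign(p$beta_exposure)
  df <- tibble(bx = p$beta_exposure * flip, by = p$beta_outcome * flip,
               se_x = p$se_exposure, se_y = p$se_outcome)
  est <- object$estimates
  lines <- tibble(
    method = est$method,
    slope = est$beta,
    intercept = ifelse(est$method == "mr_egger" & !is.null(object$egger),
                       object$egger$intercept, 0)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bx, y = .data$by)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$by - .data$se_y,
                                        ymax = .data$by + .data$se_y),
                           colour = "grey70", width = 0) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$bx - .data$se_x,
                                         xmax = .data$bx + .data$se_x),
                            colour = "grey70", height = 0) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(
      data = lines,
      ggplot2::aes(slope = .data$slope, intercept = .data$intercept,
                   colour = .data$method)
    ) +
    ggplot2::labs(x = "SNP effect on exposure",
                  y = "SNP effect on outcome", colour = "method") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
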