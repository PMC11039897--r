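#' Per-variant log approximate Bayes factor
#'
#' Wakefield's approximation to the Bayes factor for an association, on the
#' log scale: with sampling variance `V = se^2`, prior effect variance
#' `W = prior_sd^2` and `z = beta / se`,
#' `log ABF = 0.5 * (log(V / (V + W)) + z^2 * W / (V + W))`.
#' Positive values favour association, `beta = 0` always gives a negative
#' value, and the ABF tends to 1 as the prior variance shrinks to zero.
#'
#' @param beta Effect estimate(s).
#' @param se Standard error(s), > 0.
#' @param prior_sd Prior SD of the true effect (0.15 is conventional for
#'   quantitative traits, 0.2 for log odds ratios of binary traits).
#' @return Numeric vector of log Bayes factors.
#' @export
log_abf <- function(beta, se, prior_sd) {
  if (any(!is.finite(se) | se <= 0)) {
    stop("se must be positive and finite", call. = FALSE)
  }
  v <- se^2
  w <- prior_sd^2
  z2 <- (beta / se)^2
  0.5 * (log(v / (v + w)) + z2 * w / (v + w))
}

logsumexp <- function(x) {
  if (length(x) == 0) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Default colocalization priors
#'
#' @param p1,p2 Prior probability that a given variant is causal for
#'   trait 1 only / trait 2 only (default 1e-4 each).
#' @param p12 Prior probability that a given variant is causal for both
#'   traits (default 1e-5); must not exceed `min(p1, p2)`.
#' @param sd_quant Prior effect SD for quantitative traits (default 0.15).
#' @param sd_cc Prior log-odds SD for binary traits (default 0.2).
#' @return Named list of priors.
#' @export
coloc_priors <- function(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                         sd_quant = 0.15, sd_cc = 0.2) {
  stopifnot(p12 > 0, p12 <= min(p1, p2), max(p1, p2) < 1)
  list(p1 = p1, p2 = p2, p12 = p12, sd_quant = sd_quant, sd_cc = sd_cc)
}

#' Bayesian colocalization of two traits over a region
#'
#' Enumerates the five single-causal-variant hypotheses for a region —
#' H0: no association with either trait; H1/H2: association with one
#' trait only; H3: both traits associated through distinct causal
#' variants; H4: both traits share one causal variant — and returns their
#' posterior probabilities from per-variant approximate Bayes factors
#' ([log_abf()]). With per-variant log ABFs `l1_j`, `l2_j`, the
#' unnormalized hypothesis weights are `1`, `p1 S1`, `p2 S2`,
#' `p1 p2 (S1 S2 - S12)` and `p12 S12`, where `S1 = sum exp(l1_j)`,
#' `S2 = sum exp(l2_j)`, `S12 = sum exp(l1_j + l2_j)`. All sums are
#' accumulated in log space.
#'
#' The analysis is restricted to the variants shared by both traits;
#' mismatched variants are counted in the `"dropped"` attribute.
#'
#' @param trait1,trait2 Summary-statistic tibbles for the two traits over
#'   the same region (only `snp_id`, `beta`, `se` are used).
#' @param priors Priors from [coloc_priors()].
#' @param trait1_type,trait2_type `"quant"` or `"cc"`; selects the prior
#'   effect SD per trait.
#' @param pp4_threshold Posterior probability of H4 above which the
#'   verdict is `"strong_colocalization"` (default 0.75).
#' @return An object of class `coloc_fit`: list with `pp` (named numeric,
#'   pp0..pp4, summing to 1), `n_variants`, `verdict`, `priors`.
#' @export
colocalise <- function(trait1, trait2, priors = coloc_priors(),
                       trait1_type = c("quant", "cc"),
                       trait2_type = c("cc", "quant"),
                       pp4_threshold = 0.75) {
  trait1_type <- match.arg(trait1_type)
  trait2_type <- match.arg(trait2_type)
  shared <- intersect(trait1$snp_id, trait2$snp_id)
  if (length(shared) < 1) {
    stop("colocalization needs at least 1 shared variant", call. = FALSE)
  }
  # a single-variant region is legal: H3 (distinct causal variants) is
  # then an empty enumeration and its posterior is exactly zero
  n_dropped <- (nrow(trait1) - length(shared)) +
    (nrow(trait2) - length(shared))
  i1 <- match(shared, trait1$snp_id)
  i2 <- match(shared, trait2$snp_id)
  sd1 <- if (trait1_type == "quant") priors$sd_quant else priors$sd_cc
  sd2 <- if (trait2_type == "quant") priors$sd_quant else priors$sd_cc
  l1 <- log_abf(trait1$beta[i1], trait1$se[i1], sd1)
  l2 <- log_abf(trait2$beta[i2], trait2$se[i2], sd2)

  ls1 <- logsumexp(l1)
  ls2 <- logsumexp(l2)
  ls12 <- logsumexp(l1 + l2)
  # cross term S1*S2 - S12 (pairs with distinct causal variants), kept in
  # log space; exactly zero when only one variant is shared
  diff <- ls12 - (ls1 + ls2)
  lcross <- if (diff >= 0) -Inf else ls1 + ls2 + log1p(-exp(diff))

  lh <- c(
    h0 = 0,
    h1 = log(priors$p1) + ls1,
    h2 = log(priors$p2) + ls2,
    h3 = log(priors$p1) + log(priors$p2) + lcross,
    h4 = log(priors$p12) + ls12
  )
  denom <- logsumexp(lh)
  pp <- exp(lh - denom)
  names(pp) <- c("pp0", "pp1", "pp2", "pp3", "pp4")
  res <- structure(
    list(pp = pp, n_variants = length(shared),
         verdict = if (pp[["pp4"]] > pp4_threshold)
           "strong_colocalization" else "not_colocalized",
         priors = priors),
    class = "coloc_fit"
  )
  attr(res, "dropped") <- c(unshared_variants = n_dropped)
  res
}

#' @export
print.coloc_fit <- function(x, ...) {
  cat("Colocalization over", x$n_variants, "variants\n")
  print(round(x$pp, 4))
  cat("verdict:", x$verdict, "\n")
  invisible(x)
}

#' Tidy colocalization posteriors
#'
#' @param x A `coloc_fit` object.
#' @param ... Unused.
#' @return Tibble with one row per hypothesis.
#' @method tidy coloc_fit
#' @export
tidy.coloc_fit <- function(x, ...) {
  tibble(
    hypothesis = c("H0", "H1", "H2", "H3", "H4"),
    description = c("no association",
                    "trait 1 only", "trait 2 only",
                    "both traits, distinct variants",
                    "both traits, shared variant"),
    posterior = unname(x$pp)
  )
}

#' One-row colocalization summary
#'
#' @param x A `coloc_fit` object.
#' @param ... Unused.
#' @return Tibble with pp0..pp4, `n_variants` and the verdict.
#' @method glance coloc_fit
#' @export
glance.coloc_fit <- function(x, ...) {
  out <- as_tibble(as.list(x$pp))
  out$n_variants <- x$n_variants
  out$verdict <- x$verdict
  out
}

#' Bar plot of colocalization posteriors
#'
#' @param object A `coloc_fit` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot coloc_fit
#' @export
autoplot.coloc_fit <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$hypothesis,
                                   y = .data$posterior)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0.75, linetype = "dashed") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(y = "posterior probability", x = NULL) +
    ggplot2::theme_minimal()
}
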