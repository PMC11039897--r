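#' Simulate a two-sample MR exposure/outcome pair with known truth
#'
#' Generates summary statistics for an exposure and an outcome measured in
#' two non-overlapping samples, under the standard two-sample MR generative
#' model. For each variant j a minor-allele frequency is drawn uniformly
#' from `maf_range`, the true per-allele exposure effect is
#' `gamma_j ~ N(0, gamma_sd^2)`, and the marginal outcome effect is
#' `theta * gamma_j + alpha_j`, where `alpha_j` is a direct (pleiotropic)
#' effect on the outcome. Observed betas are the true effects plus sampling
#' noise with the analytic standard error `1 / sqrt(2 N p (1 - p))` for a
#' unit-variance trait; for a binary outcome the same form is scaled by
#' `1 / sqrt(cf (1 - cf))` with `cf` the case fraction, and betas are read
#' as log odds ratios. Two-sided normal p-values accompany every beta.
#'
#' Pleiotropy modes: `"none"` sets every `alpha_j = 0`; `"balanced"` draws
#' `alpha_j ~ N(0, alpha_sd^2)` for a random `prop_invalid` subset;
#' `"directional"` draws `alpha_j ~ N(alpha_mean, alpha_sd^2)` for that
#' subset, so invalid instruments share a systematic direct effect. Direct
#' effects are defined per exposure-increasing allele (they enter the
#' outcome mean as `sign(gamma_j) * alpha_j`), which makes the notion of a
#' shared direction invariant to the arbitrary sign of the allele coding.
#'
#' A `palindrome_prob` fraction of variants receive strand-ambiguous A/T or
#' C/G allele pairs; their frequencies are drawn away from 0.5 with
#' probability `1 - ambiguous_prob` so both harmonisation branches (rescue
#' by frequency, removal inside the ambiguity band) occur.
#'
#' @param n_snps Number of variants to simulate.
#' @param theta True causal effect of the exposure on the outcome.
#' @param n_exposure,n_outcome GWAS sample sizes for the two traits.
#' @param maf_range Length-2 interval within (0, 0.5] for allele frequencies.
#' @param gamma_sd SD of true per-variant exposure effects.
#' @param pleiotropy_mode One of `"none"`, `"balanced"`, `"directional"`.
#' @param alpha_mean,alpha_sd Mean and SD of direct effects for invalid
#'   instruments (the mean is only used in directional mode).
#' @param prop_invalid Fraction of variants given a direct effect; must be 0
#'   when `pleiotropy_mode = "none"`.
#' @param palindrome_prob Fraction of variants with palindromic alleles.
#' @param ambiguous_prob Probability that a palindromic variant's frequency
#'   falls inside the (0.42, 0.58) ambiguity band.
#' @param outcome_type `"binary"` (log-odds effects, default) or
#'   `"quantitative"`.
#' @param case_fraction Case fraction for a binary outcome.
#' @param seed Integer seed; identical inputs give bit-identical outputs.
#' @param id_prefix Prefix for generated variant identifiers (default
#'   `"rs"`); use distinct prefixes to combine several simulated traits
#'   without identifier collisions.
#' @return A list with `exposure` and `outcome` summary-statistic tibbles
#'   (canonical schema) and `truth`, a tibble with `snp_id`, `maf`,
#'   `gamma`, `alpha`, `invalid` plus the scalar `theta` as an attribute.
#' @export
simulate_mr_pair <- function(n_snps,
                             theta = 0,
                             n_exposure = 1e5,
                             n_outcome = 1e5,
                             maf_range = c(0.05, 0.5),
                             gamma_sd = 0.1,
                             pleiotropy_mode = c("none", "balanced",
                                                 "directional"),
                             alpha_mean = 0,
                             alpha_sd = 0,
                             prop_invalid = 0,
                             palindrome_prob = 0.1,
                             ambiguous_prob = 0.3,
                             outcome_type = c("binary", "quantitative"),
                             case_fraction = 0.2,
                             seed = 1L,
                             id_prefix = "rs") {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  outcome_type <- match.arg(outcome_type)
  stopifnot(n_snps >= 1, gamma_sd >= 0, alpha_sd >= 0,
            prop_invalid >= 0, prop_invalid <= 1,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            palindrome_prob >= 0, palindrome_prob <= 1)
  if (pleiotropy_mode == "none" && prop_invalid != 0) {
    stop("prop_invalid must be 0 when pleiotropy_mode = 'none'",
         call. = FALSE)
  }
  rng <- local_rng(seed)

  maf <- stats::runif(n_snps, maf_range[1], maf_range[2])
  gamma <- stats::rnorm(n_snps, 0, gamma_sd)

  invalid <- rep(FALSE, n_snps)
  alpha <- rep(0, n_snps)
  if (pleiotropy_mode != "none" && prop_invalid > 0) {
    n_invalid <- round(prop_invalid * n_snps)
    invalid[sample.int(n_snps, n_invalid)] <- TRUE
    mu <- if (pleiotropy_mode == "directional") alpha_mean else 0
    alpha[invalid] <- stats::rnorm(sum(invalid), mu, alpha_sd)
  }

  se_x <- 1 / sqrt(2 * n_exposure * maf * (1 - maf))
  se_y <- 1 / sqrt(2 * n_outcome * maf * (1 - maf))
  if (outcome_type == "binary") {
    se_y <- se_y / sqrt(case_fraction * (1 - case_fraction))
  }
  beta_x <- stats::rnorm(n_snps, gamma, se_x)
  # direct effects act on the exposure-increasing allele, so directional
  # pleiotropy survives any re-orientation of the (arbitrary) allele coding
  beta_y <- stats::rnorm(n_snps, theta * gamma + sign(gamma) * alpha, se_y)

  alleles <- draw_allele_pairs(n_snps, palindrome_prob)
  is_pal <- alleles$palindromic
  eaf <- maf
  # palindromic variants: keep the frequency out of the ambiguity band
  # unless this draw is meant to exercise the removal branch
  if (any(is_pal)) {
    amb <- is_pal & (stats::runif(n_snps) < ambiguous_prob)
    clear <- is_pal & !amb
    eaf[amb] <- stats::runif(sum(amb), 0.42, 0.58)
    eaf[clear] <- stats::runif(sum(clear), maf_range[1], 0.40)
  }

  snp_id <- sprintf("%s%06d", id_prefix, seq_len(n_snps))
  exposure <- tibble(
    snp_id = snp_id,
    chrom = as.character(1 + (seq_len(n_snps) - 1) %% 22),
    # 250-kb spacing per chromosome, wrapped to stay within integer range
    pos = as.integer(1e6 +
                       (((seq_len(n_snps) - 1) %/% 22) %% 8000) * 250000),
    effect_allele = alleles$effect, other_allele = alleles$other,
    eaf = eaf, beta = beta_x, se = se_x,
    pval = two_sided_p(beta_x / se_x), n = n_exposure
  )
  outcome <- exposure
  outcome$beta <- beta_y
  outcome$se <- se_y
  outcome$pval <- two_sided_p(beta_y / se_y)
  outcome$n <- n_outcome

  truth <- tibble(snp_id = snp_id, maf = maf, gamma = gamma, alpha = alpha,
                  invalid = invalid)
  attr(truth, "theta") <- theta
  list(exposure = as_gwas_tbl(exposure, quiet = TRUE),
       outcome = as_gwas_tbl(outcome, quiet = TRUE),
       truth = truth)
}

# Seed the RNG for the calling function and restore the caller's RNG
# state when that function exits; all draws flow from `seed`.
local_rng <- function(seed, envir = parent.frame()) {
  withr::local_seed(as.integer(seed), .local_envir = envir)
  invisible(seed)
}

two_sided_p <- function(z) {
  p <- 2 * stats::pnorm(-abs(z))
  pmax(p, .Machine$double.xmin)  # keep p in (0, 1]
}

non_palindromic_pairs <- rbind(
  c("A", "C"), c("A", "G"), c("C", "A"), c("C", "T"),
  c("G", "A"), c("G", "T"), c("T", "C"), c("T", "G")
)
palindromic_pairs <- rbind(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))

draw_allele_pairs <- function(n, palindrome_prob) {
  pal <- stats::runif(n) < palindrome_prob
  effect <- other <- character(n)
  if (any(pal)) {
    idx <- sample.int(nrow(palindromic_pairs), sum(pal), replace = TRUE)
    effect[pal] <- palindromic_pairs[idx, 1]
    other[pal] <- palindromic_pairs[idx, 2]
  }
  if (any(!pal)) {
    idx <- sample.int(nrow(non_palindromic_pairs), sum(!pal), replace = TRUE)
    effect[!pal] <- non_palindromic_pairs[idx, 1]
    other[!pal] <- non_palindromic_pairs[idx, 2]
  }
  list(effect = effect, other = other, palindromic = pal)
}

# Deterministic 31-bit child seed from a master seed and a string key, so
# per-exposure randomness is reproducible and independent of panel order.
derive_seed <- function(master_seed, key) {
  h <- as.double(master_seed %% 2147483647)
  for (code in utf8ToInt(key)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

#' Simulate a screening panel of exposures against one outcome
#'
#' Builds `n_exposures` independent exposure GWAS tables, each with its own
#' variants, and a single outcome table covering all of them, with the
#' first `n_causal` exposures truly causal (effect `theta`) and the rest
#' null. Each exposure is generated by [simulate_mr_pair()] under a child
#' seed derived from `seed` and the exposure id.
#'
#' @param n_exposures Number of exposures in the panel.
#' @param n_causal Number of truly causal exposures (the first ones).
#' @param theta Causal effect of each causal exposure.
#' @param n_snps Variants simulated per exposure.
#' @param seed Master seed.
#' @param ... Further arguments passed to [simulate_mr_pair()].
#' @return List with `exposures` (named list of summary-statistic
#'   tibbles), `outcome` (combined tibble), and `truth` (tibble with
#'   `exposure_id`, `theta`, `causal`).
#' @export
simulate_mr_panel <- function(n_exposures = 20, n_causal = 3, theta = 0.3,
                              n_snps = 30, seed = 1L, ...) {
  stopifnot(n_causal <= n_exposures)
  ids <- sprintf("exposure_%02d", seq_len(n_exposures))
  causal <- seq_len(n_exposures) <= n_causal
  pairs <- purrr::map2(ids, causal, function(id, is_causal) {
    simulate_mr_pair(
      n_snps = n_snps,
      theta = if (is_causal) theta else 0,
      seed = derive_seed(seed, id),
      id_prefix = paste0(sub("exposure_", "e", id), "v"),
      ...
    )
  })
  names(pairs) <- ids
  outcome <- dplyr::bind_rows(purrr::map(pairs, "outcome"))
  list(
    exposures = purrr::map(pairs, "exposure"),
    outcome = as_gwas_tbl(outcome, quiet = TRUE),
    truth = tibble(exposure_id = ids,
                   theta = ifelse(causal, theta, 0),
                   causal = causal)
  )
}

#' Simulate a colocalization region for two traits
#'
#' Builds a region of `n_variants` variants whose genotypes follow an AR(1)
#' correlation structure (`r[i, j] = ld_decay^|i - j|`) and draws marginal
#' summary statistics for two traits under one of four scenarios:
#' `"shared"` (one causal variant affecting both traits), `"distinct"`
#' (different causal variants for each trait), `"trait1_only"`, and
#' `"null"` (no causal variant). Marginal true effects are the causal
#' effect propagated through LD; observed effects add sampling noise with
#' the analytic SE used by [simulate_mr_pair()] and the same AR(1)
#' correlation across variants, as marginal GWAS estimates from one cohort
#' have noise correlated like the genotypes themselves.
#'
#' @param scenario Causal configuration, see Description.
#' @param n_variants Number of variants in the region (at least 2).
#' @param ld_decay AR(1) autocorrelation in \[0, 1).
#' @param effect_size Per-allele effect at the causal variant(s).
#' @param n1,n2 Sample sizes for trait 1 and trait 2.
#' @param maf Allele frequency used for every variant's SE.
#' @param seed Integer seed.
#' @return A list with `trait1`, `trait2` (summary-statistic tibbles),
#'   `causal` (named integer vector of causal indices per trait, `NA` when
#'   absent) and `scenario`.
#' @export
simulate_coloc_region <- function(scenario = c("shared", "distinct",
                                               "trait1_only", "null"),
                                  n_variants = 200,
                                  ld_decay = 0.9,
                                  effect_size = 0.15,
                                  n1 = 50000, n2 = 50000,
                                  maf = 0.3,
                                  seed = 1L) {
  scenario <- match.arg(scenario)
  stopifnot(n_variants >= 2, ld_decay >= 0, ld_decay < 1)
  rng <- local_rng(seed)

  idx1 <- idx2 <- NA_integer_
  if (scenario == "shared") {
    idx1 <- idx2 <- sample.int(n_variants, 1)
  } else if (scenario == "distinct") {
    pick <- sample.int(n_variants, 2)
    idx1 <- pick[1]; idx2 <- pick[2]
  } else if (scenario == "trait1_only") {
    idx1 <- sample.int(n_variants, 1)
  }

  pos_seq <- seq_len(n_variants)
  r_to <- function(idx) {
    if (is.na(idx)) rep(0, n_variants) else ld_decay^abs(pos_seq - idx)
  }
  mu1 <- effect_size * r_to(idx1)
  mu2 <- effect_size * r_to(idx2)
  se1 <- rep(1 / sqrt(2 * n1 * maf * (1 - maf)), n_variants)
  se2 <- rep(1 / sqrt(2 * n2 * maf * (1 - maf)), n_variants)
  # AR(1)-correlated sampling noise: eps_j = rho * eps_{j-1} + innovation
  ar1_noise <- function(n, rho) {
    e <- numeric(n)
    e[1] <- stats::rnorm(1)
    if (n > 1) {
      innov <- stats::rnorm(n - 1, 0, sqrt(1 - rho^2))
      for (j in 2:n) e[j] <- rho * e[j - 1] + innov[j - 1]
    }
    e
  }
  beta1 <- mu1 + se1 * ar1_noise(n_variants, ld_decay)
  beta2 <- mu2 + se2 * ar1_noise(n_variants, ld_decay)

  alleles <- draw_allele_pairs(n_variants, 0)
  base <- tibble(
    snp_id = sprintf("rv%05d", pos_seq),
    chrom = "1",
    pos = as.integer(1e6 + (pos_seq - 1) * 1000),
    effect_allele = alleles$effect, other_allele = alleles$other,
    eaf = maf
  )
  trait1 <- base
  trait1$beta <- beta1; trait1$se <- se1
  trait1$pval <- two_sided_p(beta1 / se1); trait1$n <- n1
  trait2 <- base
  trait2$beta <- beta2; trait2$se <- se2
  trait2$pval <- two_sided_p(beta2 / se2); trait2$n <- n2

  list(trait1 = as_gwas_tbl(trait1, quiet = TRUE),
       trait2 = as_gwas_tbl(trait2, quiet = TRUE),
       causal = c(trait1 = idx1, trait2 = idx2),
       scenario = scenario)
}

#' Simulate a block-diagonal LD matrix
#'
#' Variants within a block share pairwise correlation `within_r`; variants
#' in different blocks are uncorrelated.
#'
#' @param block_sizes Integer vector of block sizes.
#' @param within_r Pairwise correlation inside a block, |r| < 1.
#' @param snp_ids Optional variant labels (defaults to `ld00001`, ...).
#' @return A labelled correlation matrix.
#' @export
simulate_ld_blocks <- function(block_sizes, within_r = 0.9, snp_ids = NULL) {
  stopifnot(abs(within_r) < 1, all(block_sizes >= 1))
  n <- sum(block_sizes)
  if (is.null(snp_ids)) snp_ids <- sprintf("ld%05d", seq_len(n))
  stopifnot(length(snp_ids) == n)
  m <- matrix(0, n, n, dimnames = list(snp_ids, snp_ids))
  offset <- 0L
  for (b in block_sizes) {
    idx <- offset + seq_len(b)
    m[idx, idx] <- within_r
    offset <- offset + b
  }
  diag(m) <- 1
  validate_ld_matrix(m)
}

#' Simulate a protein-interaction graph with planted complexes
#'
#' Each planted complex is a clique; pairs of nodes in different complexes
#' are connected independently with probability `inter_edge_prob`.
#'
#' @param complex_sizes Integer vector, each at least 3.
#' @param inter_edge_prob Probability of a bridge edge between complexes.
#' @param seed Integer seed.
#' @return A list with `graph` (an [igraph::igraph]) and `complexes`, a
#'   list of character vectors giving the planted memberships.
#' @export
simulate_ppi_graph <- function(complex_sizes, inter_edge_prob = 0,
                               seed = 1L) {
  stopifnot(all(complex_sizes >= 3), inter_edge_prob >= 0,
            inter_edge_prob <= 1)
  rng <- local_rng(seed)
  n <- sum(complex_sizes)
  labels <- sprintf("P%03d", seq_len(n))
  member <- rep(seq_along(complex_sizes), complex_sizes)
  edges <- character(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      connect <- if (member[i] == member[j]) TRUE
      else stats::runif(1) < inter_edge_prob
      if (connect) edges <- c(edges, labels[i], labels[j])
    }
  }
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, n, name = labels)
  if (length(edges) > 0) g <- igraph::add_edges(g, edges)
  list(graph = g,
       complexes = split(labels, member))
}
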