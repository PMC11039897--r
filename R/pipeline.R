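#' Screen one exposure against one outcome
#'
#' Runs the full per-exposure chain: p-value preselection, LD clumping,
#' instrument-strength filtering, harmonisation, estimation
#' ([estimate_all()]) and, when enough instruments remain, the MR-Egger
#' intercept and MR-PRESSO pleiotropy diagnostics. Returns one tidy row;
#' exposures that end with zero usable instruments are reported with
#' `status = "not_analyzable"` rather than dropped.
#'
#' @param exposure Exposure summary-statistics tibble.
#' @param outcome Outcome summary-statistics tibble.
#' @param exposure_id Label for the exposure.
#' @param ld Optional LD matrix for clumping.
#' @param p_threshold,r2_threshold,window_kb,f_threshold Instrument
#'   selection thresholds (defaults 5e-6, 0.001, 10000 kb, 10).
#' @param eaf_ambiguity_band Palindrome ambiguity band for [harmonise()].
#' @param presso_n_sim MR-PRESSO simulation count (default 1000).
#' @param n_boot Weighted-median bootstrap replicates.
#' @param seed Seed for the stochastic diagnostics.
#' @return One-row tibble with the primary estimate, diagnostics and
#'   per-stage instrument counts.
#' @export
screen_exposure <- function(exposure, outcome, exposure_id = "exposure",
                            ld = NULL,
                            p_threshold = 5e-6, r2_threshold = 0.001,
                            window_kb = 10000, f_threshold = 10,
                            eaf_ambiguity_band = c(0.42, 0.58),
                            presso_n_sim = 1000, n_boot = 1000,
                            seed = 1L) {
  base <- tibble(
    exposure_id = exposure_id, status = "ok",
    n_candidates = NA_integer_, n_instruments = NA_integer_,
    n_usable = NA_integer_, method = NA_character_,
    beta = NA_real_, se = NA_real_, pval_raw = NA_real_,
    or_ = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
    effects_model = NA_character_,
    q_stat = NA_real_, q_pval = NA_real_,
    egger_intercept = NA_real_, egger_intercept_pval = NA_real_,
    presso_global_pval = NA_real_, presso_n_outliers = NA_integer_,
    mean_f_stat = NA_real_
  )
  inst <- select_instruments(exposure, ld = ld, p_threshold = p_threshold,
                             r2_threshold = r2_threshold,
                             window_kb = window_kb,
                             f_threshold = f_threshold)
  counts <- attr(inst, "stage_counts")
  base$n_candidates <- as.integer(counts[["p_filtered"]])
  base$n_instruments <- nrow(inst)
  if (nrow(inst) == 0) {
    base$status <- "not_analyzable"
    return(base)
  }
  base$mean_f_stat <- mean(inst$f_stat)
  pairs <- harmonise(inst, outcome, eaf_ambiguity_band)
  usable <- usable_pairs(pairs)
  base$n_usable <- nrow(usable)
  if (nrow(usable) == 0) {
    base$status <- "not_analyzable"
    return(base)
  }
  fit <- estimate_all(usable, seed = seed, n_boot = n_boot)
  g <- glance(fit)
  base$method <- g$method
  base$beta <- g$beta
  base$se <- g$se
  base$pval_raw <- g$pval
  base$or_ <- g$or_
  base$ci_low <- g$ci_low
  base$ci_high <- g$ci_high
  base$effects_model <- g$effects_model
  base$q_stat <- g$q_stat
  base$q_pval <- g$q_pval
  base$egger_intercept <- g$egger_intercept
  base$egger_intercept_pval <- g$egger_intercept_pval
  if (nrow(usable) >= 4) {
    pr <- mr_presso(usable, n_sim = presso_n_sim, seed = seed)
    base$presso_global_pval <- pr$global_pval
    base$presso_n_outliers <- length(pr$outlier_ids)
  }
  base
}

#' Forward screen: many exposures against one outcome
#'
#' Applies [screen_exposure()] to every exposure, then the pleiotropy
#' exclusion gate and the two-tier FDR calling
#' ([pleiotropy_gate()], [tier_results()]). Per-exposure seeds are derived
#' deterministically from `master_seed` and the exposure id, so results do
#' not depend on panel order or composition.
#'
#' @param exposures Named list of exposure summary-statistic tibbles (or
#'   file paths readable by [read_gwas()]).
#' @param outcome Outcome summary-statistics tibble or path.
#' @param family Optional character vector (recycled) labelling each
#'   exposure's FDR family; correction is applied within family.
#' @param master_seed Integer master seed.
#' @param alpha Significance level for the gate and tiering.
#' @param ... Tuning arguments passed to [screen_exposure()].
#' @return Tibble with one row per exposure including `pval_fdr` and
#'   `tier`.
#' @export
run_forward_screen <- function(exposures, outcome, family = "all",
                               master_seed = 1L, alpha = 0.05, ...) {
  if (is.character(outcome)) outcome <- read_gwas(outcome, quiet = TRUE)
  if (is.null(names(exposures)) || any(names(exposures) == "")) {
    names(exposures) <- sprintf("exposure_%02d", seq_along(exposures))
  }
  fam <- rep_len(family, length(exposures))
  rows <- purrr::imap(exposures, function(exp_i, id) {
    if (is.character(exp_i)) exp_i <- read_gwas(exp_i, quiet = TRUE)
    screen_exposure(exp_i, outcome, exposure_id = id,
                    seed = derive_seed(master_seed, id), ...)
  })
  res <- dplyr::bind_rows(rows)
  res$family <- fam
  res <- pleiotropy_gate(res, alpha = alpha)
  tier_results(res, alpha = alpha)
}

#' Reverse screen: one trait as exposure against many outcomes
#'
#' The mirror of [run_forward_screen()]: the former outcome plays the
#' exposure role and each former exposure is screened as an outcome.
#' Instruments are selected from `exposure` once per outcome (the
#' harmonisable subset differs by outcome).
#'
#' @param exposure Summary statistics of the trait now used as exposure.
#' @param outcomes Named list of outcome summary-statistic tibbles or
#'   paths.
#' @param ... Passed to [run_forward_screen()] machinery
#'   (`family`, `master_seed`, `alpha`, and [screen_exposure()] tuning).
#' @return Tibble with one row per outcome; `exposure_id` carries the
#'   outcome trait's id.
#' @export
run_reverse_screen <- function(exposure, outcomes, ...) {
  if (is.character(exposure)) exposure <- read_gwas(exposure, quiet = TRUE)
  if (is.null(names(outcomes)) || any(names(outcomes) == "")) {
    names(outcomes) <- sprintf("outcome_%02d", seq_along(outcomes))
  }
  # run one screen per outcome, reusing the forward machinery pairwise
  res <- purrr::imap(outcomes, function(out_i, id) {
    run_forward_screen(stats::setNames(list(exposure), id), out_i, ...)
  })
  dplyr::bind_rows(res)
}

#' Flag traits with support in both causal directions
#'
#' @param forward,reverse Screen-result tibbles for the two directions,
#'   joined on `exposure_id`.
#' @param tiers Tiers that count as support (default `"significant"`).
#' @return The forward tibble with a logical `bidirectional` column.
#' @export
flag_bidirectional <- function(forward, reverse,
                               tiers = "significant") {
  hit_rev <- reverse$exposure_id[reverse$tier %in% tiers]
  forward$bidirectional <- forward$tier %in% tiers &
    forward$exposure_id %in% hit_rev
  forward
}

#' Write screen results as per-family TSV reports
#'
#' One tab-separated file per FDR family plus a `run_metadata.tsv` file
#' recording the package version, timestamp policy (none recorded — files
#' are reproducible), seed and tier counts.
#'
#' @param results Screen-result tibble from [run_forward_screen()].
#' @param dir Output directory (created if absent).
#' @param master_seed Seed echoed into the metadata file.
#' @return Character vector of paths written, invisibly.
#' @export
write_report <- function(results, dir, master_seed = NA) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!"tier" %in% names(results)) results$tier <- NA_character_
  fam <- if ("family" %in% names(results)) results$family else
    rep("all", nrow(results))
  paths <- character(0)
  families <- unique(fam)
  if (length(families) == 0) families <- "all"
  for (f in families) {
    sel <- results[fam == f, , drop = FALSE]
    path <- file.path(dir, paste0("screen_", f, ".tsv"))
    utils::write.table(sel, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, path)
  }
  tier_counts <- table(results$tier)
  tier_keys <- if (length(tier_counts) > 0) {
    paste0("tier_", names(tier_counts))
  } else {
    character(0)
  }
  meta <- data.frame(
    key = c("package", "version", "master_seed", "n_exposures", tier_keys),
    value = c("mrscreen",
              as.character(utils::packageVersion("mrscreen")),
              as.character(master_seed), as.character(nrow(results)),
              as.character(as.integer(tier_counts)))
  )
  meta_path <- file.path(dir, "run_metadata.tsv")
  utils::write.table(meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(paths, meta_path))
}

#' Volcano-style overview of a screen
#'
#' @param results Screen-result tibble.
#' @return A ggplot object: log odds ratio against -log10 raw p, coloured
#'   by tier.
#' @export
plot_screen <- function(results) {
  df <- results[!is.na(results$pval_raw), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$beta,
                                   y = -log10(.data$pval_raw),
                                   colour = .data$tier)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = -log10(0.05), linetype = "dashed") +
    ggplot2::labs(x = "log OR per unit exposure",
                  y = expression(-log[10](p)), colour = "tier") +
    ggplot2::theme_minimal()
}
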