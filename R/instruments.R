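#' Keep variants below a p-value threshold
#'
#' Genome-wide instrument preselection: retains exactly the records with
#' `pval < p_threshold`, in their original order.
#'
#' @param stats Summary-statistics tibble.
#' @param p_threshold Strict upper bound on the association p-value
#'   (default `5e-6`).
#' @return Filtered tibble.
#' @export
select_by_pvalue <- function(stats, p_threshold = 5e-6) {
  stats[stats$pval < p_threshold, , drop = FALSE]
}

#' Greedy LD clumping of candidate instruments
#'
#' Thins a p-filtered set of variants so that no two retained variants on
#' the same chromosome within `window_kb` kilobases are correlated at
#' `r^2 >= r2_threshold`. The algorithm is the standard greedy one: sort
#' candidates by ascending p-value (ties broken by variant id), repeatedly
#' take the best remaining variant as an index variant, and remove every
#' remaining variant on the same chromosome whose centre lies within
#' `window_kb` kb (closed interval) and whose squared correlation with the
#' index reaches the threshold. Variant pairs absent from `ld` are treated
#' as uncorrelated; the number of such lookups is returned in the
#' `"missing_ld_pairs"` attribute with a warning. Passing `ld = NULL`
#' declares every pair unlinked (no warning), so clumping reduces to the
#' p-value ordering.
#'
#' @param stats Summary-statistics tibble, already p-value filtered.
#' @param ld Labelled correlation matrix (may omit variants).
#' @param r2_threshold Squared-correlation threshold (default 0.001).
#' @param window_kb Clumping window in kilobases (default 10000).
#' @return Tibble of index variants (a subset of `stats`, original order).
#' @export
clump <- function(stats, ld = NULL, r2_threshold = 0.001,
                  window_kb = 10000) {
  if (nrow(stats) == 0) return(stats)
  no_ld_info <- is.null(ld)
  ord <- order(stats$pval, stats$snp_id)
  remaining <- ord
  keep <- character(0)
  missing_pairs <- 0L
  ld_ids <- if (is.null(ld)) character(0) else rownames(ld)

  while (length(remaining) > 0) {
    idx <- remaining[1]
    keep <- c(keep, stats$snp_id[idx])
    remaining <- remaining[-1]
    if (length(remaining) == 0) break
    same_chr <- stats$chrom[remaining] == stats$chrom[idx]
    in_window <- abs(stats$pos[remaining] - stats$pos[idx]) <=
      window_kb * 1000
    cand <- remaining[same_chr & in_window]
    if (length(cand) > 0 && !no_ld_info) {
      id_index <- stats$snp_id[idx]
      id_cand <- stats$snp_id[cand]
      r <- rep(0, length(cand))
      if (id_index %in% ld_ids) {
        present <- id_cand %in% ld_ids
        r[present] <- ld[id_index, id_cand[present]]
        missing_pairs <- missing_pairs + sum(!present)
      } else {
        missing_pairs <- missing_pairs + length(cand)
      }
      drop <- cand[r^2 >= r2_threshold]
      remaining <- setdiff(remaining, drop)
    }
  }
  out <- stats[stats$snp_id %in% keep, , drop = FALSE]
  if (missing_pairs > 0) {
    warning(missing_pairs,
            " LD pair(s) absent from the matrix; treated as r = 0",
            call. = FALSE)
  }
  attr(out, "missing_ld_pairs") <- missing_pairs
  out
}

#' Per-variant exposure variance explained and F statistic
#'
#' For each variant, the proportion of exposure variance explained is
#' \deqn{R^2 = \frac{2\beta^2 p(1-p)}{2\beta^2 p(1-p) + 2\,SE^2 N p(1-p)}}
#' with `p` the effect-allele frequency and `N` the sample size, and the
#' instrument strength is `F = R^2 (N - 2) / (1 - R^2)`. Since the
#' frequency factor cancels, R2 reduces to `beta^2 / (beta^2 + SE^2 N)`,
#' but a variant with missing EAF is still excluded (with a count in the
#' `"dropped"` attribute) because its eligibility cannot be established.
#'
#' @param stats Summary-statistics tibble (exposure side).
#' @return The input tibble with added `r2` and `f_stat` columns; rows with
#'   missing `eaf` are dropped and counted.
#' @export
compute_instrument_strength <- function(stats) {
  has_eaf <- !is.na(stats$eaf)
  out <- stats[has_eaf, , drop = FALSE]
  pq <- out$eaf * (1 - out$eaf)
  num <- 2 * out$beta^2 * pq
  den <- num + 2 * out$se^2 * out$n * pq
  out$r2 <- ifelse(den > 0, num / den, 0)
  out$f_stat <- out$r2 * (out$n - 2) / (1 - out$r2)
  attr(out, "dropped") <- c(missing_eaf = sum(!has_eaf))
  out
}

#' Exclude weak instruments
#'
#' Keeps variants whose F statistic strictly exceeds the threshold
#' (an instrument with F exactly at the threshold is removed).
#'
#' @param records Output of [compute_instrument_strength()].
#' @param f_threshold Minimum F (default 10).
#' @return Filtered tibble.
#' @export
filter_weak <- function(records, f_threshold = 10) {
  records[records$f_stat > f_threshold, , drop = FALSE]
}

#' Full instrument-selection stage
#'
#' Convenience chain: p-value preselection, LD clumping, strength
#' computation and weak-instrument exclusion, with per-stage counts.
#'
#' @inheritParams clump
#' @inheritParams select_by_pvalue
#' @inheritParams filter_weak
#' @return Tibble of instruments with `r2`/`f_stat`, carrying a
#'   `"stage_counts"` attribute (named integer vector of rows surviving
#'   each stage).
#' @export
select_instruments <- function(stats, ld = NULL, p_threshold = 5e-6,
                               r2_threshold = 0.001, window_kb = 10000,
                               f_threshold = 10) {
  hit <- select_by_pvalue(stats, p_threshold)
  clumped <- clump(hit, ld, r2_threshold, window_kb)
  strong <- filter_weak(compute_instrument_strength(clumped), f_threshold)
  attr(strong, "stage_counts") <- c(
    input = nrow(stats), p_filtered = nrow(hit), clumped = nrow(clumped),
    final = nrow(strong)
  )
  strong
}
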