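complement_base <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic <- function(effect, other) {
  unname(complement_base[effect] == other)
}

#' Align exposure and outcome effects to a shared effect allele
#'
#' Joins each exposure instrument to the outcome summary statistics by
#' variant id and reconciles the allele coding, assigning every variant a
#' disposition:
#'
#' * `kept` — outcome alleles already match the exposure coding (possibly
#'   after complementing both outcome alleles of a non-palindromic pair to
#'   bridge a strand difference).
#' * `flipped` — outcome alleles match with effect/other swapped; the
#'   outcome beta is negated and its frequency replaced by `1 - eaf`.
#' * `removed_palindrome` — a strand-ambiguous A/T or C/G pair whose
#'   orientation could not be established from allele frequencies: either
#'   frequency lies inside the ambiguity band, or is missing. Outside the
#'   band, palindromic variants are rescued by frequency: concordant
#'   frequencies (both minor or both major) mean the codings agree,
#'   discordant ones mean the outcome effect refers to the opposite allele
#'   and is flipped.
#' * `removed_mismatch` — allele sets irreconcilable under swap and strand
#'   complementation.
#' * `removed_missing_outcome` — instrument absent from the outcome table.
#'
#' @param exposure Instrument tibble (exposure summary statistics, possibly
#'   with `r2`/`f_stat` columns from [compute_instrument_strength()]).
#' @param outcome Outcome summary-statistics tibble.
#' @param eaf_ambiguity_band Frequency interval within which a palindromic
#'   variant's orientation is considered undecidable (default
#'   `c(0.42, 0.58)`).
#' @return A tibble with one row per instrument: `snp_id`,
#'   `effect_allele`, `other_allele`, `beta_exposure`, `se_exposure`,
#'   `eaf_exposure`, `beta_outcome`, `se_outcome`, `eaf_outcome`,
#'   `pval_exposure`, `pval_outcome` and `disposition`. Removed variants
#'   keep `NA` outcome effects. The per-reason removal tally is attached as
#'   the `"dropped"` attribute.
#' @export
harmonise <- function(exposure, outcome, eaf_ambiguity_band = c(0.42, 0.58)) {
  stopifnot(length(eaf_ambiguity_band) == 2,
            eaf_ambiguity_band[1] < eaf_ambiguity_band[2])
  lo <- eaf_ambiguity_band[1]
  hi <- eaf_ambiguity_band[2]

  out_idx <- match(exposure$snp_id, outcome$snp_id)
  n <- nrow(exposure)
  res <- tibble(
    snp_id = exposure$snp_id,
    effect_allele = exposure$effect_allele,
    other_allele = exposure$other_allele,
    beta_exposure = exposure$beta,
    se_exposure = exposure$se,
    eaf_exposure = exposure$eaf,
    pval_exposure = exposure$pval,
    beta_outcome = NA_real_,
    se_outcome = NA_real_,
    eaf_outcome = NA_real_,
    pval_outcome = NA_real_,
    disposition = NA_character_
  )

  for (i in seq_len(n)) {
    j <- out_idx[i]
    if (is.na(j)) {
      res$disposition[i] <- "removed_missing_outcome"
      next
    }
    ea_x <- exposure$effect_allele[i]
    oa_x <- exposure$other_allele[i]
    ea_y <- outcome$effect_allele[j]
    oa_y <- outcome$other_allele[j]
    b_y <- outcome$beta[j]
    se_y <- outcome$se[j]
    eaf_y <- outcome$eaf[j]
    p_y <- outcome$pval[j]
    pal <- is_palindromic(ea_x, oa_x)

    if (pal) {
      # Allele labels cannot resolve strand for A/T and C/G pairs; the
      # only usable signal is allele frequency on both sides.
      if (!setequal(c(ea_x, oa_x), c(ea_y, oa_y))) {
        res$disposition[i] <- "removed_mismatch"
        next
      }
      # express the outcome effect in terms of the exposure effect allele
      if (ea_y != ea_x) {
        b_y <- -b_y
        eaf_y <- if (is.na(eaf_y)) NA_real_ else 1 - eaf_y
      }
      eaf_x <- exposure$eaf[i]
      decidable <- !is.na(eaf_x) && !is.na(eaf_y) &&
        (eaf_x < lo || eaf_x > hi) && (eaf_y < lo || eaf_y > hi)
      if (!decidable) {
        res$disposition[i] <- "removed_palindrome"
        next
      }
      concordant <- (eaf_x < 0.5) == (eaf_y < 0.5)
      if (concordant) {
        res$disposition[i] <- if (ea_y == ea_x) "kept" else "flipped"
      } else {
        # frequencies disagree: the outcome file reports the complementary
        # strand, so its stated effect allele is the exposure's other allele
        b_y <- -b_y
        eaf_y <- 1 - eaf_y
        res$disposition[i] <- if (ea_y == ea_x) "flipped" else "kept"
      }
      res$beta_outcome[i] <- b_y
      res$se_outcome[i] <- se_y
      res$eaf_outcome[i] <- eaf_y
      res$pval_outcome[i] <- p_y
      next
    }

    # non-palindromic: try direct, swapped, complemented, complement-swapped
    if (ea_y == ea_x && oa_y == oa_x) {
      disposition <- "kept"
    } else if (ea_y == oa_x && oa_y == ea_x) {
      disposition <- "flipped"
    } else {
      ea_c <- unname(complement_base[ea_y])
      oa_c <- unname(complement_base[oa_y])
      if (ea_c == ea_x && oa_c == oa_x) {
        disposition <- "kept"
      } else if (ea_c == oa_x && oa_c == ea_x) {
        disposition <- "flipped"
      } else {
        res$disposition[i] <- "removed_mismatch"
        next
      }
    }
    if (disposition == "flipped") {
      b_y <- -b_y
      eaf_y <- if (is.na(eaf_y)) NA_real_ else 1 - eaf_y
    }
    res$disposition[i] <- disposition
    res$beta_outcome[i] <- b_y
    res$se_outcome[i] <- se_y
    res$eaf_outcome[i] <- eaf_y
    res$pval_outcome[i] <- p_y
  }

  removed <- grepl("^removed_", res$disposition)
  tally <- table(factor(res$disposition[removed],
                        levels = c("removed_missing_outcome",
                                   "removed_palindrome",
                                   "removed_mismatch")))
  attr(res, "dropped") <- stats::setNames(as.integer(tally), names(tally))
  res
}

#' Usable harmonised pairs
#'
#' @param pairs Output of [harmonise()].
#' @return Rows with disposition `kept` or `flipped`.
#' @export
usable_pairs <- function(pairs) {
  pairs[pairs$disposition %in% c("kept", "flipped"), , drop = FALSE]
}
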