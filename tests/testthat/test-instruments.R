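mk_stats <- function(pvals, chrom = "1", pos = NULL, ids = NULL) {
  n <- length(pvals)
  tibble::tibble(
    snp_id = ids %||% sprintf("rs%03d", seq_len(n)),
    chrom = rep_len(chrom, n),
    pos = as.integer(pos %||% seq(1e6, by = 5000, length.out = n)),
    effect_allele = "A", other_allele = "G",
    eaf = 0.3, beta = 0.1, se = 0.01, pval = pvals, n = 10000
  )
}

test_that("p-value preselection is a strict threshold preserving order", {
  s <- mk_stats(c(1e-7, 1e-5, 1e-3))
  expect_equal(select_by_pvalue(s, 5e-6)$snp_id, "rs001")
  expect_equal(nrow(select_by_pvalue(s[0, ], 5e-6)), 0)
  expect_equal(select_by_pvalue(s, 1.0), s)
  # boundary: pval equal to the threshold is excluded
  expect_equal(nrow(select_by_pvalue(mk_stats(5e-6), 5e-6)), 0)
})

test_that("clumping keeps the most significant of a correlated close pair", {
  s <- mk_stats(c(1e-8, 1e-7), pos = c(1e6, 1e6 + 5000))
  ld <- matrix(c(1, 0.9, 0.9, 1), 2, dimnames = list(s$snp_id, s$snp_id))
  expect_equal(clump(s, ld)$snp_id, "rs001")

  # r^2 below threshold: both survive
  ld2 <- matrix(c(1, sqrt(5e-4), sqrt(5e-4), 1), 2,
                dimnames = list(s$snp_id, s$snp_id))
  expect_equal(clump(s, ld2)$snp_id, c("rs001", "rs002"))

  # outside the window: both survive despite r = 0.99
  far <- mk_stats(c(1e-8, 1e-7), pos = c(1e6, 5e8))
  ld3 <- matrix(c(1, 0.99, 0.99, 1), 2,
                dimnames = list(far$snp_id, far$snp_id))
  expect_equal(nrow(clump(far, ld3)), 2)

  # different chromosomes are never clumped together
  cross <- mk_stats(c(1e-8, 1e-7), chrom = c("1", "2"),
                    pos = c(1e6, 1e6))
  expect_equal(nrow(clump(cross, ld)), 2)
})

test_that("missing LD pairs warn and count, NULL matrix does not", {
  s <- mk_stats(c(1e-8, 1e-7))
  expect_warning(out <- clump(s, matrix(1, 1, 1,
                                        dimnames = list("zz", "zz"))),
                 "absent")
  expect_equal(attr(out, "missing_ld_pairs"), 1L)
  expect_silent(out2 <- clump(s, NULL))
  expect_equal(nrow(out2), 2)
})

test_that("clumping agrees with the brute-force greedy oracle", {
  for (i in 1:500) {
    n <- withr::with_seed(i, sample(2:20, 1))
    s <- withr::with_seed(1000 + i, {
      tibble::tibble(
        snp_id = sprintf("v%02d", sample(n)),
        chrom = as.character(sample(1:3, n, replace = TRUE)),
        pos = sample.int(3e7, n),
        effect_allele = "A", other_allele = "G",
        eaf = 0.3, beta = 0.1, se = 0.01,
        pval = round(stats::runif(n), 3) + 1e-6,  # force occasional ties
        n = 10000
      )
    })
    ld <- withr::with_seed(2000 + i, {
      keep <- sample(n, max(2, floor(n * 0.8)))  # some pairs missing
      ids <- sort(s$snp_id[keep])
      k <- length(ids)
      r <- matrix(stats::runif(k * k, -1, 1), k)
      r <- (r + t(r)) / 2
      diag(r) <- 1
      dimnames(r) <- list(ids, ids)
      r
    })
    got <- suppressWarnings(clump(s, ld, r2_threshold = 0.3,
                                  window_kb = 5000))
    want <- oracle_clump(s, ld, r2_threshold = 0.3, window_kb = 5000)
    expect_setequal(got$snp_id, want)
  }
})

test_that("clump output never contains a linked close pair", {
  for (i in 1:25) {
    s <- withr::with_seed(i, {
      n <- 15
      tibble::tibble(
        snp_id = sprintf("v%02d", 1:n), chrom = "1",
        pos = sample.int(2e7, n),
        effect_allele = "A", other_allele = "G", eaf = 0.3,
        beta = 0.1, se = 0.01, pval = stats::runif(n), n = 10000
      )
    })
    ld <- simulate_ld_blocks(c(5, 5, 5), within_r = 0.8,
                             snp_ids = s$snp_id)
    out <- clump(s, ld, r2_threshold = 0.3, window_kb = 1e5)
    expect_true(all(out$snp_id %in% s$snp_id))
    if (nrow(out) > 1) {
      combs <- utils::combn(seq_len(nrow(out)), 2)
      for (k in seq_len(ncol(combs))) {
        a <- out[combs[1, k], ]
        b <- out[combs[2, k], ]
        close <- a$chrom == b$chrom && abs(a$pos - b$pos) <= 1e8
        if (close) expect_lt(ld[a$snp_id, b$snp_id]^2, 0.3)
      }
    }
  }
})

test_that("variance explained and F match the closed-form formula", {
  s <- mk_stats(1e-8)
  s$beta <- 0.1; s$se <- 0.01; s$eaf <- 0.5; s$n <- 10000
  rec <- compute_instrument_strength(s)
  # independent arithmetic: R2 = 2 b^2 pq / (2 b^2 pq + 2 se^2 N pq)
  pq <- 0.5 * 0.5
  r2 <- (2 * 0.1^2 * pq) / (2 * 0.1^2 * pq + 2 * 0.01^2 * 10000 * pq)
  expect_equal(rec$r2, r2, tolerance = 1e-12)
  expect_equal(rec$r2, 0.009901, tolerance = 1e-4)
  expect_equal(rec$f_stat, r2 * (10000 - 2) / (1 - r2), tolerance = 1e-12)
  expect_equal(rec$f_stat, 99.97, tolerance = 1e-3)
  # construction invariant
  expect_equal(rec$f_stat, rec$r2 * (rec$n - 2) / (1 - rec$r2),
               tolerance = 1e-9)
})

test_that("R2 is independent of EAF and zero for a null beta", {
  base <- mk_stats(1e-8)
  eafs <- c(0.01, 0.1, 0.5, 0.9)
  r2s <- vapply(eafs, function(e) {
    s <- base; s$eaf <- e
    compute_instrument_strength(s)$r2
  }, numeric(1))
  expect_lt(max(r2s) - min(r2s), 1e-14)
  expect_equal(r2s[1], 0.1^2 / (0.1^2 + 0.01^2 * 10000), tolerance = 1e-12)

  s0 <- base; s0$beta <- 0
  rec0 <- compute_instrument_strength(s0)
  expect_equal(rec0$r2, 0)
  expect_equal(rec0$f_stat, 0)
})

test_that("F grows with |beta| and with sample size", {
  f_of <- function(beta, n) {
    s <- mk_stats(1e-8); s$beta <- beta; s$n <- n
    compute_instrument_strength(s)$f_stat
  }
  betas <- seq(0.02, 0.5, by = 0.02)
  fs <- vapply(betas, f_of, numeric(1), n = 10000)
  expect_true(all(diff(fs) > 0))
  ns <- seq(1000, 50000, by = 1000)
  fs_n <- vapply(ns, function(n) f_of(0.05, n), numeric(1))
  expect_true(all(diff(fs_n) > 0))
})

test_that("weak-instrument filter uses a strict inequality", {
  s <- mk_stats(c(1e-8, 1e-8, 1e-8), ids = c("a", "b", "c"))
  rec <- compute_instrument_strength(s)
  # engineer F exactly 10 for the first record
  rec$f_stat <- c(10, 9.999, 10.001)
  kept <- filter_weak(rec, 10)
  expect_equal(kept$snp_id, "c")
  expect_equal(nrow(filter_weak(rec[0, ], 10)), 0)
})

test_that("records without EAF are excluded from strength computation", {
  s <- mk_stats(c(1e-8, 1e-8))
  s$eaf[1] <- NA
  rec <- compute_instrument_strength(s)
  expect_equal(nrow(rec), 1)
  expect_equal(unname(dropped_tally(rec)[["missing_eaf"]]), 1)
})
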