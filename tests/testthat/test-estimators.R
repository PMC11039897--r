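test_that("Wald ratio does the delta-method arithmetic", {
  p <- make_pairs(0.1, 0.05, 0.005, 0.01)
  est <- wald_ratio(p)
  expect_equal(est$beta, 0.5)
  expect_equal(est$se, 0.1)
  expect_equal(est$or_, exp(0.5))
  expect_equal(est$pval, 2 * pnorm(-5))

  null <- wald_ratio(make_pairs(0.1, 0, 0.005, 0.01))
  expect_equal(null$beta, 0)
  expect_equal(null$or_, 1)
  expect_equal(null$pval, 1)

  expect_error(wald_ratio(make_pairs(0, 0.05, 0.005, 0.01)), "degenerate")
})

test_that("second-order ratio se is close to first-order for strong instruments", {
  # se_exposure / |beta_exposure| = 0.05: relative difference under 5%
  p <- make_pairs(0.1, 0.05, 0.005, 0.01)
  first <- per_snp_ratios(p)$se_ratio
  second <- per_snp_ratios(p, second_order = TRUE)$se_ratio
  expect_lt(abs(second - first) / first, 0.05)
  expect_gt(second, first)
})

test_that("Cochran's Q matches hand arithmetic and the null chi-square", {
  same <- make_pairs(c(0.1, 0.2, 0.4), c(0.03, 0.06, 0.12), 0.005,
                     c(0.01, 0.02, 0.04))
  q0 <- cochran_q(same)  # all ratios exactly 0.3
  expect_equal(q0$q_stat, 0, tolerance = 1e-20)
  expect_equal(q0$pval, 1)

  # two SNPs, ratios 0.2 and 0.4, both ratio se = 0.1:
  # weights 100 each, IVW = 0.3, Q = 100*0.01 + 100*0.01 = 2
  two <- make_pairs(c(1, 1), c(0.2, 0.4), 0.001, 0.1)
  q2 <- cochran_q(two)
  expect_equal(q2$q_stat, 2, tolerance = 1e-12)
  expect_equal(q2$df, 1)
  expect_equal(q2$pval, pchisq(2, 1, lower.tail = FALSE))

  expect_error(cochran_q(make_pairs(1, 1, 0.01, 0.1)), "at least 2")

  # under a correctly specified null the Q statistic is chi-square(n-1)
  qs <- vapply(1:400, function(i) {
    withr::with_seed(i, {
      bx <- rnorm(10, 0.1, 0.005)
      by <- rnorm(10, 0.3 * bx, 0.01)
    })
    cochran_q(make_pairs(bx, by, 0.005, 0.01))$q_stat
  }, numeric(1))
  ks <- stats::ks.test(qs, "pchisq", df = 9)
  expect_gt(ks$p.value, 0.001)
})

test_that("IVW averages ratios by precision and switches models on Q", {
  two <- make_pairs(c(1, 1), c(0.2, 0.4), 0.001, 0.1)
  fit <- ivw(two)
  expect_equal(fit$estimate$beta, 0.3)
  expect_equal(fit$estimate$se, sqrt(1 / 200))
  expect_equal(fit$estimate$effects_model, "fixed")

  # heterogeneous ratios force the random-effects inflation
  het <- make_pairs(c(1, 1, 1, 1), c(0.1, 0.5, -0.3, 0.9), 0.001, 0.05)
  fit_het <- ivw(het)
  expect_equal(fit_het$estimate$effects_model, "random")
  q <- cochran_q(het)
  expect_equal(fit_het$estimate$se,
               sqrt(1 / (4 / 0.05^2)) * sqrt(q$q_stat / q$df))
  # fixed-effects se never exceeds the random-effects se
  expect_gte(fit_het$estimate$se, sqrt(1 / (4 / 0.05^2)))

  expect_error(ivw(make_pairs(1, 1, 0.01, 0.1)), "at least 2")
})

test_that("IVW with one pair reduces to the Wald ratio", {
  # internal consistency: the IVW formula collapses for n = 1
  p <- make_pairs(0.12, 0.07, 0.004, 0.02)
  r <- per_snp_ratios(p)
  w <- 1 / r$se_ratio^2
  beta_ivw <- sum(w * r$ratio) / sum(w)
  se_ivw <- sqrt(1 / sum(w))
  wald <- wald_ratio(p)
  expect_equal(beta_ivw, wald$beta)
  expect_equal(se_ivw, wald$se)
})

test_that("IVW is invariant to pair order and joint sign flips", {
  withr::with_seed(5, {
    bx <- rnorm(12, 0.1, 0.02)
    by <- rnorm(12, 0.3 * bx, 0.01)
  })
  p <- make_pairs(bx, by, 0.005, 0.01)
  base <- ivw(p)$estimate
  shuffled <- ivw(p[sample(12), ])$estimate
  expect_equal(shuffled$beta, base$beta)
  expect_equal(shuffled$se, base$se)

  flip <- p
  flip$beta_exposure[1:6] <- -flip$beta_exposure[1:6]
  flip$beta_outcome[1:6] <- -flip$beta_outcome[1:6]
  flipped <- ivw(flip)$estimate
  expect_equal(flipped$beta, base$beta)
  expect_equal(flipped$se, base$se)
})

test_that("Egger regression rejects degenerate designs", {
  expect_error(mr_egger(make_pairs(c(1, 1), c(0.2, 0.4), 0.001, 0.1)),
               "at least 3")
  expect_error(mr_egger(make_pairs(c(1, 1, 1), c(0.2, 0.4, 0.3),
                                   0.001, 0.1)),
               "rank-deficien")
})

test_that("Egger slope and intercept match a hand-built weighted fit", {
  withr::with_seed(9, {
    bx <- runif(8, 0.05, 0.2)
    by <- 0.05 + 0.3 * bx + rnorm(8, 0, 0.01)
  })
  p <- make_pairs(bx, by, 0.001, 0.01)
  fit <- mr_egger(p)
  ref <- stats::lm(by ~ bx, weights = rep(1 / 0.01^2, 8))
  expect_equal(fit$estimate$beta, unname(coef(ref)[2]))
  expect_equal(fit$intercept, unname(coef(ref)[1]))
  sm <- summary(ref)
  expect_equal(fit$estimate$se, unname(sm$coefficients[2, 2]))
  expect_equal(fit$intercept_se, unname(sm$coefficients[1, 2]))
  expect_equal(fit$intercept_pval,
               2 * pt(abs(fit$intercept / fit$intercept_se), df = 6,
                      lower.tail = FALSE))
})

test_that("weighted median interpolates the 50% weight point", {
  p3 <- make_pairs(c(1, 1, 1), c(0.1, 0.3, 0.9), 0.001, 0.1)
  est <- weighted_median(p3, n_boot = 200, seed = 1)
  expect_equal(est$beta, 0.3)

  # unequal weights pull the estimate toward the precise instruments
  p4 <- make_pairs(c(1, 1, 1), c(0.1, 0.3, 0.9), 0.001,
                   c(0.01, 0.2, 0.2))
  est4 <- weighted_median(p4, n_boot = 200, seed = 1)
  expect_lt(est4$beta, 0.3)

  expect_error(weighted_median(make_pairs(c(1, 1), c(0.1, 0.3),
                                          0.001, 0.1)),
               "at least 3")
})

test_that("weighted median bootstrap is reproducible under a seed", {
  p <- make_pairs(c(1, 1, 1, 1), c(0.1, 0.3, 0.5, 0.9), 0.001, 0.1)
  a <- weighted_median(p, n_boot = 300, seed = 7)
  b <- weighted_median(p, n_boot = 300, seed = 7)
  expect_identical(a, b)
  c <- weighted_median(p, n_boot = 300, seed = 8)
  expect_false(identical(a$se, c$se))
})

test_that("estimate_all dispatches on the number of usable instruments", {
  one <- make_pairs(0.1, 0.05, 0.005, 0.01)
  f1 <- estimate_all(one)
  expect_equal(tidy(f1)$method, "wald_ratio")
  expect_equal(f1$primary, "wald_ratio")

  two <- make_pairs(c(0.1, 0.2), c(0.05, 0.04), 0.005, 0.01)
  f2 <- estimate_all(two)
  expect_equal(tidy(f2)$method, "ivw")
  expect_false(is.null(f2$heterogeneity))

  five <- make_pairs(seq(0.1, 0.5, 0.1), seq(0.02, 0.1, 0.02) + 0.01,
                     0.005, 0.01)
  f5 <- estimate_all(five, seed = 1, n_boot = 100)
  expect_equal(tidy(f5)$method, c("ivw", "mr_egger", "weighted_median"))
  expect_equal(f5$primary, "ivw")
  g <- glance(f5)
  expect_equal(g$method, "ivw")
  expect_false(is.na(g$egger_intercept_pval))

  removed <- one
  removed$disposition <- "removed_palindrome"
  expect_error(estimate_all(removed), "no usable")
})

test_that("estimates expose coherent OR confidence intervals", {
  five <- make_pairs(seq(0.1, 0.5, 0.1),
                     c(0.033, 0.05, 0.1, 0.13, 0.14), 0.005, 0.01)
  est <- tidy(estimate_all(five, seed = 2, n_boot = 100))
  expect_true(all(est$ci_low < est$or_ & est$or_ < est$ci_high))
  expect_equal(est$or_, exp(est$beta), tolerance = 1e-12)
  z <- qnorm(0.975)
  expect_equal(est$ci_low, exp(est$beta - z * est$se), tolerance = 1e-12)
})

test_that("autoplot returns a ggplot for an MR fit", {
  five <- make_pairs(seq(0.1, 0.5, 0.1),
                     c(0.033, 0.05, 0.1, 0.13, 0.14), 0.005, 0.01)
  fit <- estimate_all(five, seed = 2, n_boot = 50)
  expect_s3_class(autoplot(fit), "ggplot")
})
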