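test_that("frequency and viability are exact, scale-invariant ratios", {
  expect_equal(mutation_frequency(30, 1e7), 3e-6)
  expect_equal(mutation_frequency(0, 1e7), 0)
  expect_equal(mutation_frequency(60, 2e7), mutation_frequency(30, 1e7))
  expect_error(mutation_frequency(30, 0), "> 0")

  expect_equal(viability_percent(5e6, 1e7), 50)
  expect_equal(viability_percent(1e7, 1e7), 100)
  expect_equal(viability_percent(1.2e7, 1e7), 120)  # not clamped
  expect_error(viability_percent(1e6, 0), "> 0")

  expect_equal(titer_per_ml(30, 0.1, 1e-5), 3e7)
})

test_that("median CI uses the binomial order-statistic construction", {
  expect_equal(median_with_ci(c(1, 2, 3, 4, 5))$median, 3)
  expect_equal(median_with_ci(c(1, 2, 3, 4))$median, 2.5)  # midpoint for even n
  ci <- median_with_ci(1:10)
  expect_equal(c(ci$lower, ci$upper), c(2, 9))           # 2nd and 9th order stats
  expect_equal(ci$coverage, 1 - 2 * pbinom(1, 10, 0.5))  # ~0.979 >= 0.95
  expect_true(ci$coverage >= 0.95)
  small <- median_with_ci(1:5)
  expect_false(small$exact)                              # range fallback below n = 6
  expect_equal(c(small$lower, small$upper), c(1, 5))
  expect_error(median_with_ci(numeric(0)), "at least one")
})

test_that("median CI coverage is at least nominal by simulation", {
  withr::with_seed(41, {
    for (n in c(8, 12, 36)) {
      hits <- vapply(1:400, function(i) {
        x <- rnorm(n)
        ci <- median_with_ci(x)
        ci$lower <= 0 && ci$upper >= 0
      }, logical(1))
      # binomial slack below the conservative coverage
      expect_gte(mean(hits), 0.95 - 3 * sqrt(0.05 * 0.95 / 400))
    }
  })
})

test_that("Mann-Whitney: exact branch matches enumeration, wilcox.test and itself", {
  mw <- mann_whitney_one_sided(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$p_value, 1 / 20)  # only 1 of C(6,3) = 20 assignments as extreme
  expect_equal(mw$u, 9)
  expect_equal(mw$method, "exact")

  same <- mann_whitney_one_sided(c(1, 2, 3), c(1, 2, 3))
  expect_gte(same$p_value, 0.5)

  withr::with_seed(43, {
    for (i in 1:10) {
      x <- rnorm(sample(3:6, 1)); y <- rnorm(sample(3:6, 1)) + runif(1, 0, 2)
      got <- mann_whitney_one_sided(x, y)
      expect_equal(got$p_value, oracle_mw(x, y), tolerance = 1e-12)
      # tie-free: base wilcox.test exact branch is an independent cross-check
      wt <- stats::wilcox.test(y, x, alternative = "greater", exact = TRUE)
      expect_equal(got$p_value, wt$p.value, tolerance = 1e-12)
      # tied data: enumeration oracle only
      xt <- round(x); yt <- round(y)
      expect_equal(mann_whitney_one_sided(xt, yt)$p_value, oracle_mw(xt, yt),
                   tolerance = 1e-12)
    }
  })
  expect_error(mann_whitney_one_sided(numeric(0), 1), "non-empty")
})

test_that("exact and normal branches agree closely on moderate samples", {
  # For 8 vs 8 tie-free data the p-value depends only on U, so compare the
  # two branches at every achievable U: a y value placed between the i-th and
  # (i+1)-th x value beats exactly i of them. The worst-case discrepancy of
  # the continuity-corrected normal tail at this size is 0.00545, computed
  # from the full exact null distribution.
  x <- (1:8) * 10
  diffs <- vapply(0:64, function(u) {
    q <- u %/% 8L   # y values beating all 8 x values
    r <- u %% 8L    # one y value beating exactly r of them
    y <- c(1000 + seq_len(q),
           if (r > 0) x[r] + 5,
           -(1000 + seq_len(8 - q - (r > 0))))
    pe <- mann_whitney_one_sided(x, y)$p_value
    pn <- mann_whitney_one_sided(x, y, max_exact = 1)$p_value
    abs(pe - pn)
  }, numeric(1))
  expect_lt(max(diffs), 0.006)
})

test_that("group comparison reports medians, CIs, fold-change and p", {
  d <- tibble::tibble(
    culture = 1:12,
    genotype = "rad1",
    treatment = rep(c("water", "acetaldehyde"), each = 6),
    canr_per_ml = c(10, 20, 20, 30, 30, 40, 40, 50, 60, 60, 70, 80),
    viable_per_ml = 1e7
  )
  cmp <- tidy(compare_groups(d))
  expect_equal(cmp$median_untreated, 2.5e-6)
  expect_equal(cmp$median_treated, 6e-6)
  expect_equal(cmp$fold_change, 2.4)
  expect_equal(cmp$p_value,
               oracle_mw(c(10, 20, 20, 30, 30, 40) / 1e7,
                         c(40, 50, 60, 60, 70, 80) / 1e7))
  # identical groups: fold 1, p >= 0.5
  d2 <- d
  d2$canr_per_ml <- rep(c(10, 20, 20, 30, 30, 40), 2)
  cmp2 <- tidy(compare_groups(d2))
  expect_equal(cmp2$fold_change, 1)
  expect_gte(cmp2$p_value, 0.5)
})

test_that("single-group input is reported with a warning, not an error", {
  d <- tibble::tibble(culture = 1:3, genotype = "wt", treatment = "water",
                      canr_per_ml = c(10, 20, 30), viable_per_ml = 1e7)
  expect_warning(cmp <- compare_groups(d), "skipped")
  t <- tidy(cmp)
  expect_equal(t$median_untreated, 2e-6)
  expect_true(is.na(t$fold_change))
  expect_equal(t$note, "missing_group")
})

test_that("reciprocal fold-changes multiply to one", {
  withr::with_seed(53, {
    truth <- tibble::tibble(genotype = "g", treatment = c("water", "acetaldehyde"),
                            frequency = c(2e-6, 5e-6))
    m <- simulate_assay(truth, seed = 53)
    a <- tidy(compare_groups(m))$fold_change
    b <- tidy(compare_groups(m, untreated = "acetaldehyde",
                             treated = "water"))$fold_change
    expect_equal(a * b, 1)
  })
})
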