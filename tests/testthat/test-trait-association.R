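test_that("correlation matrix has the contract's shape and edge values", {
  # identical columns: r = 1; reversed: r = -1
  ph <- as_phenotypes(a = 1:8, b = 1:8, c = 8:1,
                      d = c(2L, 5L, 3L, 8L, 1L, 6L, 4L, 7L))
  ct <- correlate_traits(ph)
  expect_equal(ct$r["a", "b"], 1)
  expect_equal(ct$r["a", "c"], -1)
  expect_equal(ct$r, t(ct$r))
  expect_equal(diag(ct$r), c(a = 1, b = 1, c = 1, d = 1))
  expect_true(all(abs(ct$r) <= 1 + 1e-12))
  expect_true(all(ct$p >= 0 & ct$p <= 1))
  expect_lt(ct$p["a", "b"], 1e-12)
})

test_that("p-values follow the t transform and set the star tiers", {
  # n = 30, r = 0.5: t = 3.055, two-sided p ~ 0.00487 -> "**"
  withr::local_seed(10)
  # construct two columns with exact sample correlation 0.5 at n = 30
  x <- scale(rnorm(30))[, 1]
  e <- scale(resid(lm(rnorm(30) ~ x)))[, 1]
  y <- 0.5 * x + sqrt(1 - 0.25) * e
  ph <- as_phenotypes(a = x, b = y)
  ct <- correlate_traits(ph)
  expect_equal(ct$r["a", "b"], 0.5, tolerance = 1e-12)
  # t = 0.5 * sqrt(28 / 0.75) = 3.055, df 28 -> p = 0.0049 two-sided
  expect_equal(ct$p["a", "b"], 0.0048999, tolerance = 1e-4)
  expect_equal(ct$stars["a", "b"], "**")

  # independent oracle: cor.test on the same pair
  oracle <- stats::cor.test(x, y)
  expect_equal(ct$p["a", "b"], oracle$p.value, tolerance = 1e-12)

  # strict tier boundaries
  p <- matrix(c(0, 0.05, 0.01, 0.001, 0.0499, 0.0099, 0.0009, 0.5, 1),
              3, 3)
  s <- dusrank:::star_matrix(p)
  # strict boundaries: 0.05 -> ns, 0.01 -> *, 0.001 -> **; just below each
  # boundary moves one tier up (index 5 is the diagonal)
  expect_equal(as.vector(s)[2:8],
               c("", "*", "**", "", "**", "***", ""))
})

test_that("monomorphic characteristics are dropped and reported", {
  ph <- as_phenotypes(a = c(1:9, 1L), b = rep(2L, 10),
                      c = c(5L, 3L, 8L, 1L, 9L, 2L, 7L, 4L, 6L, 5L))
  ct <- correlate_traits(ph)
  expect_equal(ct$dropped, "b")
  expect_equal(rownames(ct$r), c("a", "c"))
  expect_error(correlate_traits(as_phenotypes(a = rep(1L, 5),
                                              b = rep(2L, 5))),
               "non-constant")
})

test_that("significant partner counts match the p matrix", {
  ph <- as_phenotypes(a = 1:10, b = c(1:9, 8L),
                      c = c(2L, 9L, 4L, 7L, 1L, 8L, 3L, 10L, 5L, 6L))
  ct <- correlate_traits(ph)
  counts <- significant_partner_counts(ct, alpha = 0.05)
  manual <- sapply(rownames(ct$p), function(i) {
    sum(ct$p[i, setdiff(rownames(ct$p), i)] < 0.05)
  })
  expect_equal(counts$n_significant, unname(manual))
  expect_error(significant_partner_counts(ct, alpha = 1.2), "alpha")

  # all-ns table gives zero counts
  ct$p[] <- 1
  expect_true(all(significant_partner_counts(ct, 0.05)$n_significant == 0))
})

test_that("correlation is invariant to row order and calibrated under the null", {
  catalog <- millet_catalog()
  cohort <- simulate_cohort(default_cohort_spec(catalog), seed = 17)
  ct <- correlate_traits(cohort)
  perm <- cohort[sample(nrow(cohort)), ]
  expect_equal(correlate_traits(perm)$r, ct$r)

  # type-I calibration: 64 mutually independent traits give 2,016
  # independent-pair tests at n = 30
  withr::local_seed(2025)
  cols <- as.data.frame(matrix(sample(1:9, 30 * 64, replace = TRUE), 30))
  names(cols) <- paste0("t", 1:64)
  ph <- do.call(as_phenotypes, cols)
  p <- correlate_traits(ph)$p
  rate <- mean(p[upper.tri(p)] < 0.05)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("tidy and glance expose the long view consistently", {
  ph <- as_phenotypes(a = 1:6, b = c(2L, 1L, 4L, 3L, 6L, 5L),
                      c = c(6L, 4L, 5L, 2L, 3L, 1L))
  ct <- correlate_traits(ph)
  long <- tidy(ct)
  expect_equal(nrow(long), 3)
  expect_equal(long$r[long$char_a == "a" & long$char_b == "b"],
               ct$r["a", "b"])
  g <- glance(ct)
  expect_equal(g$n_pairs, 3)
})
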