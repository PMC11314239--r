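test_that("PCA handles the rank-1 toy and conserves total variance", {
  # two perfectly correlated traits: eigenvalues (2, 0)
  ph <- as_phenotypes(a = 1:10, b = seq(2L, 20L, 2L))
  fit <- pca_traits(ph)
  expect_equal(fit$eigenvalues, c(2, 0), tolerance = 1e-12)
  expect_equal(fit$n_selected, 1)
  expect_equal(fit$cumulative_variance, 1)

  withr::local_seed(41)
  for (rep in 1:5) {
    m <- sample(3:10, 1)
    n <- sample((m + 2):40, 1)
    cols <- as.data.frame(matrix(sample(1:7, n * m, replace = TRUE), n))
    names(cols) <- paste0("t", seq_len(m))
    fit <- pca_traits(do.call(as_phenotypes, cols))
    expect_equal(sum(fit$eigenvalues), m, tolerance = 1e-8)
    expect_true(all(diff(fit$eigenvalues) <= 1e-12))
    expect_true(all(fit$eigenvalues >= -1e-12))
    # score means 0, score variances = eigenvalues
    expect_equal(colMeans(fit$scores), rep(0, m), tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(apply(fit$scores, 2, stats::var), fit$eigenvalues,
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("independent traits approach the identity-correlation limit", {
  withr::local_seed(42)
  m <- 6
  cols <- as.data.frame(matrix(sample(1:9, 4000 * m, replace = TRUE), 4000))
  names(cols) <- paste0("t", seq_len(m))
  fit <- pca_traits(do.call(as_phenotypes, cols))
  expect_true(all(abs(fit$eigenvalues - 1) < 0.15))
  expect_lte(fit$n_selected, m / 2)
})

test_that("monomorphic characteristics are excluded from the PCA", {
  catalog <- millet_catalog()
  cohort <- simulate_cohort(default_cohort_spec(catalog), seed = 9)
  fit <- pca_traits(cohort)
  # char32 is monomorphic by design; the near-degenerate plant-color trait
  # can also draw constant in a finite sample
  expect_true("char32" %in% fit$dropped)
  m <- 32 - length(fit$dropped)
  expect_equal(length(fit$eigenvalues), m)
  expect_equal(sum(fit$eigenvalues), m, tolerance = 1e-8)
  # loadings = eigenvector * sqrt(eigenvalue): column sums of squares
  # equal the eigenvalues
  expect_equal(colSums(fit$loadings^2), fit$eigenvalues,
               tolerance = 1e-8, ignore_attr = TRUE)
  # orientation: largest-|loading| entry positive per component
  for (j in seq_len(ncol(fit$loadings))) {
    expect_gte(fit$loadings[which.max(abs(fit$loadings[, j])), j], 0)
  }
})

test_that("clustering recovers planted blobs and honors k limits", {
  withr::local_seed(77)
  # two tight, well-separated blobs on 4 traits
  lo <- matrix(sample(1:2, 15 * 4, replace = TRUE), 15)
  hi <- matrix(sample(8:9, 10 * 4, replace = TRUE), 10)
  cols <- as.data.frame(rbind(lo, hi))
  names(cols) <- paste0("t", 1:4)
  ph <- do.call(as_phenotypes, cols)
  cl <- cluster_varieties(ph, k = 2)
  labels <- cl$labels$cluster
  expect_equal(labels, rep(c(1L, 2L), c(15, 10)))

  expect_equal(unique(cluster_varieties(ph, k = 1)$labels$cluster), 1L)
  expect_equal(sort(cluster_varieties(ph, k = 25)$labels$cluster), 1:25)
  expect_error(cluster_varieties(ph, k = 26), "k must")

  # invariant to input order up to the size-based relabeling
  perm <- sample(25)
  cl2 <- cluster_varieties(ph[perm, ], k = 2)
  expect_equal(cl2$labels$cluster[order(perm)], labels)
})

test_that("cluster profiles report sizes, shares and leading characteristics", {
  # the published cluster sizes: largest share 80.9% at 1 d.p.
  sizes <- c(4, 1, 2, 4, 4, 20, 148)
  share <- max(sizes) / sum(sizes)
  expect_equal(round(100 * share, 1), 80.9)

  withr::local_seed(55)
  catalog <- millet_catalog()
  cohort <- simulate_cohort(default_cohort_spec(catalog), seed = 55)
  cl <- cluster_varieties(cohort, k = 7)
  prof <- cluster_profile(cohort, cl)
  expect_equal(nrow(prof), 7)
  expect_equal(sum(prof$share), 1, tolerance = 1e-12)
  expect_equal(sum(prof$size), 183)
  # sizes decrease with the renumbering
  expect_true(all(diff(prof$size) <= 0))

  # single cluster: share 100%, every characteristic maximal
  one <- cluster_varieties(cohort, k = 1)
  prof1 <- cluster_profile(cohort, one)
  expect_equal(prof1$share, 1)
  expect_length(prof1$top_characteristics[[1]], 32)

  # tie contract: equal cluster means are listed for both clusters
  ph <- as_phenotypes(a = c(1L, 1L, 9L, 9L), b = c(3L, 5L, 3L, 5L))
  labels <- tibble::tibble(variety_id = ph$variety_id,
                           cluster = c(1L, 1L, 2L, 2L))
  prof <- cluster_profile(ph, labels)
  expect_equal(prof$top_characteristics[[1]], "b")
  expect_equal(prof$top_characteristics[[2]], c("a", "b"))
})
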