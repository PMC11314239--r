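test_that("the decision model follows the trend table", {
  trend <- tibble::tibble(
    char_code = c("charA", "charB", "charC"),
    direction = c("increase", "decrease", "none")
  )
  model <- build_decision_model(trend)
  expect_equal(model$char_code, c("charA", "charB"))
  expect_equal(model$orientation, c("benefit", "cost"))
  expect_equal(model$weight, c(0.5, 0.5))

  catalog <- millet_catalog()
  cohort <- simulate_cohort(default_cohort_spec(catalog), seed = 8)
  model <- build_decision_model(trend_analysis(cohort))
  expect_equal(nrow(model), 20)
  expect_equal(sum(model$orientation == "benefit"), 8)
  expect_equal(sum(model$orientation == "cost"), 12)
  expect_true(all(model$weight == 1 / 20))

  trend$direction <- "none"
  expect_error(build_decision_model(trend), "no significant")
  expect_error(decision_model("charA", "benefit", weight = 0.9), "sum to 1")
})

test_that("dominant alternatives take the extreme closeness scores", {
  ph <- as_phenotypes(charA = c(5L, 1L), charB = c(4L, 2L))
  model <- decision_model(c("charA", "charB"), c("benefit", "benefit"))
  res <- topsis_rank(ph, model)
  res <- res[order(res$variety_id), ]
  expect_equal(res$score, c(1, 0))
  expect_equal(res$rank, c(1L, 2L))
})

test_that("the one-criterion case matches the hand evaluation", {
  ph <- as_phenotypes(charA = c(1L, 2L, 3L))
  benefit <- decision_model("charA", "benefit")
  res <- topsis_rank(ph, benefit)
  res <- res[order(res$variety_id), ]
  expect_equal(res$score, c(0, 0.5, 1), tolerance = 1e-12)
  expect_equal(res$rank, c(3L, 2L, 1L))

  cost <- decision_model("charA", "cost")
  res <- topsis_rank(ph, cost)
  res <- res[order(res$variety_id), ]
  expect_equal(res$score, c(1, 0.5, 0), tolerance = 1e-12)
})

test_that("pipeline distances equal the brute-force oracle", {
  withr::local_seed(99)
  for (rep in 1:500) {
    n <- sample(2:8, 1)
    m <- sample(1:6, 1)
    x <- matrix(sample(1:9, n * m, replace = TRUE), n, m)
    orientation <- sample(c("benefit", "cost"), m, replace = TRUE)
    w <- stats::runif(m) + 0.1
    w <- w / sum(w)
    cols <- as.data.frame(x)
    names(cols) <- paste0("c", seq_len(m))
    ph <- do.call(as_phenotypes, cols)
    model <- decision_model(names(cols), orientation, weight = w)
    res <- suppressWarnings(topsis_rank(ph, model))
    res <- res[order(match(res$variety_id, ph$variety_id)), ]
    oracle <- brute_force_topsis(x, orientation, w)
    expect_equal(res$d_plus, oracle$d_plus, tolerance = 1e-10)
    expect_equal(res$d_minus, oracle$d_minus, tolerance = 1e-10)
    expect_equal(res$score, oracle$score, tolerance = 1e-10)
    expect_equal(sort(res$rank), seq_len(n))
  }
})

test_that("scores are scale-invariant per criterion", {
  withr::local_seed(13)
  cols <- as.data.frame(matrix(sample(1:9, 10 * 3, replace = TRUE), 10))
  names(cols) <- c("c1", "c2", "c3")
  ph <- do.call(as_phenotypes, cols)
  model <- decision_model(names(cols), c("benefit", "cost", "benefit"))
  base <- topsis_rank(ph, model)
  ph2 <- ph
  ph2$c2 <- ph2$c2 * 7L
  scaled <- topsis_rank(ph2, model)
  expect_equal(scaled$score, base$score, tolerance = 1e-12)
  expect_equal(scaled$variety_id, base$variety_id)
})

test_that("duplicating a variety only acts through the normalization", {
  withr::local_seed(14)
  cols <- as.data.frame(matrix(sample(1:9, 6 * 3, replace = TRUE), 6))
  names(cols) <- c("c1", "c2", "c3")
  ph <- do.call(as_phenotypes, cols)
  model <- decision_model(names(cols), c("benefit", "cost", "cost"))
  dup <- rbind(ph, ph[3, ])
  dup$variety_id[7] <- "v999"
  res <- topsis_rank(dup, model)
  res <- res[order(match(res$variety_id, dup$variety_id)), ]
  oracle <- brute_force_topsis(as.matrix(dup[, c("c1", "c2", "c3")]),
                               model$orientation, model$weight)
  expect_equal(res$score, oracle$score, tolerance = 1e-10)
  # the duplicate shares its twin's score exactly
  expect_equal(res$score[7], res$score[3], tolerance = 1e-12)
})

test_that("degenerate and error cases follow the contract", {
  # all varieties identical on every criterion
  ph <- as_phenotypes(charA = rep(3L, 4), charB = rep(5L, 4))
  model <- decision_model(c("charA", "charB"), c("benefit", "cost"))
  expect_warning(res <- topsis_rank(ph, model), "identical")
  expect_equal(res$score, rep(0.5, 4))
  expect_equal(sort(res$rank), 1:4)

  # zero-norm criterion column
  ph <- as_phenotypes(charA = c(0L, 0L, 0L), charB = c(1L, 2L, 3L))
  model <- decision_model(c("charA", "charB"), c("benefit", "benefit"))
  expect_error(topsis_rank(ph, model), "zero norm")

  # missing criterion column
  model <- decision_model("charZ", "benefit")
  expect_error(topsis_rank(as_phenotypes(charA = 1:3), model), "charZ")
})

test_that("distance mode ranks ascending by distance to the ideal", {
  withr::local_seed(15)
  cols <- as.data.frame(matrix(sample(1:9, 12 * 4, replace = TRUE), 12))
  names(cols) <- paste0("c", 1:4)
  ph <- do.call(as_phenotypes, cols)
  model <- decision_model(names(cols),
                          c("benefit", "cost", "benefit", "cost"))
  res <- topsis_rank(ph, model, score_mode = "distance")
  expect_equal(res$score, res$d_plus)
  expect_true(all(diff(res$score[order(res$rank)]) >= 0))
})

test_that("entropy weighting yields a valid weight vector", {
  withr::local_seed(16)
  cols <- as.data.frame(matrix(sample(1:9, 20 * 5, replace = TRUE), 20))
  names(cols) <- paste0("c", 1:5)
  ph <- do.call(as_phenotypes, cols)
  model <- decision_model(names(cols),
                          rep(c("benefit", "cost"), c(3, 2)),
                          weighting = "entropy")
  res <- topsis_rank(ph, model)
  w <- attr(res, "weights")
  expect_length(w, 5)
  expect_true(all(w >= 0))
  expect_equal(sum(w), 1, tolerance = 1e-9)
})
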