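#' Build a trend-directed TOPSIS decision model
#'
#' Turns a breeding-trend table into a multi-criteria decision model: every
#' characteristic with a significant group difference becomes a criterion,
#' oriented `benefit` where breeding has increased the trait (the ideal
#' solution is the maximum) and `cost` where it has decreased it (the ideal
#' is the minimum). All criteria receive equal weight `1/m`; `weighting =
#' "entropy"` instead derives weights from the entropy-weight method on the
#' decision matrix at ranking time (an extension beyond the equal-weight
#' reference analysis).
#'
#' @param trend a trend table from [trend_analysis()].
#' @param weighting `"equal"` (default) or `"entropy"`.
#' @return An object of class `decision_model`: a tibble with columns
#'   `char_code`, `orientation`, `weight`, plus a `weighting` attribute.
#' @export
build_decision_model <- function(trend, weighting = c("equal", "entropy")) {
  weighting <- match.arg(weighting)
  stopifnot(all(c("char_code", "direction") %in% names(trend)))
  sig <- trend[trend$direction != "none", ]
  if (nrow(sig) == 0) {
    stop("no significant characteristic: supply orientations manually ",
         "via decision_model()", call. = FALSE)
  }
  decision_model(
    char_code = sig$char_code,
    orientation = ifelse(sig$direction == "increase", "benefit", "cost"),
    weighting = weighting
  )
}

#' @rdname build_decision_model
#' @param char_code criterion characteristic codes.
#' @param orientation per-criterion `"benefit"` or `"cost"`.
#' @param weight per-criterion positive weights summing to 1; defaults to
#'   equal weights (ignored with a message when `weighting = "entropy"`,
#'   which computes weights from the data at ranking time).
#' @export
decision_model <- function(char_code, orientation,
                           weight = rep(1 / length(char_code),
                                        length(char_code)),
                           weighting = c("equal", "entropy")) {
  weighting <- match.arg(weighting)
  if (length(char_code) == 0) {
    stop("criteria must be non-empty", call. = FALSE)
  }
  stopifnot(length(orientation) == length(char_code),
            all(orientation %in% c("benefit", "cost")),
            length(weight) == length(char_code), all(weight > 0))
  if (abs(sum(weight) - 1) > 1e-9) {
    stop("weights must sum to 1", call. = FALSE)
  }
  out <- tibble::tibble(char_code = as.character(char_code),
                        orientation = orientation, weight = weight)
  attr(out, "weighting") <- weighting
  class(out) <- c("decision_model", class(out))
  out
}

entropy_weights <- function(x) {
  # entropy-weight method: column shares -> entropy -> divergence weights
  n <- nrow(x)
  w <- apply(x, 2, function(col) {
    p <- col / sum(col)
    p <- p[p > 0]
    e <- -sum(p * log(p)) / log(n)
    1 - e
  })
  if (sum(w) == 0) {
    rep(1 / ncol(x), ncol(x))
  } else {
    w / sum(w)
  }
}

#' Rank varieties with the TOPSIS model
#'
#' Scores every variety's breeding potential against the decision model:
#' (1) vector normalization of each criterion column,
#' `r_ij = x_ij / sqrt(sum_i x_ij^2)`; (2) weighting `v_ij = w_j * r_ij`;
#' (3) the positive ideal takes each criterion's best weighted value
#' (maximum for benefit criteria, minimum for cost) and the negative ideal
#' the worst; (4) Euclidean distances `d_plus`/`d_minus` of each variety to
#' the two ideals; (5) the proximity (closeness) score
#' `C = d_minus / (d_plus + d_minus)`; (6) ranking. Under the default
#' `score_mode = "closeness"`, rank 1 is the maximal `C`; `score_mode =
#' "distance"` instead reports `score = d_plus` and ranks ascending
#' (rank 1 = nearest to the ideal), the convention matching score tables
#' whose printed values are small distances. Ties are broken by input
#' order, so ranks are always a permutation of `1..n`.
#'
#' If all varieties are identical on every criterion (`d_plus + d_minus =
#' 0`), every score is defined as 0.5 with a warning.
#'
#' @inheritParams diversity_summary
#' @param model a `decision_model` from [build_decision_model()].
#' @param score_mode `"closeness"` (default) or `"distance"`.
#' @return A tibble of class `topsis_result` with one row per variety,
#'   ordered by rank: `variety_id`, `group` (if present), `d_plus`,
#'   `d_minus`, `score`, `rank`.
#' @examples
#' catalog <- read_catalog(system.file("extdata", "characteristics.csv",
#'                                     package = "dusrank"))
#' cohort <- simulate_cohort(default_cohort_spec(catalog), seed = 1)
#' model <- build_decision_model(trend_analysis(cohort))
#' head(topsis_rank(cohort, model))
#' @export
topsis_rank <- function(phenotypes, model,
                        score_mode = c("closeness", "distance")) {
  score_mode <- match.arg(score_mode)
  stopifnot(inherits(model, "decision_model"))
  miss <- setdiff(model$char_code, names(phenotypes))
  if (length(miss) > 0) {
    stop("criterion column(s) missing from the phenotype table: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  x <- as.matrix(tibble::as_tibble(phenotypes)[model$char_code])
  storage.mode(x) <- "double"
  norms <- sqrt(colSums(x^2))
  zero <- model$char_code[norms == 0]
  if (length(zero) > 0) {
    stop("criterion column(s) with zero norm: ",
         paste(zero, collapse = ", "), call. = FALSE)
  }
  w <- if (attr(model, "weighting") == "entropy") {
    entropy_weights(x)
  } else {
    model$weight
  }
  v <- sweep(sweep(x, 2, norms, "/"), 2, w, "*")
  benefit <- model$orientation == "benefit"
  a_plus <- ifelse(benefit, apply(v, 2, max), apply(v, 2, min))
  a_minus <- ifelse(benefit, apply(v, 2, min), apply(v, 2, max))
  d_plus <- sqrt(rowSums(sweep(v, 2, a_plus)^2))
  d_minus <- sqrt(rowSums(sweep(v, 2, a_minus)^2))
  denom <- d_plus + d_minus
  if (all(denom == 0)) {
    warning("all varieties identical on every criterion; scores set to 0.5")
    closeness <- rep(0.5, nrow(x))
  } else {
    closeness <- d_minus / denom
  }
  score <- if (score_mode == "closeness") closeness else d_plus
  # stable ranking: ties broken by input order
  ord <- if (score_mode == "closeness") {
    order(-score, seq_along(score))
  } else {
    order(score, seq_along(score))
  }
  rank <- integer(length(score))
  rank[ord] <- seq_along(score)
  out <- tibble::tibble(
    variety_id = phenotypes$variety_id,
    d_plus = d_plus,
    d_minus = d_minus,
    score = score,
    rank = rank
  )
  if ("group" %in% names(phenotypes)) {
    out <- dplyr::mutate(out, group = phenotypes$group, .after = "variety_id")
  }
  out <- dplyr::arrange(out, .data$rank)
  attr(out, "score_mode") <- score_mode
  attr(out, "weights") <- w
  class(out) <- c("topsis_result", class(out))
  out
}

#' @export
glance.topsis_result <- function(x, ...) {
  tibble::tibble(
    n_varieties = nrow(x),
    score_mode = attr(x, "score_mode"),
    n_criteria = length(attr(x, "weights")),
    best_variety = x$variety_id[x$rank == 1]
  )
}

#' @export
autoplot.topsis_result <- function(object, ...) {
  df <- tibble::as_tibble(object)
  mapping <- if ("group" %in% names(df)) {
    ggplot2::aes(x = .data$rank, y = .data$score, colour = .data$group)
  } else {
    ggplot2::aes(x = .data$rank, y = .data$score)
  }
  ggplot2::ggplot(df, mapping) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "rank", y = paste0("score (",
                                         attr(object, "score_mode"), ")")) +
    ggplot2::theme_minimal()
}
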