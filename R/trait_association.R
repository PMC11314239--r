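#' Pairwise Pearson correlation among characteristics
#'
#' Computes Pearson's r between all pairs of non-monomorphic characteristic
#' columns (ordinal codes treated as numeric), two-sided p-values from the
#' t transform `t = r * sqrt((n - 2) / (1 - r^2))` with `n - 2` degrees of
#' freedom, and significance stars at the strict tiers p < 0.05 (`*`),
#' p < 0.01 (`**`), p < 0.001 (`***`). Monomorphic (zero-variance)
#' characteristics are dropped before computation and reported in the
#' result. No multiple-testing correction is applied by default, matching
#' the usual starred-heatmap presentation; `adjust = "BH"` switches the
#' p-values (and stars) to Benjamini-Hochberg adjusted values.
#'
#' @inheritParams diversity_summary
#' @param adjust `"none"` (default) or `"BH"`.
#' @return An object of class `trait_correlation`: a list with symmetric
#'   matrices `r`, `p`, `stars`, the sample size `n`, and `dropped` (codes
#'   of excluded monomorphic characteristics). Use [tidy()] for a long
#'   tibble and [autoplot()] for a heatmap.
#' @examples
#' catalog <- read_catalog(system.file("extdata", "characteristics.csv",
#'                                     package = "dusrank"))
#' cohort <- simulate_cohort(default_cohort_spec(catalog), seed = 1)
#' ct <- correlate_traits(cohort)
#' head(tidy(ct))
#' @export
correlate_traits <- function(phenotypes, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  vals <- trait_columns(phenotypes)
  n <- nrow(vals)
  if (n < 3) {
    stop("at least 3 varieties are required", call. = FALSE)
  }
  sds <- vapply(vals, stats::sd, numeric(1))
  dropped <- names(vals)[sds == 0]
  vals <- vals[sds > 0]
  if (ncol(vals) < 2) {
    stop("fewer than 2 non-constant characteristics", call. = FALSE)
  }
  r <- stats::cor(as.matrix(vals))
  t_stat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(t_stat), df = n - 2, lower.tail = FALSE)
  diag(p) <- 0
  if (adjust == "BH") {
    off <- upper.tri(p)
    p[off] <- stats::p.adjust(p[off], method = "BH")
    p[lower.tri(p)] <- t(p)[lower.tri(p)]
  }
  structure(
    list(r = r, p = p, stars = star_matrix(p), n = n, dropped = dropped,
         adjust = adjust),
    class = "trait_correlation"
  )
}

star_matrix <- function(p) {
  s <- matrix("", nrow(p), ncol(p), dimnames = dimnames(p))
  s[p < 0.05] <- "*"
  s[p < 0.01] <- "**"
  s[p < 0.001] <- "***"
  diag(s) <- ""
  s
}

#' Count significant correlation partners per characteristic
#'
#' For each characteristic in a [correlate_traits()] result, the number of
#' other characteristics correlated with it at `p < alpha`.
#'
#' @param table a `trait_correlation`.
#' @param alpha significance level, strictly between 0 and 1.
#' @return A tibble with columns `char_code`, `n_significant`.
#' @export
significant_partner_counts <- function(table, alpha = 0.05) {
  stopifnot(inherits(table, "trait_correlation"))
  if (alpha <= 0 || alpha >= 1) {
    stop("alpha must lie strictly between 0 and 1", call. = FALSE)
  }
  p <- table$p
  diag(p) <- 1
  tibble::tibble(
    char_code = rownames(p),
    n_significant = as.integer(rowSums(p < alpha))
  )
}

#' @export
tidy.trait_correlation <- function(x, ...) {
  cc <- rownames(x$r)
  idx <- which(upper.tri(x$r), arr.ind = TRUE)
  tibble::tibble(
    char_a = cc[idx[, 1]],
    char_b = cc[idx[, 2]],
    r = x$r[idx],
    p = x$p[idx],
    stars = x$stars[idx]
  )
}

#' @export
glance.trait_correlation <- function(x, ...) {
  off <- upper.tri(x$p)
  tibble::tibble(
    n_varieties = x$n,
    n_characteristics = ncol(x$r),
    n_dropped = length(x$dropped),
    n_pairs = sum(off),
    n_significant_05 = sum(x$p[off] < 0.05),
    mean_abs_r = mean(abs(x$r[off]))
  )
}

#' @export
print.trait_correlation <- function(x, ...) {
  g <- glance(x)
  cat("Pairwise Pearson correlation of", g$n_characteristics,
      "characteristics over", g$n_varieties, "varieties\n")
  if (length(x$dropped) > 0) {
    cat("Dropped monomorphic:", paste(x$dropped, collapse = ", "), "\n")
  }
  cat(g$n_significant_05, "of", g$n_pairs, "pairs significant at p < 0.05",
      if (x$adjust == "BH") "(BH-adjusted)" else "", "\n")
  invisible(x)
}

#' @export
autoplot.trait_correlation <- function(object, ...) {
  long <- tidy(object)
  long2 <- dplyr::bind_rows(
    long,
    dplyr::rename(long, char_a = "char_b", char_b = "char_a")
  )
  lv <- rownames(object$r)
  long2$char_a <- factor(long2$char_a, levels = lv)
  long2$char_b <- factor(long2$char_b, levels = rev(lv))
  ggplot2::ggplot(long2, ggplot2::aes(x = .data$char_a, y = .data$char_b,
                                      fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$stars), size = 2) +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
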