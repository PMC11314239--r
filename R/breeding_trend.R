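.tier_breaks <- c(0.05, 0.01, 0.001, 0.0001)

p_to_tier <- function(p) {
  dplyr::case_when(
    p < 0.0001 ~ "****",
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ "ns"
  )
}

#' Landrace-versus-cultivated breeding-trend analysis
#'
#' For every characteristic, compares the coded values of the landrace and
#' cultivated groups with a two-sample test (Welch's unequal-variance t-test
#' by default, Wilcoxon rank-sum optionally), assigns a significance tier at
#' the strict thresholds p < 0.05 (`*`), 0.01 (`**`), 0.001 (`***`),
#' 0.0001 (`****`), `ns` otherwise, and derives the selection direction from
#' the sign of (cultivated mean - landrace mean) whenever the difference is
#' significant: `increase` for characteristics breeding has pushed up,
#' `decrease` for those it has pushed down, `none` otherwise. If both groups
#' are constant at the same value the characteristic is reported with
#' statistic 0 and p = 1 (not an error). No multiple-testing correction is
#' applied by default; `adjust = "BH"` applies Benjamini-Hochberg before
#' tiers are assigned.
#'
#' @inheritParams diversity_summary
#' @param test `"welch"` (default) or `"wilcoxon"`.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return A tibble with one row per characteristic and columns
#'   `char_code`, `mean_landrace`, `mean_cultivated`, `statistic`, `p`,
#'   `tier`, `direction`.
#' @examples
#' catalog <- read_catalog(system.file("extdata", "characteristics.csv",
#'                                     package = "dusrank"))
#' cohort <- simulate_cohort(default_cohort_spec(catalog), seed = 1)
#' trend <- trend_analysis(cohort)
#' table(trend$direction)
#' @export
trend_analysis <- function(phenotypes, test = c("welch", "wilcoxon"),
                           adjust = c("none", "BH")) {
  test <- match.arg(test)
  adjust <- match.arg(adjust)
  g <- phenotypes$group
  if (sum(g == "landrace") < 2 || sum(g == "cultivated") < 2) {
    stop("both groups need at least 2 varieties", call. = FALSE)
  }
  vals <- trait_columns(phenotypes)
  out <- purrr::map_dfr(names(vals), function(cc) {
    x <- vals[[cc]][g == "landrace"]
    y <- vals[[cc]][g == "cultivated"]
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      stat <- if (mean(x) == mean(y)) 0 else sign(mean(y) - mean(x)) * Inf
      p <- if (mean(x) == mean(y)) 1 else 0
    } else if (test == "welch") {
      fit <- stats::t.test(y, x, var.equal = FALSE)
      stat <- unname(fit$statistic)
      p <- fit$p.value
    } else {
      fit <- suppressWarnings(stats::wilcox.test(y, x))
      stat <- unname(fit$statistic)
      p <- fit$p.value
    }
    tibble::tibble(
      char_code = cc,
      mean_landrace = mean(x),
      mean_cultivated = mean(y),
      statistic = stat,
      p = p
    )
  })
  if (adjust == "BH") {
    out$p <- stats::p.adjust(out$p, method = "BH")
  }
  out |>
    dplyr::mutate(
      tier = p_to_tier(.data$p),
      direction = dplyr::case_when(
        .data$tier == "ns" ~ "none",
        .data$mean_cultivated > .data$mean_landrace ~ "increase",
        TRUE ~ "decrease"
      )
    )
}

#' Partition characteristics by selection direction
#'
#' @param trend a trend table from [trend_analysis()].
#' @return A list with character vectors `increased`, `decreased`,
#'   `unchanged`, each in the trend table's (catalog) order.
#' @export
trend_directions <- function(trend) {
  stopifnot(all(c("char_code", "direction") %in% names(trend)))
  list(
    increased = trend$char_code[trend$direction == "increase"],
    decreased = trend$char_code[trend$direction == "decrease"],
    unchanged = trend$char_code[trend$direction == "none"]
  )
}

#' Group-difference panel plot
#'
#' Convenience plot of a trend table: per characteristic, the landrace and
#' cultivated group means side by side with the significance tier printed
#' above.
#'
#' @param trend a trend table from [trend_analysis()].
#' @return A ggplot object.
#' @export
plot_trend <- function(trend) {
  long <- trend |>
    tidyr::pivot_longer(c("mean_landrace", "mean_cultivated"),
                        names_to = "group", values_to = "mean_code",
                        names_prefix = "mean_")
  long$char_code <- factor(long$char_code, levels = trend$char_code)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$char_code,
                                     y = .data$mean_code,
                                     fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_text(
      data = dplyr::mutate(trend,
                           y = pmax(.data$mean_landrace,
                                    .data$mean_cultivated) + 0.3),
      ggplot2::aes(x = .data$char_code, y = .data$y, label = .data$tier),
      inherit.aes = FALSE, size = 2.5
    ) +
    ggplot2::labs(x = NULL, y = "mean expression code", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
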