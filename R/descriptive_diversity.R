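#' Per-characteristic descriptive statistics and Shannon diversity
#'
#' Computes, for every characteristic column of a coded phenotype table, the
#' mean, sample standard deviation (n - 1 denominator), coefficient of
#' variation CV = SD / mean x 100, minimum, maximum, median, and Shannon's
#' diversity index H' = -sum(Pi * ln(Pi)) over the observed state
#' proportions Pi (natural log, in nats; states with zero count contribute
#' nothing). A monomorphic characteristic therefore has CV = 0 and H' = 0.
#'
#' @param phenotypes a coded phenotype tibble (columns `variety_id`,
#'   `group`, then one integer column per characteristic); at least 2
#'   varieties.
#' @return A tibble with one row per characteristic and columns
#'   `char_code`, `mean`, `sd`, `cv`, `max`, `min`, `median`, `shannon`,
#'   `n_states` (number of observed states).
#' @examples
#' catalog <- read_catalog(system.file("extdata", "characteristics.csv",
#'                                     package = "dusrank"))
#' cohort <- simulate_cohort(default_cohort_spec(catalog), seed = 1)
#' diversity_summary(cohort)
#' @export
diversity_summary <- function(phenotypes) {
  vals <- trait_columns(phenotypes)
  if (nrow(vals) < 2) {
    stop("at least 2 varieties are required", call. = FALSE)
  }
  purrr::map_dfr(names(vals), function(cc) {
    v <- vals[[cc]]
    m <- mean(v)
    if (m == 0) {
      stop("characteristic ", cc, ": mean is 0, CV undefined", call. = FALSE)
    }
    s <- stats::sd(v)
    tibble::tibble(
      char_code = cc,
      mean = m,
      sd = s,
      cv = s / m * 100,
      max = max(v),
      min = min(v),
      median = stats::median(v),
      shannon = shannon_index(v),
      n_states = length(unique(v))
    )
  })
}

#' Shannon diversity index of a vector of state codes
#'
#' @param values vector of observed states.
#' @return H' in nats: `-sum(Pi * ln(Pi))` over observed state proportions.
#' @export
shannon_index <- function(values) {
  p <- as.numeric(table(values)) / length(values)
  p <- p[p > 0]
  # + 0 normalizes the IEEE negative zero of the monomorphic case
  -sum(p * log(p)) + 0
}

#' Ten-grade coding of measured values
#'
#' Maps continuous measurements (leaf length, stem length, panicle weight,
#' ...) onto the 10-grade DUS coding scale around the trait mean `x_bar` and
#' standard deviation `s`: grade 1 below `x_bar - 2s`, grade 10 above
#' `x_bar + 2s`, and grades 2..9 covering eight consecutive half-open
#' intervals of width `0.5 s` in between (grade g covers
#' `[x_bar + (g - 6) * 0.5 s, x_bar + (g - 5) * 0.5 s)`). The exact upper
#' boundary `x_bar + 2s` is assigned grade 10, continuing the left-closed
#' convention upward. With `s = 0` every value receives the central grade 5.
#'
#' @param values numeric measurements to grade.
#' @param x_bar trait mean.
#' @param s trait standard deviation, `s >= 0`.
#' @return Integer grades in 1..10, one per value.
#' @examples
#' grade_values(c(2.9, 5.0, 7.2), x_bar = 5, s = 1)
#' @export
grade_values <- function(values, x_bar, s) {
  stopifnot(is.numeric(values), s >= 0)
  if (s == 0) {
    return(rep(5L, length(values)))
  }
  g <- floor((values - (x_bar - 2 * s)) / (0.5 * s)) + 2
  as.integer(pmin(pmax(g, 1), 10))
}

#' Relative state frequencies per characteristic
#'
#' The long-format content of a variation-type distribution panel: for each
#' characteristic, the relative frequency of each observed state code.
#'
#' @inheritParams diversity_summary
#' @return A tibble with columns `char_code`, `code`, `count`, `frequency`;
#'   frequencies sum to 1 within each characteristic.
#' @export
frequency_distribution <- function(phenotypes) {
  vals <- trait_columns(phenotypes)
  n <- nrow(vals)
  purrr::map_dfr(names(vals), function(cc) {
    tab <- table(vals[[cc]])
    tibble::tibble(
      char_code = cc,
      code = as.integer(names(tab)),
      count = as.integer(tab),
      frequency = as.integer(tab) / n
    )
  })
}

# The characteristic columns of a phenotype table, as a tibble.
trait_columns <- function(phenotypes) {
  stopifnot(is.data.frame(phenotypes))
  keep <- setdiff(names(phenotypes), c("variety_id", "group"))
  if (length(keep) == 0) {
    stop("phenotype table has no characteristic columns", call. = FALSE)
  }
  tibble::as_tibble(phenotypes)[keep]
}

#' State-frequency bar panel
#'
#' Convenience plot of [frequency_distribution()]: one bar panel per
#' characteristic.
#'
#' @inheritParams diversity_summary
#' @param chars optional character vector restricting the panel to some
#'   characteristics.
#' @return A ggplot object.
#' @export
plot_frequency_distribution <- function(phenotypes, chars = NULL) {
  freq <- frequency_distribution(phenotypes)
  if (!is.null(chars)) {
    freq <- dplyr::filter(freq, .data$char_code %in% chars)
  }
  freq$char_code <- factor(freq$char_code, levels = unique(freq$char_code))
  ggplot2::ggplot(freq, ggplot2::aes(x = factor(.data$code),
                                     y = .data$frequency)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~char_code, scales = "free_x") +
    ggplot2::labs(x = "expression state code", y = "relative frequency") +
    ggplot2::theme_minimal()
}
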