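#' Run the full evaluation pipeline
#'
#' One call covering the whole analysis: descriptive diversity, state
#' frequencies, trait correlation, PCA, Ward clustering, the
#' landrace-versus-cultivated trend analysis, and the trend-directed TOPSIS
#' ranking. Input is either an existing phenotype table (`phenotypes` or
#' `phenotypes_path`) or a simulated cohort (`simulate = TRUE`). Writes six
#' CSVs (`summary.csv`, `correlation.csv`, `pca.csv`, `clusters.csv`,
#' `trend.csv`, `ranking.csv`) plus `manifest.yaml` into `out_dir`; every
#' CSV starts with `#`-prefixed comment lines recording the package version
#' and seed, which [read_phenotypes()]-style readers skip. Given the same
#' seed and inputs the outputs are byte-identical across runs.
#'
#' @param out_dir output directory (created if needed).
#' @param catalog a `dus_catalog`; defaults to the packaged
#'   32-characteristic guideline.
#' @param phenotypes an already-validated phenotype tibble, or `NULL`.
#' @param phenotypes_path path to a phenotypes CSV, used when `phenotypes`
#'   is `NULL` and `simulate` is `FALSE`.
#' @param simulate if `TRUE`, simulate the input cohort with
#'   [default_cohort_spec()] / [simulate_cohort()].
#' @param seed integer seed for simulation (recorded in the manifest).
#' @param effect_size planted standardized effect for simulation.
#' @param n_landrace,n_cultivated simulated group sizes.
#' @param k number of clusters.
#' @param test two-group test passed to [trend_analysis()].
#' @param score_mode passed to [topsis_rank()].
#' @param weighting passed to [build_decision_model()].
#' @return Invisibly, a named list of the written file paths.
#' @export
run_pipeline <- function(out_dir,
                         catalog = read_catalog(
                           system.file("extdata", "characteristics.csv",
                                       package = "dusrank")),
                         phenotypes = NULL,
                         phenotypes_path = NULL,
                         simulate = is.null(phenotypes) &&
                           is.null(phenotypes_path),
                         seed = 1L,
                         effect_size = 1,
                         n_landrace = 52L,
                         n_cultivated = 131L,
                         k = 7L,
                         test = "welch",
                         score_mode = "closeness",
                         weighting = "equal") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(phenotypes)) {
    if (simulate) {
      spec <- default_cohort_spec(catalog, effect_size = effect_size,
                                  n_landrace = n_landrace,
                                  n_cultivated = n_cultivated, seed = seed)
      phenotypes <- simulate_cohort(spec)
    } else if (!is.null(phenotypes_path)) {
      phenotypes <- read_phenotypes(phenotypes_path, catalog)
    } else {
      stop("supply phenotypes, phenotypes_path, or simulate = TRUE",
           call. = FALSE)
    }
  } else {
    phenotypes <- validate_phenotypes(phenotypes, catalog)
  }
  k <- min(k, nrow(phenotypes))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
    })
  }
  summary_tbl <- stage("describe", diversity_summary(phenotypes))
  cor_tbl <- stage("correlate", tidy(correlate_traits(phenotypes)))
  pca_fit <- stage("pca", pca_traits(phenotypes))
  clust <- stage("cluster", cluster_varieties(phenotypes, k = k))
  trend <- stage("trend", trend_analysis(phenotypes, test = test))
  ranking <- stage("rank", {
    model <- build_decision_model(trend, weighting = weighting)
    topsis_rank(phenotypes, model, score_mode = score_mode)
  })

  pca_tbl <- tibble::as_tibble(pca_fit$scores[, seq_len(min(2, ncol(pca_fit$scores))), drop = FALSE]) |>
    dplyr::mutate(variety_id = pca_fit$variety_id,
                  group = pca_fit$groups, .before = 1)

  header <- sprintf("# dusrank %s | seed %s",
                    as.character(utils::packageVersion("dusrank")), seed)
  write_stamped <- function(tbl, file) {
    path <- file.path(out_dir, file)
    writeLines(header, path)
    readr::write_csv(tbl, path, append = TRUE, col_names = TRUE,
                     progress = FALSE)
    path
  }
  paths <- list(
    summary = write_stamped(summary_tbl, "summary.csv"),
    correlation = write_stamped(cor_tbl, "correlation.csv"),
    pca = write_stamped(pca_tbl, "pca.csv"),
    clusters = write_stamped(tidy(clust), "clusters.csv"),
    trend = write_stamped(trend, "trend.csv"),
    ranking = write_stamped(tibble::as_tibble(ranking), "ranking.csv")
  )
  manifest <- list(
    package = "dusrank",
    version = as.character(utils::packageVersion("dusrank")),
    seed = as.integer(seed),
    simulate = simulate,
    effect_size = effect_size,
    n_varieties = nrow(phenotypes),
    n_landrace = sum(phenotypes$group == "landrace"),
    n_cultivated = sum(phenotypes$group == "cultivated"),
    k = as.integer(k),
    test = test,
    score_mode = score_mode,
    weighting = weighting,
    n_selected_components = pca_fit$n_selected,
    cumulative_variance = round(pca_fit$cumulative_variance, 6),
    outputs = vapply(paths, basename, character(1))
  )
  manifest_path <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(manifest, manifest_path)
  invisible(c(paths, manifest = manifest_path))
}
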