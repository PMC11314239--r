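#' Correlation-matrix PCA of the characteristic profile
#'
#' Standardizes each non-monomorphic characteristic to zero mean and unit
#' sample SD, performs an eigendecomposition of the resulting correlation
#' matrix, and selects components by the strict Kaiser rule (eigenvalue
#' > 1). Loadings are reported as eigenvector x sqrt(eigenvalue); because
#' eigenvector signs are arbitrary, each component is oriented so its
#' largest-magnitude loading is positive. Scores are the standardized data
#' projected on the eigenvectors, so per-component score variances equal
#' the eigenvalues.
#'
#' @inheritParams diversity_summary
#' @return An object of class `trait_pca`: a list with `eigenvalues`
#'   (descending), `loadings` (characteristics x components), `scores`
#'   (varieties x components), `n_selected` (Kaiser count),
#'   `cumulative_variance` (fraction of total variance carried by the
#'   selected components), `groups`, `variety_id`, `dropped` (monomorphic
#'   characteristics excluded), and `warnings`. Methods: [tidy()]
#'   (eigenvalues), [glance()], [autoplot()] (PC1/PC2 score plot by group).
#' @examples
#' catalog <- read_catalog(system.file("extdata", "characteristics.csv",
#'                                     package = "dusrank"))
#' cohort <- simulate_cohort(default_cohort_spec(catalog), seed = 1)
#' fit <- pca_traits(cohort)
#' fit$n_selected
#' @export
pca_traits <- function(phenotypes) {
  vals <- trait_columns(phenotypes)
  sds <- vapply(vals, stats::sd, numeric(1))
  dropped <- names(vals)[sds == 0]
  vals <- vals[sds > 0]
  m <- ncol(vals)
  if (m < 2) {
    stop("at least 2 non-constant characteristics are required",
         call. = FALSE)
  }
  warnings <- character(0)
  if (nrow(vals) <= m) {
    warnings <- paste0("n (", nrow(vals), ") does not exceed the number of ",
                       "characteristics (", m, "); trailing eigenvalues are 0")
  }
  z <- scale(as.matrix(vals))
  eig <- eigen(stats::cor(as.matrix(vals)), symmetric = TRUE)
  values <- pmax(eig$values, 0)
  vectors <- eig$vectors
  # orient: largest-|loading| entry of each component positive
  for (j in seq_len(m)) {
    i <- which.max(abs(vectors[, j]))
    if (vectors[i, j] < 0) vectors[, j] <- -vectors[, j]
  }
  scores <- z %*% vectors
  loadings <- vectors %*% diag(sqrt(values), m, m)
  dimnames(loadings) <- list(colnames(vals), paste0("PC", seq_len(m)))
  dimnames(scores) <- list(phenotypes$variety_id, paste0("PC", seq_len(m)))
  n_selected <- sum(values > 1)
  structure(
    list(
      eigenvalues = values,
      loadings = loadings,
      scores = scores,
      n_selected = n_selected,
      cumulative_variance = sum(values[seq_len(n_selected)]) / m,
      groups = phenotypes$group,
      variety_id = phenotypes$variety_id,
      dropped = dropped,
      warnings = warnings
    ),
    class = "trait_pca"
  )
}

#' @export
tidy.trait_pca <- function(x, ...) {
  m <- length(x$eigenvalues)
  tibble::tibble(
    component = paste0("PC", seq_len(m)),
    eigenvalue = x$eigenvalues,
    prop_variance = x$eigenvalues / m,
    cum_variance = cumsum(x$eigenvalues) / m,
    selected = x$eigenvalues > 1
  )
}

#' @export
glance.trait_pca <- function(x, ...) {
  tibble::tibble(
    n_varieties = nrow(x$scores),
    n_characteristics = length(x$eigenvalues),
    n_selected = x$n_selected,
    cumulative_variance = x$cumulative_variance
  )
}

#' @export
print.trait_pca <- function(x, ...) {
  cat("Correlation-matrix PCA of", length(x$eigenvalues),
      "characteristics over", nrow(x$scores), "varieties\n")
  cat(x$n_selected, "components with eigenvalue > 1, explaining",
      sprintf("%.2f%%", 100 * x$cumulative_variance), "of total variance\n")
  if (length(x$dropped) > 0) {
    cat("Dropped monomorphic:", paste(x$dropped, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
autoplot.trait_pca <- function(object, ...) {
  df <- tibble::tibble(
    PC1 = object$scores[, 1],
    PC2 = object$scores[, 2],
    group = object$groups
  )
  pv <- object$eigenvalues / length(object$eigenvalues) * 100
  ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                   colour = .data$group)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::stat_ellipse(level = 0.95) +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", pv[1]),
                  y = sprintf("PC2 (%.1f%%)", pv[2]), colour = NULL) +
    ggplot2::theme_minimal()
}

#' Ward hierarchical clustering of varieties
#'
#' Agglomerative clustering of varieties on their standardized codes
#' (monomorphic characteristics excluded), using Euclidean distance and
#' Ward linkage (`hclust` method `"ward.D2"`), with the tree cut into `k`
#' groups. Clusters are renumbered by decreasing size, ties broken by the
#' first variety (input order) they contain.
#'
#' @inheritParams diversity_summary
#' @param k number of clusters, `1 <= k <= n`. Default 7.
#' @return An object of class `variety_clusters`: a list with `labels`
#'   (a tibble `variety_id`, `group`, `cluster`), `k`, and `tree` (the
#'   `hclust` merge history). [tidy()] returns the labels tibble.
#' @export
cluster_varieties <- function(phenotypes, k = 7) {
  n <- nrow(phenotypes)
  if (k < 1 || k > n) {
    stop("k must lie in 1..", n, call. = FALSE)
  }
  vals <- trait_columns(phenotypes)
  vals <- vals[vapply(vals, stats::sd, numeric(1)) > 0]
  z <- scale(as.matrix(vals))
  rownames(z) <- phenotypes$variety_id
  tree <- stats::hclust(stats::dist(z, method = "euclidean"),
                        method = "ward.D2")
  raw <- stats::cutree(tree, k = k)
  labels <- renumber_clusters(raw)
  structure(
    list(
      labels = tibble::tibble(variety_id = phenotypes$variety_id,
                              group = phenotypes$group,
                              cluster = labels),
      k = as.integer(k),
      tree = tree
    ),
    class = "variety_clusters"
  )
}

# Renumber cluster ids 1..k by decreasing size; ties broken by the first
# member's position in input order.
renumber_clusters <- function(raw) {
  ids <- unique(raw)
  size <- vapply(ids, function(i) sum(raw == i), integer(1))
  first <- vapply(ids, function(i) which(raw == i)[1], integer(1))
  new_order <- ids[order(-size, first)]
  match(raw, new_order)
}

#' @export
tidy.variety_clusters <- function(x, ...) x$labels

#' @export
glance.variety_clusters <- function(x, ...) {
  tibble::tibble(
    n_varieties = nrow(x$labels),
    k = x$k,
    largest_share = max(table(x$labels$cluster)) / nrow(x$labels)
  )
}

#' @export
print.variety_clusters <- function(x, ...) {
  cat("Ward clustering of", nrow(x$labels), "varieties into", x$k,
      "clusters\n")
  print(table(cluster = x$labels$cluster))
  invisible(x)
}

#' Per-cluster size, share and leading characteristics
#'
#' Summarizes a clustering: each cluster's size, its share of all
#' varieties, and the characteristics on which the cluster's mean code is
#' the strict maximum across clusters (ties listed for every tied cluster).
#'
#' @inheritParams diversity_summary
#' @param clusters a `variety_clusters` from [cluster_varieties()], or any
#'   tibble with `variety_id` and `cluster` columns.
#' @return A tibble with columns `cluster`, `size`, `share`,
#'   `top_characteristics` (list-column of characteristic codes).
#' @export
cluster_profile <- function(phenotypes, clusters) {
  if (inherits(clusters, "variety_clusters")) {
    clusters <- clusters$labels
  }
  stopifnot(all(c("variety_id", "cluster") %in% names(clusters)))
  df <- dplyr::inner_join(tibble::as_tibble(phenotypes), clusters,
                          by = "variety_id", suffix = c("", ".cl"))
  if (nrow(df) != nrow(phenotypes)) {
    stop("cluster labels do not cover every variety", call. = FALSE)
  }
  chars <- setdiff(names(trait_columns(phenotypes)), character(0))
  means <- df |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(chars), mean),
                     .groups = "drop")
  mm <- as.matrix(means[chars])
  top <- purrr::map(seq_len(nrow(means)), function(i) {
    chars[mm[i, ] == apply(mm, 2, max)]
  })
  sizes <- df |> dplyr::count(.data$cluster, name = "size")
  dplyr::left_join(sizes, tibble::tibble(cluster = means$cluster,
                                         top_characteristics = top),
                   by = "cluster") |>
    dplyr::mutate(share = .data$size / sum(.data$size),
                  .after = "size") |>
    dplyr::arrange(.data$cluster)
}
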