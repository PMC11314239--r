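millet_catalog <- function() {
  read_catalog(system.file("extdata", "characteristics.csv",
                           package = "dusrank"))
}

planted_increase <- paste0("char", c(1, 6, 12, 15, 17, 26, 28, 29))
planted_decrease <- paste0("char", c(3, 4, 5, 7, 8, 9, 10, 11, 20, 22, 25, 30))

# A small random catalog + valid phenotype table, for round-trip and
# property tests.
random_catalog <- function(n_chars = 5) {
  states <- lapply(seq_len(n_chars), function(i) {
    codes <- sort(sample(1:10, sample(2:6, 1)))
    tibble::tibble(code = codes, label = paste0("state", codes))
  })
  new_catalog(
    char_code = paste0("char", seq_len(n_chars)),
    name = paste("trait", seq_len(n_chars)),
    type = sample(c("QL", "PQ", "QN"), n_chars, replace = TRUE),
    method = sample(c("VS", "VG", "MS", "MG", "MS/MG"), n_chars,
                    replace = TRUE),
    states = states
  )
}

random_phenotypes <- function(catalog, n = 10) {
  cols <- lapply(catalog$char_code, function(cc) {
    sample(allowed_codes(catalog, cc), n, replace = TRUE)
  })
  names(cols) <- catalog$char_code
  tibble::as_tibble(c(
    list(variety_id = sprintf("v%03d", seq_len(n)),
         group = sample(c("landrace", "cultivated"), n, replace = TRUE)),
    cols
  ))
}

# Independent brute-force TOPSIS: explicit double loops over the five-step
# recipe, kept free of the package's vectorized path.
brute_force_topsis <- function(x, orientation, weights) {
  n <- nrow(x)
  m <- ncol(x)
  r <- matrix(0, n, m)
  for (j in seq_len(m)) {
    denom <- sqrt(sum(x[, j]^2))
    for (i in seq_len(n)) r[i, j] <- x[i, j] / denom
  }
  v <- r
  for (j in seq_len(m)) v[, j] <- v[, j] * weights[j]
  a_plus <- numeric(m)
  a_minus <- numeric(m)
  for (j in seq_len(m)) {
    if (orientation[j] == "benefit") {
      a_plus[j] <- max(v[, j]); a_minus[j] <- min(v[, j])
    } else {
      a_plus[j] <- min(v[, j]); a_minus[j] <- max(v[, j])
    }
  }
  d_plus <- d_minus <- numeric(n)
  for (i in seq_len(n)) {
    sp <- sm <- 0
    for (j in seq_len(m)) {
      sp <- sp + (v[i, j] - a_plus[j])^2
      sm <- sm + (v[i, j] - a_minus[j])^2
    }
    d_plus[i] <- sqrt(sp)
    d_minus[i] <- sqrt(sm)
  }
  score <- numeric(n)
  for (i in seq_len(n)) {
    # totally tied decision matrix: the score is defined as 0.5
    score[i] <- if (d_plus[i] + d_minus[i] == 0) {
      0.5
    } else {
      d_minus[i] / (d_plus[i] + d_minus[i])
    }
  }
  list(d_plus = d_plus, d_minus = d_minus, score = score)
}

# Phenotype table wrapping arbitrary integer columns, for statistics tests
# that do not need catalog validation.
as_phenotypes <- function(..., group = NULL) {
  cols <- list(...)
  n <- length(cols[[1]])
  if (is.null(group)) {
    group <- rep(c("landrace", "cultivated"), length.out = n)
  }
  tibble::as_tibble(c(
    list(variety_id = sprintf("v%03d", seq_len(n)), group = group),
    cols
  ))
}
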