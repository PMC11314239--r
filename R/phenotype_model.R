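#' Characteristic catalogs and coded phenotype tables
#'
#' A DUS (Distinctness, Uniformity, Stability) characteristic catalog lists
#' the scored characteristics of a crop guideline: a short code
#' (`char1`, `char2`, ...), a name, an expression type (`QL` qualitative,
#' `PQ` pseudo-quantitative, `QN` quantitative), an observation method
#' (`VS`/`VG` individual/population visual scoring, `MS`/`MG`
#' individual/population measurement, or `MS/MG`), and the ordered list of
#' allowed expression states, each an integer code in 1..10 with a label.
#'
#' A phenotype table holds one row per variety: a unique `variety_id`, a
#' `group` label (`"landrace"` or `"cultivated"`), and one integer column per
#' catalog characteristic whose values must be allowed state codes. Codes are
#' ordinal and are treated as numeric by every downstream statistic.
#'
#' @name dus-data
NULL

.expression_types <- c("QL", "PQ", "QN")
.observation_methods <- c("VS", "VG", "MS", "MG", "MS/MG")
.group_levels <- c("landrace", "cultivated")

#' Build a characteristic catalog from its components
#'
#' Validates and assembles a catalog tibble. Most users will call
#' [read_catalog()] on a CSV instead.
#'
#' @param char_code character vector of unique characteristic codes.
#' @param name characteristic names.
#' @param type expression types, each one of `"QL"`, `"PQ"`, `"QN"`.
#' @param method observation methods, each one of `"VS"`, `"VG"`, `"MS"`,
#'   `"MG"`, `"MS/MG"`.
#' @param states list of tibbles, one per characteristic, with integer
#'   `code` and character `label` columns; codes must be strictly increasing
#'   and lie in 1..10.
#' @return A tibble of class `dus_catalog` with columns `char_code`, `name`,
#'   `type`, `method` and the list-column `states`.
#' @export
new_catalog <- function(char_code, name, type, method, states) {
  cat <- tibble::tibble(
    char_code = as.character(char_code),
    name = as.character(name),
    type = as.character(type),
    method = as.character(method),
    states = states
  )
  validate_catalog(cat)
}

#' @rdname new_catalog
#' @param catalog a candidate catalog tibble.
#' @export
validate_catalog <- function(catalog) {
  stopifnot(is.data.frame(catalog))
  need <- c("char_code", "name", "type", "method", "states")
  miss <- setdiff(need, names(catalog))
  if (length(miss) > 0) {
    stop("catalog is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  dup <- catalog$char_code[duplicated(catalog$char_code)]
  if (length(dup) > 0) {
    stop("duplicate char_code in catalog: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  bad_type <- which(!catalog$type %in% .expression_types)
  if (length(bad_type) > 0) {
    stop("row ", bad_type[1], " (", catalog$char_code[bad_type[1]],
         "): unknown expression type '", catalog$type[bad_type[1]], "'",
         call. = FALSE)
  }
  bad_method <- which(!catalog$method %in% .observation_methods)
  if (length(bad_method) > 0) {
    stop("row ", bad_method[1], " (", catalog$char_code[bad_method[1]],
         "): unknown observation method '", catalog$method[bad_method[1]], "'",
         call. = FALSE)
  }
  for (i in seq_len(nrow(catalog))) {
    st <- catalog$states[[i]]
    if (!is.data.frame(st) || !all(c("code", "label") %in% names(st)) ||
        nrow(st) < 1) {
      stop("row ", i, " (", catalog$char_code[i],
           "): states must be a table with >= 1 (code, label) row",
           call. = FALSE)
    }
    codes <- st$code
    if (any(codes != as.integer(codes)) || any(codes < 1) || any(codes > 10)) {
      stop("row ", i, " (", catalog$char_code[i],
           "): state codes must be integers in 1..10", call. = FALSE)
    }
    if (nrow(st) > 1 && any(diff(codes) <= 0)) {
      stop("row ", i, " (", catalog$char_code[i],
           "): state codes must be strictly increasing", call. = FALSE)
    }
  }
  class(catalog) <- unique(c("dus_catalog", class(tibble::as_tibble(catalog))))
  catalog
}

parse_states <- function(string, row_label) {
  parts <- strsplit(string, ";", fixed = TRUE)[[1]]
  parts <- trimws(parts)
  parts <- parts[nzchar(parts)]
  if (length(parts) == 0) {
    stop(row_label, ": empty states string", call. = FALSE)
  }
  m <- regmatches(parts, regexec("^(.*)\\(([0-9]+)\\)$", parts))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) {
    stop(row_label, ": malformed state entry '", parts[which(bad)[1]],
         "' (expected \"label(code)\")", call. = FALSE)
  }
  tibble::tibble(
    code = vapply(m, function(x) as.integer(x[3]), integer(1)),
    label = trimws(vapply(m, function(x) x[2], character(1)))
  )
}

#' Read a characteristic catalog from CSV
#'
#' The CSV must have the header `char_code,name,type,method,states`, with the
#' allowed states of each characteristic encoded as
#' `"label(code);label(code);..."` (e.g. `"waxy(1);non-waxy(2)"`). Row order
#' is preserved. The 32-characteristic foxtail millet guideline shipped with
#' the package is at `system.file("extdata", "characteristics.csv",
#' package = "dusrank")`.
#'
#' @param path path to the catalog CSV.
#' @return A validated `dus_catalog` tibble (see [new_catalog()]).
#' @examples
#' catalog <- read_catalog(system.file("extdata", "characteristics.csv",
#'                                     package = "dusrank"))
#' nrow(catalog)
#' @export
read_catalog <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  need <- c("char_code", "name", "type", "method", "states")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    stop("catalog CSV is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  states <- purrr::map2(raw$states, seq_len(nrow(raw)), function(s, i) {
    parse_states(s, paste0("row ", i, " (", raw$char_code[i], ")"))
  })
  new_catalog(raw$char_code, raw$name, raw$type, raw$method, states)
}

#' Codes allowed for one characteristic
#'
#' @param catalog a `dus_catalog`.
#' @param char_code one characteristic code.
#' @return Integer vector of allowed state codes, in increasing order.
#' @export
allowed_codes <- function(catalog, char_code) {
  i <- match(char_code, catalog$char_code)
  if (is.na(i)) {
    stop("unknown characteristic: ", char_code, call. = FALSE)
  }
  catalog$states[[i]]$code
}

#' Validate a coded phenotype table against a catalog
#'
#' Checks the contract every pipeline stage assumes: unique variety ids,
#' a `landrace`/`cultivated` group label for every variety, one column per
#' catalog characteristic (reordered to catalog order if needed), no missing
#' cells, and every value an allowed state code of its characteristic.
#'
#' @param phenotypes a data frame with columns `variety_id`, `group`, and one
#'   integer column per catalog characteristic.
#' @param catalog a `dus_catalog`.
#' @return The validated phenotype tibble, characteristic columns in catalog
#'   order.
#' @export
validate_phenotypes <- function(phenotypes, catalog) {
  stopifnot(is.data.frame(phenotypes))
  phenotypes <- tibble::as_tibble(phenotypes)
  miss <- setdiff(c("variety_id", "group"), names(phenotypes))
  if (length(miss) > 0) {
    stop("phenotype table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  missing_chars <- setdiff(catalog$char_code, names(phenotypes))
  if (length(missing_chars) > 0) {
    stop("phenotype table is missing characteristic column(s): ",
         paste(missing_chars, collapse = ", "), call. = FALSE)
  }
  phenotypes <- phenotypes[, c("variety_id", "group", catalog$char_code)]
  phenotypes$variety_id <- as.character(phenotypes$variety_id)
  phenotypes$group <- as.character(phenotypes$group)
  dup <- phenotypes$variety_id[duplicated(phenotypes$variety_id)]
  if (length(dup) > 0) {
    stop("duplicate variety_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  bad_group <- which(is.na(phenotypes$group) |
                       !phenotypes$group %in% .group_levels)
  if (length(bad_group) > 0) {
    stop("variety '", phenotypes$variety_id[bad_group[1]],
         "': group must be one of ", paste(.group_levels, collapse = ", "),
         call. = FALSE)
  }
  for (cc in catalog$char_code) {
    v <- phenotypes[[cc]]
    if (any(is.na(v))) {
      stop("variety '", phenotypes$variety_id[which(is.na(v))[1]],
           "', characteristic ", cc, ": missing value", call. = FALSE)
    }
    if (!is.numeric(v) || any(v != as.integer(v))) {
      stop("characteristic ", cc, ": codes must be integers", call. = FALSE)
    }
    ok <- v %in% allowed_codes(catalog, cc)
    if (!all(ok)) {
      i <- which(!ok)[1]
      stop("variety '", phenotypes$variety_id[i], "', characteristic ", cc,
           ": code ", v[i], " is not an allowed state (allowed: ",
           paste(allowed_codes(catalog, cc), collapse = ", "), ")",
           call. = FALSE)
    }
    phenotypes[[cc]] <- as.integer(v)
  }
  phenotypes
}

#' Read a coded phenotype table from CSV
#'
#' The CSV must have the header `variety_id,group,char1,...,charN`;
#' characteristic columns are matched to the catalog by name, not position.
#' Lines starting with `#` are treated as comments and skipped.
#'
#' @inheritParams validate_phenotypes
#' @param path path to the phenotypes CSV.
#' @return A validated phenotype tibble (see [validate_phenotypes()]).
#' @export
read_phenotypes <- function(path, catalog) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    variety_id = "c", group = "c", .default = "d"
  ), comment = "#", progress = FALSE)
  validate_phenotypes(raw, catalog)
}

#' Write a coded phenotype table to CSV
#'
#' Writes comma-separated UTF-8 with a header and no quoting of numeric
#' cells; the output is read back unchanged by [read_phenotypes()] and is
#' bit-identical under re-write.
#'
#' @param phenotypes a validated phenotype tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(phenotypes, path) {
  readr::write_csv(phenotypes, path, progress = FALSE)
  invisible(path)
}
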