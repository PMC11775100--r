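#' @title Reading and writing the pipeline's tables
#' @description Delimited-text readers for the four input tables (study-center
#'   creatinine, eMR creatinine, diagnostic events, baseline covariates), a
#'   configurable read-code-to-category mapping, and a writer that emits every
#'   pipeline output with a run manifest. All tables are UTF-8 delimited text
#'   (TSV by default, CSV accepted by file extension) with a header row and
#'   ISO-8601 dates.
#' @name records_io
NULL

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("Required column%s %s missing from %s.",
                  if (length(missing) > 1) "s" else "",
                  paste0("`", missing, "`", collapse = ", "), what))
  }
  invisible(df)
}

read_table_file <- function(path) {
  if (!file.exists(path)) abort(sprintf("File `%s` does not exist.", path))
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
}

parse_iso_date <- function(x, file, allow_missing = FALSE) {
  blank <- is.na(x) | trimws(x) == ""
  parsed <- as.Date(rep(NA_character_, length(x)))
  parsed[!blank] <- as.Date(x[!blank], format = "%Y-%m-%d")
  bad <- !blank & is.na(parsed)
  if (any(bad)) {
    abort(sprintf("Unparseable date `%s` at row %d of %s (expected ISO 8601).",
                  x[which(bad)[1]], which(bad)[1], file))
  }
  if (!allow_missing && any(blank)) {
    abort(sprintf("Missing date at row %d of %s.", which(blank)[1], file))
  }
  parsed
}

#' Default technical-error predicate for raw creatinine rows
#'
#' Flags rows that cannot represent a valid measurement: non-numeric or
#' non-positive values, or a missing measurement date. Supply your own
#' function of the raw tibble (returning a logical vector) to change what
#' counts as a technical error.
#'
#' @param df Raw tibble with character `value` and parsed `exam_date`.
#' @return Logical vector, `TRUE` = technical error.
#' @export
default_technical_error <- function(df) {
  value_num <- suppressWarnings(as.numeric(df$value))
  is.na(value_num) | value_num <= 0 | is.na(df$exam_date)
}

#' Read a creatinine table
#'
#' Reads a delimited table with columns `person_id`, `exam_date` (ISO 8601)
#' and `value` (µmol/L). Rows failing the technical-error predicate are kept
#' with `qc_status = "excluded_nonnumeric"`; all others start as `"raw"`
#' (study-center records, measured centrally under one protocol, are marked
#' `"pass"` directly).
#'
#' @param path File path (TSV, or CSV by extension).
#' @param source `"SC"` or `"eMR"`.
#' @param technical_error Predicate function, see [default_technical_error()].
#' @param date_range Plausible exam-date range; rows outside it are technical
#'   errors.
#' @return Tibble: `person_id`, `exam_date`, `value`, `source`, `qc_status`,
#'   and `read_code` when present in the file.
#' @export
read_creatinine <- function(path, source = c("eMR", "SC"),
                            technical_error = default_technical_error,
                            date_range = as.Date(c("1900-01-01", "2030-12-31"))) {
  source <- match.arg(source)
  raw <- read_table_file(path)
  require_columns(raw, c("person_id", "exam_date", "value"),
                  sprintf("file `%s`", path))
  raw$exam_date <- parse_iso_date(raw$exam_date, path, allow_missing = TRUE)
  out_of_range <- !is.na(raw$exam_date) &
    (raw$exam_date < date_range[1] | raw$exam_date > date_range[2])
  tech <- technical_error(raw) | out_of_range
  value_num <- suppressWarnings(as.numeric(raw$value))
  initial_status <- if (source == "SC") "pass" else "raw"
  out <- tibble::tibble(
    person_id = raw$person_id,
    exam_date = raw$exam_date,
    value = value_num,
    source = source,
    qc_status = ifelse(tech, "excluded_nonnumeric", initial_status)
  )
  if ("read_code" %in% names(raw)) out$read_code <- raw$read_code
  out
}

#' The illustrative read-code list shipped with the package
#'
#' A small demonstration mapping of read-code-style strings to kidney-relevant
#' event categories. Real analyses substitute their own code list (e.g. the
#' full Read v2 / CTV3 selections for AKI, ESKD, nephrectomy, dialysis,
#' transplant, pregnancy and diabetes) via [read_codelist()].
#'
#' @return Tibble with columns `raw_code`, `category`.
#' @export
default_codelist <- function() {
  read_codelist(system.file("extdata", "codelist_demo.tsv",
                            package = "egfrtraj", mustWork = TRUE))
}

EVENT_CATEGORIES <- c("AKI", "ESKD", "transplant", "dialysis", "nephrectomy",
                      "pregnancy", "diabetes")

#' Read a code-list mapping file
#'
#' @param path Delimited file with columns `raw_code`, `category`.
#' @return Tibble `raw_code`, `category`; categories outside the recognized
#'   set raise an error.
#' @export
read_codelist <- function(path) {
  cl <- read_table_file(path)
  require_columns(cl, c("raw_code", "category"), sprintf("file `%s`", path))
  bad <- setdiff(unique(cl$category), EVENT_CATEGORIES)
  if (length(bad) > 0) {
    abort(sprintf("Unknown event categor%s: %s.",
                  if (length(bad) > 1) "ies" else "y",
                  paste(bad, collapse = ", ")))
  }
  tibble::tibble(raw_code = cl$raw_code, category = cl$category)
}

#' Read and categorize a diagnostic-event table
#'
#' Maps raw read codes to event categories through the supplied code list.
#' Rows whose code is absent from the list are dropped (a count is reported);
#' duplicated (person, date, category) events are collapsed to one.
#' Categorization is a pure function of (raw code, code list).
#'
#' @param path Delimited file with columns `person_id`, `event_date`, `code`.
#' @param codelist Tibble from [read_codelist()] / [default_codelist()].
#' @return Tibble: `person_id`, `event_date`, `category`, `raw_code`.
#' @export
read_events <- function(path, codelist = default_codelist()) {
  raw <- read_table_file(path)
  require_columns(raw, c("person_id", "event_date", "code"),
                  sprintf("file `%s`", path))
  if (nrow(raw) == 0) {
    return(tibble::tibble(person_id = character(), event_date = as.Date(character()),
                          category = character(), raw_code = character()))
  }
  raw$event_date <- parse_iso_date(raw$event_date, path)
  mapped <- dplyr::inner_join(raw, codelist, by = c(code = "raw_code"))
  n_unmapped <- nrow(raw) - nrow(mapped)
  if (n_unmapped > 0) {
    inform(sprintf("Dropped %d event row%s with codes absent from the code list.",
                   n_unmapped, if (n_unmapped > 1) "s" else ""))
  }
  mapped |>
    dplyr::transmute(.data$person_id, event_date = .data$event_date,
                     .data$category, raw_code = .data$code) |>
    dplyr::distinct(.data$person_id, .data$event_date, .data$category,
                    .keep_all = TRUE) |>
    dplyr::arrange(.data$person_id, .data$event_date)
}

#' Read the baseline covariate table
#'
#' @param path Delimited file; required columns `person_id`, `sex` (0 female /
#'   1 male), `birth_year`, `birth_month`; optional `smoking` (0 never /
#'   1 ever), `bmi` (kg/m^2), `diabetes` (0/1), `variant_dosage` (allele
#'   dosage in \[0, 2\] of the decline-associated variant).
#' @return Typed tibble.
#' @export
read_covariates <- function(path) {
  raw <- read_table_file(path)
  require_columns(raw, c("person_id", "sex", "birth_year", "birth_month"),
                  sprintf("file `%s`", path))
  num <- function(col) suppressWarnings(as.numeric(raw[[col]]))
  out <- tibble::tibble(
    person_id = raw$person_id,
    sex = normalize_sex(raw$sex),
    birth_year = as.integer(raw$birth_year),
    birth_month = as.integer(raw$birth_month)
  )
  for (col in c("smoking", "bmi", "diabetes", "variant_dosage")) {
    out[[col]] <- if (col %in% names(raw)) num(col) else NA_real_
  }
  if (any(out$bmi <= 0, na.rm = TRUE)) abort("`bmi` must be positive when present.")
  if (any(out$variant_dosage < 0 | out$variant_dosage > 2, na.rm = TRUE)) {
    abort("`variant_dosage` must lie in [0, 2].")
  }
  out
}

#' Write pipeline outputs with a run manifest
#'
#' Writes every element of `results` (a named list of data frames) as a TSV
#' under `out_dir`, plus a `run_metadata.tsv` recording the seed, a hash of
#' the configuration, and the package version. Re-running with the same
#' inputs produces byte-identical files.
#'
#' @param results Named list of data frames.
#' @param out_dir Output directory (created if absent).
#' @param seed Integer seed recorded in the metadata.
#' @param config Configuration object hashed into the metadata.
#' @return Tibble manifest: `file`, `rows`, `path`.
#' @export
write_outputs <- function(results, out_dir, seed = NA_integer_, config = NULL) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("Cannot create output directory `%s`.", out_dir))
  }
  if (file.access(out_dir, 2) != 0) {
    abort(sprintf("Output directory `%s` is not writable.", out_dir))
  }
  stopifnot(is.list(results), !is.null(names(results)))
  manifest <- purrr::imap(results, function(df, name) {
    path <- file.path(out_dir, paste0(name, ".tsv"))
    readr::write_tsv(as.data.frame(df), path, progress = FALSE)
    tibble::tibble(file = paste0(name, ".tsv"), rows = nrow(df), path = path)
  }) |> purrr::list_rbind()
  meta <- tibble::tibble(
    key = c("seed", "config_hash", "package_version", "n_outputs"),
    value = c(as.character(seed),
              if (is.null(config)) NA_character_ else rlang::hash(config),
              as.character(utils::packageVersion("egfrtraj")),
              as.character(nrow(manifest)))
  )
  meta_path <- file.path(out_dir, "run_metadata.tsv")
  readr::write_tsv(meta, meta_path, progress = FALSE)
  dplyr::bind_rows(manifest,
                   tibble::tibble(file = "run_metadata.tsv", rows = nrow(meta),
                                  path = meta_path))
}
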