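#' Quality-control configuration for raw eMR creatinine
#'
#' @param lod Limit of detection, µmol/L: values strictly below are excluded.
#' @param loq Limit of quantification, µmol/L: values below (but at/above the
#'   LOD) are set to the LoQ. Defaults are lab-specific placeholders.
#' @param max_value Upper plausibility bound, µmol/L; values above it are
#'   excluded (default 6524, the highest credible recorded creatinine).
#' @param duplicate_key Columns defining a duplicate record; the first
#'   occurrence in stable input order is kept. Same-day differing values are
#'   both kept (plausibly distinct draws).
#' @return A `qc_config` list.
#' @export
qc_config <- function(lod = 18, loq = 18, max_value = 6524,
                      duplicate_key = c("person_id", "exam_date", "value")) {
  if (!(lod > 0 && lod <= loq && loq < max_value)) {
    abort("Require 0 < lod <= loq < max_value.")
  }
  structure(list(lod = lod, loq = loq, max_value = max_value,
                 duplicate_key = duplicate_key),
            class = "qc_config")
}

#' Quality-control raw eMR creatinine records
#'
#' Assigns each record exactly one final QC status, in order of precedence:
#' already-flagged technical errors stay `excluded_nonnumeric`; values above
#' `max_value` become `excluded_above_max`; values strictly below the LOD
#' become `excluded_below_lod`; duplicates (same `duplicate_key`) beyond the
#' first occurrence become `excluded_duplicate`; values below the LoQ are
#' floored to the LoQ (`floored_to_loq`); everything else is `pass`.
#' Study-center records bypass QC and pass unchanged. The status counts
#' partition the input: `sum(report$n) == nrow(records)`.
#'
#' @param records Creatinine tibble from [read_creatinine()].
#' @param config A [qc_config()].
#' @return List with `records` (all rows, final `qc_status`; floored rows have
#'   `value` set to the LoQ) and `report` (tibble `qc_status`, `n`). Use
#'   [qc_passed()] to keep analysable rows.
#' @export
qc_emr_creatinine <- function(records, config = qc_config()) {
  require_columns(records, c("person_id", "exam_date", "value", "source",
                             "qc_status"), "records")
  rec <- records
  sc <- rec$source == "SC"
  status <- rec$qc_status
  status[sc & status == "raw"] <- "pass"
  open <- !sc & status %in% c("raw", "pass", "floored_to_loq")
  status[open] <- "raw"

  above <- open & rec$value > config$max_value
  status[above] <- "excluded_above_max"
  open <- open & !above

  below <- open & rec$value < config$lod
  status[below] <- "excluded_below_lod"
  open <- open & !below

  key <- do.call(paste, c(lapply(config$duplicate_key, function(k) rec[[k]]),
                          sep = "\r"))
  key[!open] <- paste0("\x01", which(!open))  # excluded rows never form pairs
  dup <- open & duplicated(key)
  status[dup] <- "excluded_duplicate"
  open <- open & !dup

  floor <- open & rec$value < config$loq
  rec$value[floor] <- config$loq
  status[floor] <- "floored_to_loq"
  status[open & !floor] <- "pass"

  rec$qc_status <- status
  report <- rec |>
    dplyr::count(.data$qc_status, name = "n") |>
    dplyr::arrange(.data$qc_status)
  list(records = rec, report = report)
}

#' Keep QC-passed creatinine records
#'
#' @param records Records tibble with a `qc_status` column.
#' @return Rows with status `pass` or `floored_to_loq` (the analysable set).
#' @export
qc_passed <- function(records) {
  dplyr::filter(records, .data$qc_status %in% c("pass", "floored_to_loq"))
}
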