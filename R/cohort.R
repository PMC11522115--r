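#' Pulmonary vein labels and ERC status levels
#'
#' The four standard pulmonary veins and the recognised early-reconnection /
#' dormant-conduction (ERC) outcome categories. A vein is ERC-positive when it
#' reconnected during the 30-minute waiting period before adenosine, or showed
#' dormant conduction under adenosine.
#'
#' @format Character vectors of allowed values.
#' @name vein-vocabulary
NULL

#' @rdname vein-vocabulary
#' @export
pv_labels <- c("LSPV", "LIPV", "RIPV", "RSPV")

#' @rdname vein-vocabulary
#' @export
erc_status_levels <- c("none", "reconnection_pre_adenosine",
                       "dormant_with_adenosine", "untested")

#' Is a vein ERC-positive?
#'
#' Maps an `erc_status` value to the binary outcome used by the prediction
#' model: reconnection before adenosine and dormant conduction with adenosine
#' both count as ERC. Veins never tested (`"untested"`) are treated as
#' negative, mirroring how untested veins enter a validation analysis when no
#' adenosine challenge was performed.
#'
#' @param status Character vector of `erc_status` values.
#' @return Logical vector, `NA` where `status` is `NA`.
#' @export
#' @examples
#' erc_positive(c("none", "dormant_with_adenosine", "untested"))
erc_positive <- function(status) {
  bad <- !is.na(status) & !status %in% erc_status_levels
  if (any(bad)) {
    abort(paste0("unknown erc_status value(s): ",
                 paste(unique(status[bad]), collapse = ", ")))
  }
  ifelse(is.na(status), NA,
         status %in% c("reconnection_pre_adenosine", "dormant_with_adenosine"))
}

# Validate/coerce a vein table; used by the reader and exported for
# programmatically built tables.
#' Validate a vein-level table
#'
#' Checks the invariants of the vein-level record: known vein labels, unique
#' (patient, vein) pairs, non-negative finite `tti_s` and `n_unsuccessful`,
#' known `erc_status` values. Missing values are permitted everywhere except
#' `patient_id` and `vein`.
#'
#' @param veins Data frame with columns `patient_id`, `vein`, and optionally
#'   `tti_s`, `n_unsuccessful`, `nadir_temp_c`, `erc_status`, `n_bonus`.
#' @return The validated table as a tibble, with absent optional columns
#'   added as `NA`.
#' @export
validate_vein_table <- function(veins) {
  veins <- as_tibble(veins)
  for (col in c("patient_id", "vein")) {
    if (!col %in% names(veins)) abort(paste0("column '", col, "' is required"))
  }
  optional <- c(tti_s = NA_real_, n_unsuccessful = NA_real_,
                nadir_temp_c = NA_real_, erc_status = NA_character_,
                n_bonus = NA_real_)
  for (col in names(optional)) {
    if (!col %in% names(veins)) veins[[col]] <- optional[[col]]
  }
  if (anyNA(veins$patient_id) || anyNA(veins$vein)) {
    abort("patient_id and vein must not be missing")
  }
  bad_vein <- !veins$vein %in% pv_labels
  if (any(bad_vein)) {
    abort(paste0("unknown vein label(s): ",
                 paste(unique(veins$vein[bad_vein]), collapse = ", "),
                 " (expected LSPV/LIPV/RIPV/RSPV)"))
  }
  key <- paste(veins$patient_id, veins$vein)
  if (anyDuplicated(key)) {
    abort(paste0("duplicated (patient, vein) pair(s): ",
                 paste(unique(key[duplicated(key)]), collapse = ", ")))
  }
  for (col in c("tti_s", "n_unsuccessful", "nadir_temp_c", "n_bonus")) {
    veins[[col]] <- as.numeric(veins[[col]])
  }
  with_val <- !is.na(veins$tti_s)
  if (any(with_val & (veins$tti_s < 0 | !is.finite(veins$tti_s)))) {
    abort("tti_s must be finite and >= 0 where present")
  }
  with_u <- !is.na(veins$n_unsuccessful)
  if (any(with_u & (veins$n_unsuccessful < 0 |
                    veins$n_unsuccessful != round(veins$n_unsuccessful)))) {
    abort("n_unsuccessful must be a non-negative integer where present")
  }
  bad_status <- !is.na(veins$erc_status) &
    !veins$erc_status %in% erc_status_levels
  if (any(bad_status)) {
    abort(paste0("unknown erc_status value(s): ",
                 paste(unique(veins$erc_status[bad_status]), collapse = ", ")))
  }
  veins
}

#' Read a vein-level table
#'
#' Reads a delimited vein-level table with one row per pulmonary vein.
#' Expected columns: `patient_id`, `vein` (one of LSPV/LIPV/RIPV/RSPV),
#' `tti_s` (time to isolation, s), `n_unsuccessful` (unsuccessful
#' cryo-applications), `nadir_temp_c` (nadir balloon temperature, deg C),
#' `erc_status`, `n_bonus`. Empty cells become missing values; sentinel
#' numerics are never interpreted as missing.
#'
#' Rows with an unknown vein label, an unknown ERC status, or an unparsable
#' numeric cell are rejected with a warning naming the row. Duplicated
#' (patient, vein) pairs are an error, since vein labels are unique within a
#' patient.
#'
#' @param path Path to the delimited file.
#' @param delim Field delimiter, `","` by default; `"\t"` is also common.
#' @return A validated tibble of vein records (see [validate_vein_table()]).
#' @seealso [write_vein_table()], [filter_complete_veins()]
#' @export
read_vein_table <- function(path, delim = ",") {
  raw <- readr::read_delim(path, delim = delim,
                           col_types = readr::cols(.default = readr::col_character()),
                           na = c(""), trim_ws = TRUE, progress = FALSE)
  for (col in c("patient_id", "vein")) {
    if (!col %in% names(raw)) abort(paste0("column '", col, "' is required in ", path))
  }
  numeric_cols <- intersect(c("tti_s", "n_unsuccessful", "nadir_temp_c", "n_bonus"),
                            names(raw))
  reject <- rep(FALSE, nrow(raw))
  reasons <- rep(NA_character_, nrow(raw))
  flag <- function(bad, why) {
    newly <- bad & !reject
    reasons[newly] <<- why
    reject <<- reject | bad
  }
  flag(is.na(raw$patient_id) | is.na(raw$vein), "missing patient_id or vein")
  flag(!is.na(raw$vein) & !raw$vein %in% pv_labels, "unknown vein label")
  if ("erc_status" %in% names(raw)) {
    flag(!is.na(raw$erc_status) & !raw$erc_status %in% erc_status_levels,
         "unknown erc_status")
  }
  parsed <- list()
  for (col in numeric_cols) {
    x <- suppressWarnings(as.numeric(raw[[col]]))
    flag(!is.na(raw[[col]]) & is.na(x), paste0("unparsable numeric in ", col))
    parsed[[col]] <- x
  }
  if (any(reject)) {
    warn(paste0("rejected ", sum(reject), " row(s) of ", path, ": ",
                paste0("row ", which(reject), " (", reasons[reject], ")",
                       collapse = "; ")))
  }
  out <- raw[!reject, , drop = FALSE]
  for (col in numeric_cols) out[[col]] <- parsed[[col]][!reject]
  validate_vein_table(out)
}

#' Write a vein-level table
#'
#' Inverse of [read_vein_table()]: missing values are written as empty cells
#' so that a write/read round trip reproduces all fields and missingness
#' exactly.
#'
#' @param veins A vein table (validated on the way out).
#' @param path Output path.
#' @param delim Field delimiter.
#' @return `veins`, invisibly.
#' @export
write_vein_table <- function(veins, path, delim = ",") {
  veins <- validate_vein_table(veins)
  readr::write_delim(veins, path, delim = delim, na = "")
  invisible(veins)
}

#' Keep veins with complete model data
#'
#' The prediction model needs all three predictors: time to isolation, number
#' of unsuccessful applications, and nadir balloon temperature. This filter
#' keeps exactly the veins where all three are present, optionally also
#' requiring an adenosine-tested ERC outcome, and reports how many veins were
#' retained and dropped.
#'
#' @param veins A vein table.
#' @param require_tested If `TRUE`, additionally drop veins with
#'   `erc_status == "untested"`. The default `FALSE` matches a validation
#'   analysis in which untested veins are retained as ERC-negative.
#' @param quiet Suppress the retained/dropped message.
#' @return Tibble of the retained vein records. Idempotent: filtering twice
#'   changes nothing.
#' @export
filter_complete_veins <- function(veins, require_tested = FALSE, quiet = FALSE) {
  veins <- validate_vein_table(veins)
  keep <- !is.na(veins$tti_s) & !is.na(veins$n_unsuccessful) &
    !is.na(veins$nadir_temp_c)
  if (require_tested) {
    keep <- keep & !is.na(veins$erc_status) & veins$erc_status != "untested"
  }
  if (!quiet) {
    inform(paste0("filter_complete_veins: retained ", sum(keep), " of ",
                  nrow(veins), " veins (dropped ", sum(!keep), ")"))
  }
  veins[keep, , drop = FALSE]
}

#' Patient-level ERC status
#'
#' Aggregates vein-level outcomes: a patient is ERC-positive iff any of their
#' veins reconnected before adenosine or showed dormant conduction with
#' adenosine.
#'
#' @param veins A vein table.
#' @return Tibble with one row per patient: `patient_id`, `n_veins`,
#'   `n_erc_veins`, `erc_patient`.
#' @export
patient_erc <- function(veins) {
  veins <- validate_vein_table(veins)
  veins |>
    mutate(.erc = erc_positive(.data$erc_status) %in% TRUE) |>
    group_by(.data$patient_id) |>
    summarise(n_veins = n(),
              n_erc_veins = sum(.data$.erc),
              erc_patient = any(.data$.erc),
              .groups = "drop")
}
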