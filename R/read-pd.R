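# Reader for Proteome-Discoverer-style precursor-area exports.

PD_COLUMNS <- list(
  first_scan = c("First Scan", "FirstScan", "First scan"),
  area       = c("Area", "Precursor Area")
)

#' Read a precursor-area export and index areas by scan number
#'
#' Parses a delimited export with "First Scan" and "Area" columns (synonyms
#' accepted). Blank, `"n/a"` and zero areas are treated as absent (the
#' exporter writes 0 for failed integrations), so every stored area is
#' strictly positive. Several rows for one scan collapse to the maximum area,
#' mirroring the highest-area preference used downstream and avoiding double
#' counting one precursor.
#'
#' @param path Path to the export (CSV or TSV).
#' @return A tibble with columns `scan` (integer, unique) and `area`
#'   (positive numeric).
#' @export
read_pd_areas <- function(path) {
  df <- readr::read_delim(path, delim = .sniff_delim(path),
                          show_col_types = FALSE, progress = FALSE,
                          col_types = readr::cols(.default = "c"))
  cols <- .resolve_columns(names(df), PD_COLUMNS,
                           required = c("first_scan", "area"), path = path)
  if (nrow(df) == 0) {
    return(tibble(scan = integer(0), area = numeric(0)))
  }
  area_text <- trimws(df[[cols$area]])
  area <- suppressWarnings(as.numeric(area_text))
  area[!is.na(area_text) & tolower(area_text) %in% c("n/a", "na", "")] <- NA
  scan <- extract_scan_number(df[[cols$first_scan]])
  tibble(scan = scan, area = area) |>
    filter(!is.na(.data$area), .data$area > 0) |>
    group_by(.data$scan) |>
    summarise(area = max(.data$area), .groups = "drop")
}
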