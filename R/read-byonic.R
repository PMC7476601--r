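# Reader for Byonic-style identification exports.
#
# Header-driven with a synonym table, CSV or TSV. Rows are parsed into PSM
# records; decoy ("Reverse") and contaminant entries are removed before any
# grouping, and the UniProtKB accession is extracted into a master id that
# collapses isoform entries.

# Published UniProtKB accession pattern. Isoform suffixes ("-2") are not part
# of the match, so isoforms collapse to one master id.
UNIPROT_ACCESSION_REGEX <-
  "[OPQ][0-9][A-Z0-9]{3}[0-9]|[A-NR-Z][0-9](?:[A-Z][A-Z0-9]{2}[0-9]){1,2}"

BYONIC_COLUMNS <- list(
  protein_name = c("Protein Name", "Protein name"),
  scan         = c("Scan number", "Scan #", "Scan Number", "Scan"),
  peptide      = c("Peptide"),
  glycans      = c("Glycans NHFAGNa", "Glycans"),
  mod_types    = c("Modification Type(s)", "Modification Types"),
  score        = c("Score"),
  calc_mz      = c("Calc. m/z", "Calc. mass (m/z)", "Calc mz"),
  start        = c("Starting position", "Start position", "Starting Position")
)

#' Extract a UniProtKB accession from a protein name
#'
#' Returns the first substring matching the published UniProtKB accession
#' pattern; when no accession matches, the entire protein name is returned, so
#' the operation is total and idempotent.
#'
#' @param protein_name Character vector of protein names.
#' @return Character vector of master ids.
#' @export
#' @examples
#' extract_accession("sp|P01857|IGHG1_HUMAN Immunoglobulin heavy constant gamma 1")
extract_accession <- function(protein_name) {
  hit <- stringr::str_extract(protein_name, UNIPROT_ACCESSION_REGEX)
  ifelse(is.na(hit), protein_name, hit)
}

#' Is a protein entry a decoy or contaminant?
#'
#' Decoys are recognised by the Byonic `">Reverse"` tag (a leading "Reverse"
#' marker, case-insensitive); contaminants by a configurable marker list
#' matched case-insensitively anywhere in the name.
#'
#' @param protein_name Character vector.
#' @param contaminant_markers Character vector of contaminant marker
#'   substrings.
#' @return Logical vector.
#' @export
is_excluded_protein <- function(protein_name,
                                contaminant_markers = "Common contaminant") {
  decoy <- stringr::str_detect(
    protein_name, stringr::regex("^>?\\s*Reverse\\b", ignore_case = TRUE))
  contam <- rep(FALSE, length(protein_name))
  for (marker in contaminant_markers) {
    contam <- contam | stringr::str_detect(
      protein_name, stringr::fixed(marker, ignore_case = TRUE))
  }
  decoy | contam
}

#' Extract the numeric MS2 scan number
#'
#' Accepts plain integers (`"12345"`), labelled forms (`"Scan 12345"`) and the
#' dotted spectrum-title dialect (`"file.12345.12345.2"`, where the scan field
#' is the repeated integer, i.e. the penultimate dotted field).
#'
#' @param scan_text Character vector.
#' @return Integer vector; an element with no parseable scan raises an error
#'   naming the offending text.
#' @export
extract_scan_number <- function(scan_text) {
  one <- function(x) {
    x <- trimws(as.character(x))
    if (grepl("^[0-9]+$", x)) return(as.integer(x))
    m <- stringr::str_match(x, "\\.([0-9]+)\\.([0-9]+)\\.([0-9]+)$")
    if (!is.na(m[1, 1])) return(as.integer(m[1, 3]))
    m <- stringr::str_match(x, stringr::regex("scan[ #:]*([0-9]+)",
                                              ignore_case = TRUE))
    if (!is.na(m[1, 1])) return(as.integer(m[1, 2]))
    ints <- stringr::str_extract_all(x, "[0-9]+")[[1]]
    if (length(ints) == 1) return(as.integer(ints))
    abort(sprintf("Cannot extract a scan number from \"%s\"", x),
          class = "glycoquant_parse_error")
  }
  vapply(scan_text, one, integer(1), USE.NAMES = FALSE)
}

# Sniff the delimiter of a delimited text file from its header line.
.sniff_delim <- function(path) {
  header <- readLines(path, n = 1L, warn = FALSE)
  if (length(header) == 0) return(",")
  if (stringr::str_count(header, "\t") >= stringr::str_count(header, ","))
    "\t" else ","
}

# Resolve spec -> actual column names through the synonym table; required
# columns missing raise a configuration error naming the file.
.resolve_columns <- function(found, synonyms, required, path) {
  out <- list()
  for (key in names(synonyms)) {
    hit <- intersect(synonyms[[key]], found)
    if (length(hit)) {
      out[[key]] <- hit[[1]]
    } else if (key %in% required) {
      abort(sprintf("File %s is missing a required column (one of: %s)",
                    path, paste(synonyms[[key]], collapse = ", ")),
            class = "glycoquant_config_error")
    }
  }
  out
}

#' Read a Byonic-style identification export
#'
#' Reads a CSV/TSV export, removes decoy and contaminant rows, extracts the
#' UniProtKB accession into `master_id`, parses scan numbers, modified
#' peptides and glycan compositions, and flags rows that cannot enter
#' quantification (multiple glycans on one peptide; a glycan modification type
#' with a blank glycan column).
#'
#' @param path Path to the export.
#' @param sample Sample label attached to every row (defaults to the file
#'   name).
#' @param contaminant_markers Passed to [is_excluded_protein()].
#' @return A tibble of identification rows with parsed columns
#'   (`master_id`, `scan`, `seq`, `peptide` (list), `glycans` (list),
#'   `glycan_text`, `n_glycans`, `multi_glycan`, `score`, `calc_mz`,
#'   `pep_start`, `sample`). Attribute `counts` records rows read, excluded
#'   and skipped.
#' @export
read_byonic <- function(path, sample = basename(path),
                        contaminant_markers = "Common contaminant") {
  df <- readr::read_delim(path, delim = .sniff_delim(path),
                          show_col_types = FALSE, progress = FALSE,
                          col_types = readr::cols(.default = "c"))
  cols <- .resolve_columns(
    names(df), BYONIC_COLUMNS,
    required = c("protein_name", "scan", "peptide", "glycans", "score",
                 "calc_mz"),
    path = path)
  n_in <- nrow(df)
  if (n_in == 0) {
    empty <- tibble(
      protein_name = character(0), master_id = character(0),
      scan = integer(0), peptide = list(), seq = character(0),
      pep_start = integer(0), glycan_text = character(0), glycans = list(),
      n_glycans = integer(0), multi_glycan = logical(0),
      mod_types = character(0), score = numeric(0), calc_mz = numeric(0),
      sample = character(0))
    attr(empty, "counts") <- list(read = 0L, excluded = 0L, inconsistent = 0L)
    return(empty)
  }

  protein_name <- df[[cols$protein_name]]
  excluded <- is_excluded_protein(protein_name, contaminant_markers)
  df <- df[!excluded, , drop = FALSE]
  protein_name <- protein_name[!excluded]

  mod_types <- if (!is.null(cols$mod_types)) df[[cols$mod_types]] else
    rep(NA_character_, nrow(df))
  glycan_text <- df[[cols$glycans]]
  glycan_text[is.na(glycan_text)] <- ""

  # A declared glycan modification with a blank glycan column cannot be
  # quantified; skip such rows with a warning rather than guessing.
  inconsistent <- !is.na(mod_types) &
    stringr::str_detect(mod_types, stringr::fixed("glycan",
                                                  ignore_case = TRUE)) &
    !nzchar(trimws(glycan_text))
  if (any(inconsistent)) {
    warn(sprintf(
      "%s: %d row(s) declare a glycan modification but have no glycan composition; skipped",
      path, sum(inconsistent)))
  }
  keep <- !inconsistent
  df <- df[keep, , drop = FALSE]
  protein_name <- protein_name[keep]
  mod_types <- mod_types[keep]
  glycan_text <- glycan_text[keep]

  start_raw <- if (!is.null(cols$start))
    suppressWarnings(as.integer(df[[cols$start]])) else
    rep(NA_integer_, nrow(df))
  peptides <- purrr::map2(df[[cols$peptide]], start_raw, parse_byonic_peptide)
  glycans <- purrr::map(glycan_text, parse_glycans)
  n_glycans <- vapply(
    glycans,
    function(gl) sum(!vapply(gl, is_unglycosylated, logical(1))),
    integer(1))

  out <- tibble(
    protein_name = protein_name,
    master_id = extract_accession(protein_name),
    scan = extract_scan_number(df[[cols$scan]]),
    peptide = peptides,
    seq = vapply(peptides, function(p) p$sequence, character(1)),
    pep_start = start_raw,
    glycan_text = glycan_text,
    glycans = glycans,
    n_glycans = n_glycans,
    multi_glycan = n_glycans > 1L,
    mod_types = mod_types,
    score = as.numeric(df[[cols$score]]),
    calc_mz = as.numeric(df[[cols$calc_mz]]),
    sample = sample
  )
  if (any(out$score < 0, na.rm = TRUE)) {
    abort(sprintf("Negative Byonic score in %s", path),
          class = "glycoquant_parse_error")
  }
  attr(out, "counts") <- list(read = n_in, excluded = sum(excluded),
                              inconsistent = sum(inconsistent))
  out
}
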