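# End-to-end orchestration: sample map in, quantification tables out.

#' Build a pipeline run configuration
#'
#' Validates the sample map and analysis parameters before any file is
#' touched. Configuration problems (missing files, duplicate labels, unknown
#' mode) raise a `glycoquant_config_error`.
#'
#' @param samples Data frame with columns `sample`, `ident`, `area` and
#'   optionally `condition` (or `group`) for the statistics layer.
#' @param mode Grouping mode, `"site"` or `"peptide"`.
#' @param score_cutoff Minimum identification score (default 200).
#' @param tolerance Glycan delta-mass tolerance in Da (default 0.05).
#' @param out_dir Output directory for the CSV tables.
#' @param protein_names Optional offline accession-to-name map: a CSV path
#'   (two columns: accession, name), a named character vector, or a data
#'   frame.
#' @param stats Run the two-group comparison (requires a `condition`/`group`
#'   column with exactly two levels).
#' @param variant t-test variant for the statistics layer.
#' @param stats_value Quantity tested by the statistics layer.
#' @return A `glycoquant_config` list.
#' @export
glycoquant_config <- function(samples, mode = c("site", "peptide"),
                              score_cutoff = 200, tolerance = 0.05,
                              out_dir = ".", protein_names = NULL,
                              stats = FALSE,
                              variant = c("student", "welch"),
                              stats_value = "proportion_without") {
  if (length(mode) == 1 && !mode %in% c("site", "peptide")) {
    abort(sprintf("Unknown analysis mode \"%s\"", mode),
          class = "glycoquant_config_error")
  }
  mode <- match.arg(mode)
  variant <- match.arg(variant)
  samples <- as_tibble(samples)
  if ("group" %in% names(samples) && !"condition" %in% names(samples)) {
    samples <- rename(samples, condition = "group")
  }
  required <- c("sample", "ident", "area")
  if (!all(required %in% names(samples))) {
    abort("samples must have columns sample, ident and area.",
          class = "glycoquant_config_error")
  }
  if (anyDuplicated(samples$sample)) {
    abort("Sample labels must be unique.", class = "glycoquant_config_error")
  }
  missing_files <- c(samples$ident[!file.exists(samples$ident)],
                     samples$area[!file.exists(samples$area)])
  if (length(missing_files)) {
    abort(sprintf("Input file(s) not found: %s",
                  paste(missing_files, collapse = ", ")),
          class = "glycoquant_config_error")
  }
  if (is.character(protein_names) && length(protein_names) == 1 &&
      is.null(names(protein_names))) {
    if (!file.exists(protein_names)) {
      abort(sprintf("Protein name map not found: %s", protein_names),
            class = "glycoquant_config_error")
    }
    protein_names <- readr::read_csv(protein_names, show_col_types = FALSE,
                                     progress = FALSE)
  }
  if (stats &&
      (!"condition" %in% names(samples) ||
       length(unique(samples$condition)) != 2)) {
    abort("Statistics require a condition/group column with exactly two levels.",
          class = "glycoquant_config_error")
  }
  structure(
    list(samples = samples, mode = mode, score_cutoff = score_cutoff,
         tolerance = tolerance, out_dir = out_dir,
         protein_names = protein_names, stats = stats, variant = variant,
         stats_value = stats_value),
    class = "glycoquant_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' The YAML mirrors the arguments of [glycoquant_config()]: a `samples` list
#' of `{sample, ident, area, condition}` records plus scalar options.
#' Relative input paths are resolved against the YAML file's directory.
#'
#' @param path Path to the YAML file.
#' @return A `glycoquant_config`.
#' @export
load_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- dirname(path)
  samples <- bind_rows(lapply(raw$samples, as_tibble))
  for (col in c("ident", "area")) {
    rel <- !file.exists(samples[[col]]) &
      file.exists(file.path(base, samples[[col]]))
    samples[[col]][rel] <- file.path(base, samples[[col]][rel])
  }
  args <- raw[setdiff(names(raw), "samples")]
  do.call(glycoquant_config, c(list(samples = samples), args))
}

#' Run the full quantification pipeline
#'
#' For every sample: reads the identification and area exports, joins areas
#' to PSMs by scan number, applies the no-area and score filters, assigns
#' glycosylation sites by delta-mass matching, then (across samples)
#' deduplicates to unique PSMs, aggregates glycoform AUC per anchor and
#' computes proportions and occupancy. Writes four CSV tables to `out_dir`
#' (`auc.csv`, `proportions.csv`, `occupancy.csv`, and `stats.csv` when
#' requested) with numbers at six significant digits, plus a per-stage row
#' count audit (`run_log.csv`). Re-running on identical inputs yields
#' byte-identical outputs.
#'
#' @param config A `glycoquant_config` (or the arguments to build one).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with `cells` (long quantification),
#'   `tables` (the written tibbles), `counts` (audit tibble) and `files`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (!inherits(config, "glycoquant_config")) {
    config <- do.call(glycoquant_config, config)
  }
  say <- function(...) if (!quiet) inform(sprintf(...))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  audit <- list()
  psm_list <- vector("list", nrow(config$samples))
  for (i in seq_len(nrow(config$samples))) {
    s <- config$samples[i, ]
    ident <- read_byonic(s$ident, sample = s$sample)
    areas <- read_pd_areas(s$area)
    rc <- attr(ident, "counts")
    joined <- join_and_filter(ident, areas,
                              score_cutoff = config$score_cutoff)
    jc <- attr(joined, "counts")
    assigned <- assign_psm_sites(joined, tol = config$tolerance)
    ac <- attr(assigned, "counts")
    audit[[i]] <- tibble(
      sample = s$sample, rows_read = rc$read, excluded = rc$excluded,
      inconsistent = rc$inconsistent, no_area = jc$no_area,
      low_score = jc$low_score, multi_glycan = ac$multi_glycan,
      unassignable = ac$unassignable, ambiguous = ac$ambiguous,
      quantifiable = nrow(assigned))
    say("%s: %d rows read, %d decoy/contaminant, %d no-area, %d sub-cutoff, %d quantifiable",
        s$sample, rc$read, rc$excluded, jc$no_area, jc$low_score,
        nrow(assigned))
    psm_list[[i]] <- assigned
  }
  psms <- bind_rows(psm_list)
  audit <- bind_rows(audit)

  sample_order <- config$samples$sample
  files <- list(
    auc = file.path(config$out_dir, "auc.csv"),
    proportions = file.path(config$out_dir, "proportions.csv"),
    occupancy = file.path(config$out_dir, "occupancy.csv"),
    log = file.path(config$out_dir, "run_log.csv"))

  if (nrow(psms) == 0) {
    warn("No quantifiable PSMs; writing empty outputs.")
    empty <- tibble(master_id = character(0), protein = character(0),
                    anchor = character(0), glycan = character(0))
    readr::write_csv(empty, files$auc)
    readr::write_csv(empty, files$proportions)
    readr::write_csv(empty[setdiff(names(empty), "glycan")], files$occupancy)
    readr::write_csv(audit, files$log)
    return(invisible(list(cells = tibble(), tables = list(), counts = audit,
                          files = files)))
  }

  uniq <- select_unique_psms(psms, mode = config$mode)
  cells <- aggregate_auc(uniq, mode = config$mode) |> compute_proportions()
  wide <- build_wide_table(cells, protein_names = config$protein_names,
                           samples = sample_order)
  occ <- occupancy_table(cells, samples = sample_order)

  auc_tbl <- select(wide, "master_id", "protein", "anchor", "glycan",
                    starts_with("auc."))
  prop_tbl <- select(wide, "master_id", "protein", "anchor", "glycan",
                     starts_with("proportion_with."),
                     starts_with("proportion_without."))
  readr::write_csv(.round_numeric(auc_tbl), files$auc, na = "")
  readr::write_csv(.round_numeric(prop_tbl), files$proportions, na = "")
  readr::write_csv(.round_numeric(occ), files$occupancy, na = "")
  readr::write_csv(audit, files$log)

  tables <- list(auc = auc_tbl, proportions = prop_tbl, occupancy = occ)

  if (isTRUE(config$stats)) {
    group_map <- setNames(config$samples$condition, config$samples$sample)
    stats_tbl <- compare_groups(cells, group_map,
                                value = config$stats_value,
                                variant = config$variant)
    files$stats <- file.path(config$out_dir, "stats.csv")
    readr::write_csv(.round_numeric(stats_tbl), files$stats, na = "")
    tables$stats <- stats_tbl
  }

  say("Quantified %d glycoforms at %d anchors across %d samples",
      nrow(wide), nrow(occ), length(sample_order))
  invisible(list(cells = cells, tables = tables, counts = audit,
                 files = files))
}

# Fixed float formatting (6 significant digits) for reproducible diffs.
.round_numeric <- function(df) {
  mutate(df, across(where(is.numeric), ~ signif(.x, 6)))
}
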