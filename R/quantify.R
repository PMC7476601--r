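# Core quantification: join identifications to areas, filter, assign sites,
# deduplicate to unique PSMs, aggregate glycoform AUC, and compute
# proportions and occupancy.
#
# Grouping deliberately uses the *unmodified* peptide sequence, so non-glycan
# modifications (oxidation, deamidation, ...) never split a glycoform.

#' Join identifications to precursor areas and filter
#'
#' Each identification row gains the area recorded at its scan number. Rows
#' with no area (no value, failed integration) and rows below the score
#' cutoff are removed; removal counts are kept in the `counts` attribute.
#'
#' @param ident_rows Tibble from [read_byonic()] (one source file).
#' @param area_map Tibble from [read_pd_areas()] for the matching file.
#' @param score_cutoff Minimum identification score to retain (default 200).
#' @return Filtered PSM tibble with an `area` column (> 0 everywhere).
#' @export
join_and_filter <- function(ident_rows, area_map, score_cutoff = 200) {
  stopifnot(score_cutoff >= 0)
  joined <- left_join(ident_rows, area_map, by = "scan")
  no_area <- is.na(joined$area)
  low_score <- !no_area & joined$score < score_cutoff
  out <- joined[!no_area & !low_score, , drop = FALSE]
  attr(out, "counts") <- list(
    joined = nrow(ident_rows),
    no_area = sum(no_area),
    low_score = sum(low_score),
    kept = nrow(out))
  out
}

#' Assign glycosylation sites to PSM rows
#'
#' Runs delta-mass site assignment ([assign_glycan_sites()]) on every
#' glycosylated row. Unglycosylated rows keep an empty canonical glycan
#' string and no site. Rows that cannot be quantified are excluded and
#' counted rather than silently dropped: multi-glycan rows (one glycan per
#' peptide is the supported path), rows whose glycan matches no modification
#' within `tol`, and ambiguous ties.
#'
#' @param psms Tibble from [join_and_filter()] (or [read_byonic()]).
#' @param tol Delta-mass tolerance in Da (default 0.05).
#' @return Tibble with added columns `glycan`, `glycan_mass`, `site_pep`,
#'   `site_prot`, `site_res`; attribute `counts` records exclusions.
#' @export
assign_psm_sites <- function(psms, tol = 0.05) {
  n <- nrow(psms)
  glycan <- character(n)
  glycan_mass <- numeric(n)
  site_pep <- rep(NA_integer_, n)
  site_prot <- rep(NA_integer_, n)
  site_res <- rep(NA_character_, n)
  drop_reason <- rep(NA_character_, n)

  for (i in seq_len(n)) {
    if (psms$multi_glycan[[i]]) {
      drop_reason[i] <- "multi_glycan"
      next
    }
    gl <- psms$glycans[[i]]
    gl <- gl[!vapply(gl, is_unglycosylated, logical(1))]
    if (length(gl) == 0) next  # unglycosylated row
    res <- tryCatch(
      assign_glycan_sites(psms$peptide[[i]], gl, tol = tol),
      glycoquant_unassignable_error = function(e) e,
      glycoquant_ambiguous_site_error = function(e) e)
    if (inherits(res, "error")) {
      drop_reason[i] <- if (inherits(res, "glycoquant_unassignable_error"))
        "unassignable" else "ambiguous"
      next
    }
    glycan[i] <- res$glycan[[1]]
    glycan_mass[i] <- composition_mass(res$composition[[1]])
    site_pep[i] <- res$peptide_pos[[1]]
    site_prot[i] <- res$protein_pos[[1]]
    site_res[i] <- substr(psms$seq[[i]], res$peptide_pos[[1]],
                          res$peptide_pos[[1]])
  }

  counts <- list(
    multi_glycan = sum(drop_reason == "multi_glycan", na.rm = TRUE),
    unassignable = sum(drop_reason == "unassignable", na.rm = TRUE),
    ambiguous = sum(drop_reason == "ambiguous", na.rm = TRUE))
  if (sum(unlist(counts)) > 0) {
    warn(sprintf(
      "Excluded from quantification: %d multi-glycan, %d unassignable, %d ambiguous row(s)",
      counts$multi_glycan, counts$unassignable, counts$ambiguous))
  }
  out <- psms |>
    mutate(glycan = glycan, glycan_mass = glycan_mass,
           site_pep = site_pep, site_prot = site_prot, site_res = site_res)
  out <- out[is.na(drop_reason), , drop = FALSE]
  attr(out, "counts") <- counts
  out
}

#' Select unique PSMs per glycoform group
#'
#' PSMs sharing unmodified peptide sequence, glycan composition, calculated
#' m/z (so each charge state is its own group) and — in site mode — the
#' assigned glycosylation site are grouped within each sample; the
#' highest-area PSM of each group is its unique PSM. Ties break to the higher
#' score, then the lower scan number, making the selection deterministic and
#' invariant to input order.
#'
#' @param psms Tibble from [assign_psm_sites()], possibly several samples
#'   bound together.
#' @param mode `"site"` or `"peptide"`.
#' @return Tibble of unique PSMs. In site mode, glycosylated rows lacking a
#'   protein-coordinate site (no starting position) are excluded and counted.
#' @export
select_unique_psms <- function(psms, mode = c("site", "peptide")) {
  mode <- match.arg(mode)
  n_unlocated <- 0L
  if (mode == "site") {
    unlocated <- nzchar(psms$glycan) & is.na(psms$site_prot)
    n_unlocated <- sum(unlocated)
    if (n_unlocated > 0) {
      warn(sprintf(
        "site mode: %d glycosylated row(s) without a protein start position excluded",
        n_unlocated))
      psms <- psms[!unlocated, , drop = FALSE]
    }
  }
  keys <- c("sample", "master_id", "seq", "glycan", "calc_mz",
            if (mode == "site") "site_prot")
  out <- psms |>
    arrange(desc(.data$area), desc(.data$score), .data$scan) |>
    group_by(across(all_of(keys))) |>
    slice(1) |>
    ungroup() |>
    arrange(.data$sample, .data$master_id, .data$seq, .data$glycan,
            .data$calc_mz, .data$site_prot, .data$scan)
  attr(out, "counts") <- list(unlocated = n_unlocated, unique = nrow(out))
  out
}

# Known glycosites: every (protein, site) observed glycosylated anywhere in
# the experiment, with the residue letter taken from the covering peptide.
.known_sites <- function(unique_psms) {
  unique_psms |>
    filter(nzchar(.data$glycan), !is.na(.data$site_prot)) |>
    distinct(.data$master_id, .data$site_prot, .data$site_res)
}

#' Aggregate unique-PSM areas into glycoform AUC per anchor
#'
#' Sums the areas of unique PSMs sharing (protein, anchor, composition)
#' within each sample — charge states and, in site mode, peptide variants
#' (e.g. missed-cleavage forms) covering the same site merge into one
#' glycoform total.
#'
#' In site mode the anchor is the glycosylated protein residue (label like
#' `"N180"`); unglycosylated peptides contribute under the all-zero
#' composition at every known glycosite they span (a site is "known" when it
#' is observed glycosylated somewhere in the experiment). In peptide mode the
#' anchor is the proteolytic peptide form (`"SEQ@start"`); only peptides
#' observed glycosylated at least once are quantifiable anchors.
#'
#' @param unique_psms Tibble from [select_unique_psms()].
#' @param mode `"site"` or `"peptide"` (must match the dedup mode).
#' @return Long tibble of cells: `sample`, `master_id`, `anchor`,
#'   `anchor_sort`, `glycan`, `auc`.
#' @export
aggregate_auc <- function(unique_psms, mode = c("site", "peptide")) {
  mode <- match.arg(mode)
  if (mode == "site") {
    sites <- .known_sites(unique_psms)
    glyc <- unique_psms |>
      filter(nzchar(.data$glycan)) |>
      mutate(anchor = paste0(.data$site_res, .data$site_prot),
             anchor_sort = as.numeric(.data$site_prot))
    unglyc <- unique_psms |>
      filter(!nzchar(.data$glycan), !is.na(.data$pep_start)) |>
      inner_join(sites, by = "master_id", suffix = c("", ".site"),
                 relationship = "many-to-many") |>
      filter(.data$site_prot.site >= .data$pep_start,
             .data$site_prot.site <= .data$pep_start + nchar(.data$seq) - 1L) |>
      mutate(anchor = paste0(.data$site_res.site, .data$site_prot.site),
             anchor_sort = as.numeric(.data$site_prot.site))
    cells <- bind_rows(glyc, unglyc)
  } else {
    anchored <- unique_psms |>
      mutate(anchor = paste0(.data$seq, "@", .data$pep_start),
             anchor_sort = as.numeric(.data$pep_start))
    quantifiable <- anchored |>
      filter(nzchar(.data$glycan)) |>
      distinct(.data$master_id, .data$anchor)
    cells <- anchored |>
      semi_join(quantifiable, by = c("master_id", "anchor"))
  }
  cells |>
    group_by(.data$sample, .data$master_id, .data$anchor,
             .data$anchor_sort, .data$glycan) |>
    summarise(auc = sum(.data$area), .groups = "drop")
}

#' Glycoform proportions and site occupancy per sample
#'
#' Within each (sample, protein, anchor), computes the proportion of each
#' glycoform with and without inclusion of the unglycosylated form, and the
#' occupancy. Glycosylation status is assumed not to affect detection
#' quantitatively, so proportions are ratios of summed AUC:
#' `proportion_with = auc / sum(all forms)`,
#' `proportion_without = auc / sum(glycosylated forms)` (absent for the
#' unglycosylated row and when no glycosylated AUC exists), and
#' `occupancy = sum(glycosylated) / sum(all) = 1 - proportion_with(unglyc)`.
#'
#' @param cells Long tibble from [aggregate_auc()].
#' @return The cells with `proportion_with`, `proportion_without` and
#'   `occupancy` columns added.
#' @export
compute_proportions <- function(cells) {
  cells |>
    group_by(.data$sample, .data$master_id, .data$anchor) |>
    mutate(
      total_all = sum(.data$auc),
      total_glyc = sum(.data$auc[nzchar(.data$glycan)]),
      proportion_with = .data$auc / .data$total_all,
      proportion_without = ifelse(
        nzchar(.data$glycan) & .data$total_glyc > 0,
        .data$auc / .data$total_glyc, NA_real_),
      occupancy = .data$total_glyc / .data$total_all) |>
    ungroup() |>
    select(-"total_all", -"total_glyc")
}

#' Site occupancy table
#'
#' One row per (protein, anchor) with occupancy per sample in wide form.
#'
#' @param cells Tibble from [compute_proportions()].
#' @param samples Optional sample ordering for the columns.
#' @return A wide tibble.
#' @export
occupancy_table <- function(cells, samples = NULL) {
  long <- cells |>
    distinct(.data$sample, .data$master_id, .data$anchor, .data$anchor_sort,
             .data$occupancy)
  samples <- samples %||% sort(unique(long$sample))
  long |>
    mutate(sample = factor(.data$sample, levels = samples)) |>
    pivot_wider(names_from = "sample", values_from = "occupancy",
                names_prefix = "occupancy.", names_expand = TRUE) |>
    arrange(.data$master_id, .data$anchor_sort, .data$anchor) |>
    select(-"anchor_sort")
}

#' Build the wide glycoform output table
#'
#' One row per glycoform (protein, anchor, composition), with per-sample
#' column blocks for summed AUC, proportion including the unglycosylated
#' form, and proportion among glycosylated forms. A glycoform not observed in
#' a sample is left blank (missing values are not imputed), never zero. Row
#' order is deterministic: protein, anchor, then composition (unglycosylated
#' first).
#'
#' @param cells Tibble from [compute_proportions()].
#' @param protein_names Optional named character vector or two-column data
#'   frame (`accession`, `name`) mapping accessions to display names; unknown
#'   accessions get a blank name.
#' @param samples Optional sample ordering for the column blocks.
#' @return A wide tibble.
#' @export
build_wide_table <- function(cells, protein_names = NULL, samples = NULL) {
  samples <- samples %||% sort(unique(cells$sample))
  name_of <- .protein_name_lookup(protein_names)
  if (nrow(cells) == 0) {
    return(tibble(master_id = character(0), protein = character(0),
                  anchor = character(0), glycan = character(0)))
  }
  wide <- cells |>
    mutate(sample = factor(.data$sample, levels = samples)) |>
    select("master_id", "anchor", "anchor_sort", "glycan", "sample",
           "auc", "proportion_with", "proportion_without") |>
    pivot_wider(
      names_from = "sample",
      values_from = c("auc", "proportion_with", "proportion_without"),
      names_glue = "{.value}.{sample}", names_expand = TRUE) |>
    arrange(.data$master_id, .data$anchor_sort, .data$anchor,
            nzchar(.data$glycan), .data$glycan) |>
    mutate(protein = name_of(.data$master_id), .after = "master_id") |>
    select(-"anchor_sort")
  metric_cols <- as.vector(outer(
    c("auc", "proportion_with", "proportion_without"), samples,
    function(m, s) paste0(m, ".", s)))
  wide |>
    select("master_id", "protein", "anchor", "glycan", all_of(metric_cols))
}

.protein_name_lookup <- function(protein_names) {
  if (is.null(protein_names)) return(function(id) rep("", length(id)))
  if (is.data.frame(protein_names)) {
    protein_names <- setNames(as.character(protein_names[[2]]),
                              as.character(protein_names[[1]]))
  }
  function(id) {
    out <- unname(protein_names[id])
    out[is.na(out)] <- ""
    out
  }
}
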