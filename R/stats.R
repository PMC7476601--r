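# Two-group comparison of glycoform quantities across replicate samples.
#
# Unpaired two-tailed t-tests, no multiple-testing correction and no
# imputation: a glycoform missing in a sample simply contributes no value.

#' Compare glycoform quantities between two groups of samples
#'
#' Runs an unpaired two-tailed t-test per glycoform row on the chosen
#' quantity. Student's equal-variance test is the default; Welch's test is
#' available via `variant`. Rows with fewer than two non-missing values in
#' either group are reported but not tested. No multiple-testing correction
#' is applied; a significance flag is set at `p < alpha`.
#'
#' @param cells Long tibble from [compute_proportions()].
#' @param group_map Data frame with columns `sample` and `group` (exactly two
#'   groups), or a named character vector `sample -> group`. The first group
#'   in the map's order is group A; `t` has the sign of `mean_a - mean_b`.
#' @param value Quantity to test: `"proportion_without"` (default; the
#'   relative abundance among glycosylated forms), `"proportion_with"`,
#'   `"auc"`, or `"occupancy"` (collapses to one row per anchor).
#' @param variant `"student"` (pooled variance) or `"welch"`.
#' @param alpha Significance threshold for the flag (default 0.05).
#' @return A tibble with one row per glycoform: group means and sizes,
#'   `t`, `p`, `log2_ratio` (log2 of mean B over mean A), `neg_log10_p`,
#'   `significant`, and a `note` for untested rows ("insufficient
#'   replicates", "degenerate variance").
#' @export
#' @examples
#' # compare_groups(cells, c(healthy_1 = "healthy", disease_1 = "disease", ...))
compare_groups <- function(cells, group_map,
                           value = c("proportion_without", "proportion_with",
                                     "auc", "occupancy"),
                           variant = c("student", "welch"), alpha = 0.05) {
  value <- match.arg(value)
  variant <- match.arg(variant)
  groups <- .normalise_group_map(group_map)
  levels_ab <- unique(groups$group)
  if (length(levels_ab) != 2) {
    abort("group_map must assign samples to exactly two groups.",
          class = "glycoquant_config_error")
  }

  if (value == "occupancy") {
    long <- cells |>
      distinct(.data$sample, .data$master_id, .data$anchor,
               .data$anchor_sort, .data$occupancy) |>
      mutate(glycan = "(occupancy)") |>
      rename(value = "occupancy")
  } else {
    long <- cells |>
      select("sample", "master_id", "anchor", "anchor_sort", "glycan",
             value = all_of(value))
  }

  long <- long |>
    filter(!is.na(.data$value)) |>
    inner_join(groups, by = "sample")

  long |>
    group_by(.data$master_id, .data$anchor, .data$anchor_sort, .data$glycan) |>
    summarise(
      .test_one(.data$value[.data$group == levels_ab[[1]]],
                .data$value[.data$group == levels_ab[[2]]],
                variant = variant),
      .groups = "drop") |>
    mutate(significant = !is.na(.data$p) & .data$p < alpha,
           neg_log10_p = -log10(.data$p)) |>
    arrange(.data$master_id, .data$anchor_sort, .data$anchor, .data$glycan) |>
    select(-"anchor_sort")
}

.normalise_group_map <- function(group_map) {
  if (is.data.frame(group_map)) {
    stopifnot(all(c("sample", "group") %in% names(group_map)))
    out <- tibble(sample = as.character(group_map$sample),
                  group = as.character(group_map$group))
  } else {
    out <- tibble(sample = names(group_map),
                  group = as.character(group_map))
  }
  if (anyDuplicated(out$sample)) {
    abort("Each sample must be assigned to exactly one group.",
          class = "glycoquant_config_error")
  }
  out
}

.test_one <- function(a, b, variant) {
  base <- tibble(
    mean_a = if (length(a)) mean(a) else NA_real_,
    mean_b = if (length(b)) mean(b) else NA_real_,
    n_a = length(a), n_b = length(b),
    t = NA_real_, p = NA_real_,
    log2_ratio = ifelse(length(a) && length(b) &&
                          mean(a) > 0 && mean(b) > 0,
                        log2(mean(b) / mean(a)), NA_real_),
    note = NA_character_)
  if (length(a) < 2 || length(b) < 2) {
    base$note <- "insufficient replicates"
    return(base)
  }
  fit <- tryCatch(
    t.test(a, b, var.equal = variant == "student"),
    error = function(e) e)
  if (inherits(fit, "error")) {
    base$note <- "degenerate variance"
    return(base)
  }
  base$t <- unname(fit$statistic)
  base$p <- fit$p.value
  base
}
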