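# Fixture simulator: writes matched identification and precursor-area
# exports from a planted ground-truth glycoproteome.
#
# The generator emulates what the two exporters print, not the instrument:
# per sample it plants one primary PSM per (glycoform, charge state) whose
# areas are exact shares of the site total, then layers in the artefacts the
# pipeline must survive — redundant duplicate PSMs with strictly smaller
# areas (so max-area deduplication is exercised non-trivially), decoy and
# contaminant rows, rows with no recorded area, and sub-cutoff scores.

PROTON_MASS <- 1.007276466
WATER_MASS <- 18.0105646863

# Monoisotopic amino-acid residue masses, used only to print plausible
# calculated m/z values in fixtures.
AA_MASSES <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931)

peptide_mono_mass <- function(seq) {
  sum(AA_MASSES[strsplit(seq, "")[[1]]]) + WATER_MASS
}

#' Default glycan composition library
#'
#' A small library of common N- or O-glycan compositions used by the fixture
#' generator, standing in for the much larger composition databases typical
#' search engines ship.
#'
#' @param type `"N"` or `"O"`.
#' @return Character vector of canonical composition strings.
#' @export
default_glycan_library <- function(type = c("N", "O")) {
  type <- match.arg(type)
  if (type == "N") {
    c("HexNAc(2)Hex(5)", "HexNAc(2)Hex(6)", "HexNAc(2)Hex(7)",
      "HexNAc(2)Hex(8)", "HexNAc(2)Hex(9)",
      "HexNAc(4)Hex(3)", "HexNAc(4)Hex(3)Fuc(1)", "HexNAc(4)Hex(4)Fuc(1)",
      "HexNAc(4)Hex(5)Fuc(1)", "HexNAc(4)Hex(5)",
      "HexNAc(4)Hex(5)NeuAc(1)", "HexNAc(4)Hex(5)NeuAc(2)",
      "HexNAc(4)Hex(5)Fuc(1)NeuAc(1)", "HexNAc(5)Hex(6)NeuAc(3)",
      "HexNAc(6)Hex(7)NeuAc(4)")
  } else {
    c("HexNAc(1)", "HexNAc(1)Hex(1)", "HexNAc(1)Hex(1)NeuAc(1)",
      "HexNAc(1)Hex(1)NeuAc(2)", "HexNAc(2)Hex(1)", "HexNAc(2)Hex(2)",
      "HexNAc(2)Hex(2)NeuAc(1)", "HexNAc(1)NeuAc(1)")
  }
}

#' Construct a ground-truth glycoproteome model
#'
#' @param proteins List of protein specs. Each is a list with `accession`,
#'   `name` (entry name), `description`, and `sites`: a list of site specs
#'   with `peptide` (tryptic sequence), `start` (1-based protein position of
#'   the first residue), `site_pep` (1-based position of the glycosylated
#'   residue in the peptide), `total` (site total AUC), `occupancy` (named
#'   numeric per condition, in \[0,1\]) and `glycoforms` (named list mapping
#'   composition string to a named numeric of per-condition proportions;
#'   proportions must sum to 1 within each condition).
#' @param samples Data frame with columns `sample` and `condition`.
#' @param noise_sd Multiplicative log-normal sd on planted areas (0 = exact).
#' @param redundancy Duplicate-PSM count per precursor: each primary PSM gets
#'   `redundancy - 1` duplicates with strictly smaller areas.
#' @param decoy_rate,contaminant_rate,no_area_rate,low_score_rate Injection
#'   rates, as fractions of the number of genuine rows per sample.
#' @param score_range Range of identification scores for genuine rows.
#' @param seed Integer seed; the same seed yields byte-identical files.
#' @return A validated `glyco_truth_model`.
#' @export
truth_model <- function(proteins, samples, noise_sd = 0, redundancy = 2,
                        decoy_rate = 0.1, contaminant_rate = 0.05,
                        no_area_rate = 0.05, low_score_rate = 0.05,
                        score_range = c(250, 600), seed = 1L) {
  model <- structure(
    list(proteins = proteins, samples = as_tibble(samples),
         noise_sd = noise_sd, redundancy = as.integer(redundancy),
         decoy_rate = decoy_rate, contaminant_rate = contaminant_rate,
         no_area_rate = no_area_rate, low_score_rate = low_score_rate,
         score_range = score_range, seed = as.integer(seed)),
    class = "glyco_truth_model")
  validate_truth_model(model)
  model
}

#' @rdname truth_model
#' @param model A `glyco_truth_model`.
#' @export
validate_truth_model <- function(model) {
  stopifnot(inherits(model, "glyco_truth_model"))
  if (!all(c("sample", "condition") %in% names(model$samples))) {
    abort("samples must have columns sample and condition.",
          class = "glycoquant_config_error")
  }
  if (anyDuplicated(model$samples$sample)) {
    abort("Sample labels must be unique.", class = "glycoquant_config_error")
  }
  conditions <- unique(model$samples$condition)
  for (prot in model$proteins) {
    for (site in prot$sites) {
      res <- substr(site$peptide, site$site_pep, site$site_pep)
      if (!nzchar(res)) {
        abort(sprintf("Site position %d outside peptide %s",
                      site$site_pep, site$peptide),
              class = "glycoquant_config_error")
      }
      for (cond in conditions) {
        occ <- site$occupancy[[cond]]
        if (is.null(occ) || occ < 0 || occ > 1) {
          abort(sprintf("Occupancy for %s site %s condition %s must be in [0,1]",
                        prot$accession, site$peptide, cond),
                class = "glycoquant_config_error")
        }
        props <- vapply(site$glycoforms, function(gf) gf[[cond]], numeric(1))
        if (abs(sum(props) - 1) > 1e-9) {
          abort(sprintf(
            "Glycoform proportions for %s site %s condition %s sum to %.6f, not 1",
            prot$accession, site$peptide, cond, sum(props)),
            class = "glycoquant_config_error")
        }
      }
    }
  }
  invisible(model)
}

#' Default ground-truth model
#'
#' Three glycoproteins with six sites carrying two to four glycoforms each
#' plus an unglycosylated form, profiled in two conditions with three
#' replicates each. Site totals, occupancies and per-condition glycoform
#' distributions are fixed; the disease condition carries lower sialylation
#' and lower occupancy at several sites, giving the statistics layer real
#' signal when noise is enabled. Every peptide contains exactly one
#' glycosite, so site- and peptide-mode analyses are comparable.
#'
#' @inheritParams truth_model
#' @return A `glyco_truth_model`.
#' @export
default_truth_model <- function(seed = 1L, noise_sd = 0, redundancy = 2,
                                decoy_rate = 0.1, contaminant_rate = 0.05,
                                no_area_rate = 0.05, low_score_rate = 0.05) {
  gf <- function(...) {
    specs <- list(...)
    lapply(specs, function(s) c(healthy = s[[1]], disease = s[[2]]))
  }
  proteins <- list(
    list(
      accession = "P10001", name = "GLYA1_TEST",
      description = "Synthetic test glycoprotein A",
      sites = list(
        list(peptide = "LVNATSAK", start = 118L, site_pep = 3L, total = 2e7,
             occupancy = c(healthy = 0.92, disease = 0.75),
             glycoforms = setNames(
               gf(c(0.60, 0.35), c(0.40, 0.65)),
               c("HexNAc(4)Hex(3)Fuc(1)", "HexNAc(4)Hex(5)"))),
        list(peptide = "EEQYNSTYR", start = 176L, site_pep = 5L, total = 3.2e7,
             occupancy = c(healthy = 0.88, disease = 0.88),
             glycoforms = setNames(
               gf(c(0.25, 0.45), c(0.35, 0.30), c(0.25, 0.15), c(0.15, 0.10)),
               c("HexNAc(4)Hex(3)Fuc(1)", "HexNAc(4)Hex(4)Fuc(1)",
                 "HexNAc(4)Hex(5)Fuc(1)", "HexNAc(4)Hex(5)NeuAc(2)"))),
        list(peptide = "YGNSSTDHVK", start = 269L, site_pep = 3L, total = 1.5e7,
             occupancy = c(healthy = 0.95, disease = 0.60),
             glycoforms = setNames(
               gf(c(0.50, 0.20), c(0.30, 0.45), c(0.20, 0.35)),
               c("HexNAc(5)Hex(6)NeuAc(3)", "HexNAc(4)Hex(5)NeuAc(2)",
                 "HexNAc(4)Hex(5)NeuAc(1)"))))),
    list(
      accession = "P20002", name = "GLYB1_TEST",
      description = "Synthetic test glycoprotein B",
      sites = list(
        list(peptide = "GTNGTSR", start = 76L, site_pep = 3L, total = 1e7,
             occupancy = c(healthy = 0.80, disease = 0.80),
             glycoforms = setNames(
               gf(c(0.70, 0.50), c(0.30, 0.50)),
               c("HexNAc(2)Hex(5)", "HexNAc(2)Hex(6)"))),
        list(peptide = "VVLHPNYSK", start = 179L, site_pep = 6L, total = 2.4e7,
             occupancy = c(healthy = 0.85, disease = 0.70),
             glycoforms = setNames(
               gf(c(0.40, 0.20), c(0.35, 0.40), c(0.25, 0.40)),
               c("HexNAc(4)Hex(5)NeuAc(2)", "HexNAc(4)Hex(5)NeuAc(1)",
                 "HexNAc(4)Hex(5)"))))),
    list(
      accession = "Q30003", name = "GLYC1_TEST",
      description = "Synthetic test glycoprotein C (O-glycosylated)",
      sites = list(
        list(peptide = "GGSTSYGTGSETESPR", start = 272L, site_pep = 3L,
             total = 8e6,
             occupancy = c(healthy = 0.50, disease = 0.70),
             glycoforms = setNames(
               gf(c(0.35, 0.20), c(0.30, 0.45), c(0.20, 0.20), c(0.15, 0.15)),
               c("HexNAc(1)Hex(1)NeuAc(2)", "HexNAc(1)Hex(1)NeuAc(1)",
                 "HexNAc(1)Hex(1)", "HexNAc(1)"))))))
  conditions <- c("healthy", "disease")
  samples <- tibble(
    sample = paste(rep(conditions, each = 3), 1:3, sep = "_"),
    condition = rep(conditions, each = 3))
  truth_model(proteins, samples, noise_sd = noise_sd,
              redundancy = redundancy, decoy_rate = decoy_rate,
              contaminant_rate = contaminant_rate,
              no_area_rate = no_area_rate, low_score_rate = low_score_rate,
              seed = seed)
}

#' Planted truth table for a model
#'
#' One row per (condition, site, glycoform incl. the unglycosylated form)
#' with the planted proportions and occupancy — what a perfect analysis of
#' noiseless fixtures must recover.
#'
#' @param model A `glyco_truth_model`.
#' @return A tibble.
#' @export
truth_table <- function(model) {
  conditions <- unique(model$samples$condition)
  rows <- list()
  for (prot in model$proteins) {
    for (site in prot$sites) {
      res <- substr(site$peptide, site$site_pep, site$site_pep)
      pos <- site$start + site$site_pep - 1L
      for (cond in conditions) {
        occ <- site$occupancy[[cond]]
        props <- vapply(site$glycoforms, function(gf) gf[[cond]], numeric(1))
        forms <- tibble(
          glycan = names(site$glycoforms),
          proportion_with = unname(props) * occ,
          proportion_without = unname(props))
        if (occ < 1) {
          forms <- bind_rows(forms, tibble(
            glycan = "", proportion_with = 1 - occ,
            proportion_without = NA_real_))
        }
        pep <- site$peptide
        pep_start <- site$start
        rows[[length(rows) + 1L]] <- forms |>
          mutate(condition = cond, master_id = prot$accession,
                 site = pos, site_label = paste0(res, pos),
                 peptide = pep, start = pep_start,
                 peptide_label = paste0(pep, "@", pep_start),
                 occupancy = occ)
      }
    }
  }
  bind_rows(rows) |>
    select("condition", "master_id", "site", "site_label", "peptide",
           "start", "peptide_label", "glycan", "proportion_with",
           "proportion_without", "occupancy")
}

#' Generate matched identification and area export files
#'
#' Writes, for each sample in the model, an identification CSV in the
#' Byonic-style dialect (`Protein Name` with `sp|ACC|NAME` entries, dotted
#' scan titles, bracketed glycan delta masses consistent with
#' [composition_mass()] to four decimals, scores, calculated m/z for charge
#' states 2 and 3, starting positions) and a precursor-area TSV
#' (`First Scan`, `Area`), plus the planted truth table and a sample map.
#' The same seed yields byte-identical files.
#'
#' @param model A `glyco_truth_model`.
#' @param dir Output directory (created if needed).
#' @return A list with `samples` (tibble: sample, condition, ident, area),
#'   `truth` (tibble from [truth_table()]) and `dir`, invisibly classed
#'   `glyco_fixture_set`.
#' @export
generate_fixture_files <- function(model, dir = tempfile("glycofix")) {
  validate_truth_model(model)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(model$seed)
  charge_weights <- c(`2` = 0.7, `3` = 0.3)

  sample_files <- vector("list", nrow(model$samples))
  for (si in seq_len(nrow(model$samples))) {
    label <- model$samples$sample[[si]]
    cond <- model$samples$condition[[si]]
    scan <- 1000L
    rows <- list()
    areas <- list()
    add_row <- function(prot_name, scan, z, pep_str, glycan, mod_type,
                        score, mz, start, area) {
      rows[[length(rows) + 1L]] <<- tibble(
        `Protein Name` = prot_name,
        `Scan number` = sprintf("%s.%d.%d.%d", label, scan, scan, z),
        Peptide = pep_str, `Glycans NHFAGNa` = glycan,
        `Modification Type(s)` = mod_type, Score = score,
        `Calc. m/z` = mz, `Starting position` = start)
      if (!is.na(area)) {
        areas[[length(areas) + 1L]] <<- tibble(`First Scan` = scan,
                                               Area = area)
      }
    }

    for (prot in model$proteins) {
      prot_name <- sprintf("sp|%s|%s %s", prot$accession, prot$name,
                           prot$description)
      for (site in prot$sites) {
        occ <- site$occupancy[[cond]]
        props <- vapply(site$glycoforms, function(gf) gf[[cond]], numeric(1))
        eff <- c(setNames(unname(props) * occ, names(site$glycoforms)))
        if (occ < 1) eff <- c(eff, setNames(1 - occ, ""))
        pep_mass <- peptide_mono_mass(site$peptide)
        for (fi in seq_along(eff)) {
          form <- names(eff)[[fi]]
          if (eff[[fi]] <= 0) next
          glyc_mass <- if (nzchar(form))
            composition_mass(parse_glycan_composition(form)) else 0
          auc_form <- site$total * eff[[fi]] *
            exp(rnorm(1, 0, model$noise_sd))
          pep_str <- if (nzchar(form)) {
            chars <- strsplit(site$peptide, "")[[1]]
            chars[site$site_pep] <- sprintf("%s[%+.4f]",
                                            chars[site$site_pep], glyc_mass)
            paste0("K.", paste0(chars, collapse = ""), ".V")
          } else {
            paste0("K.", site$peptide, ".V")
          }
          for (z in c(2L, 3L)) {
            area <- auc_form * charge_weights[[as.character(z)]]
            mz <- round((pep_mass + glyc_mass + z * PROTON_MASS) / z, 5)
            scan <- scan + 3L
            add_row(prot_name, scan, z, pep_str, form,
                    if (nzchar(form)) "Glycan" else "",
                    round(runif(1, model$score_range[1],
                                model$score_range[2]), 1),
                    mz, site$start, area)
            # redundant duplicates: same key, strictly smaller area, so the
            # max-area rule decides which PSM represents the precursor
            for (d in seq_len(model$redundancy - 1L)) {
              scan <- scan + 3L
              add_row(prot_name, scan, z, pep_str, form,
                      if (nzchar(form)) "Glycan" else "",
                      round(runif(1, model$score_range[1],
                                  model$score_range[2]), 1),
                      mz, site$start, area * runif(1, 0.3, 0.8))
            }
          }
        }
      }
    }

    n_real <- length(rows)
    glyco_idx <- which(vapply(rows, function(r)
      nzchar(r$`Glycans NHFAGNa`), logical(1)))
    inject <- function(n, f) {
      for (k in seq_len(n)) {
        tmpl <- rows[[glyco_idx[[1L + (k - 1L) %% length(glyco_idx)]]]]
        scan <<- scan + 3L
        f(tmpl, scan)
      }
    }
    inject(round(model$decoy_rate * n_real), function(tmpl, scan) {
      add_row(paste0(">Reverse ", tmpl$`Protein Name`), scan, 2L,
              tmpl$Peptide, tmpl$`Glycans NHFAGNa`, "Glycan",
              round(runif(1, model$score_range[1], model$score_range[2]), 1),
              tmpl$`Calc. m/z`, tmpl$`Starting position`,
              runif(1, 1e4, 1e6))
    })
    inject(round(model$contaminant_rate * n_real), function(tmpl, scan) {
      add_row("Common contaminant protein Trypsin", scan, 2L,
              "K.VATVSLPR.S", "", "",
              round(runif(1, model$score_range[1], model$score_range[2]), 1),
              round((peptide_mono_mass("VATVSLPR") + 2 * PROTON_MASS) / 2, 5),
              NA_integer_, runif(1, 1e4, 1e6))
    })
    inject(round(model$no_area_rate * n_real), function(tmpl, scan) {
      add_row(tmpl$`Protein Name`, scan, 2L, tmpl$Peptide,
              tmpl$`Glycans NHFAGNa`, "Glycan",
              round(runif(1, model$score_range[1], model$score_range[2]), 1),
              tmpl$`Calc. m/z`, tmpl$`Starting position`, NA_real_)
    })
    inject(round(model$low_score_rate * n_real), function(tmpl, scan) {
      add_row(tmpl$`Protein Name`, scan, 2L, tmpl$Peptide,
              tmpl$`Glycans NHFAGNa`, "Glycan",
              round(runif(1, 50, 190), 1),
              tmpl$`Calc. m/z`, tmpl$`Starting position`,
              runif(1, 1e4, 1e6))
    })

    ident <- bind_rows(rows)
    ident <- ident[sample.int(nrow(ident)), , drop = FALSE]
    area_tbl <- bind_rows(areas) |> arrange(.data$`First Scan`)

    ident_path <- file.path(dir, paste0(label, "_byonic.csv"))
    area_path <- file.path(dir, paste0(label, "_pd.txt"))
    readr::write_csv(ident, ident_path, na = "")
    readr::write_tsv(area_tbl, area_path, na = "")
    sample_files[[si]] <- tibble(sample = label, condition = cond,
                                 ident = ident_path, area = area_path)
  }

  truth <- truth_table(model)
  sample_map <- bind_rows(sample_files)
  readr::write_csv(truth, file.path(dir, "truth.csv"), na = "")
  readr::write_csv(sample_map, file.path(dir, "sample_map.csv"), na = "")
  invisible(structure(list(samples = sample_map, truth = truth, dir = dir),
                      class = "glyco_fixture_set"))
}

#' Randomised site-assignment test cases
#'
#' Generates peptides with one planted glycan delta mass (rounded to the four
#' decimals the export dialect prints) plus zero to two decoy non-glycan
#' modifications (oxidation, deamidation, pyro-Glu, carbamidomethyl) at
#' other positions. Every case is unambiguous by construction: the decoy
#' deltas are far from every library glycan mass.
#'
#' @param n Number of cases.
#' @param seed Integer seed.
#' @return A tibble with `peptide` (list of `modified_peptide`), `glycan`
#'   (list of `glycan_composition`) and `true_pos` (planted 1-based peptide
#'   position).
#' @export
simulate_assignment_cases <- function(n = 200, seed = 1L) {
  set.seed(seed)
  library_strings <- c(default_glycan_library("N"), default_glycan_library("O"))
  decoy_deltas <- c(15.9949, 0.9840, -17.0265, 57.0215)
  aa <- strsplit(AMINO_ACIDS, "")[[1]]
  cases <- vector("list", n)
  for (i in seq_len(n)) {
    len <- sample(8:20, 1)
    seq <- paste0(sample(aa, len, replace = TRUE), collapse = "")
    comp <- parse_glycan_composition(sample(library_strings, 1))
    pos <- sample(len, 1)
    n_decoy <- sample(0:2, 1)
    decoy_pos <- setdiff(seq_len(len), pos)
    decoy_pos <- if (n_decoy > 0) sample(decoy_pos, n_decoy) else integer(0)
    mods <- tibble(
      position = c(pos, decoy_pos),
      delta = c(round(composition_mass(comp), 4),
                sample(decoy_deltas, n_decoy, replace = TRUE)))
    mods <- mods[order(mods$position), , drop = FALSE]
    p <- structure(
      list(flank_n = "K", sequence = seq, flank_c = "R", mods = mods,
           start = sample(1:500, 1)),
      class = "modified_peptide")
    cases[[i]] <- tibble(peptide = list(p), glycan = list(comp),
                         true_pos = pos)
  }
  bind_rows(cases)
}
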