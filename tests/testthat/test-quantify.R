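# Joining, filtering, unique-PSM selection, AUC aggregation, proportions.

test_that("joining attaches areas and drops no-area and sub-cutoff rows", {
  ident <- tibble::tibble(
    scan = c(10288L, 99999L, 10289L), score = c(350, 350, 150),
    sample = "s1")
  areas <- tibble::tibble(scan = c(10288L, 10289L), area = c(2e6, 1e6))
  out <- join_and_filter(ident, areas, score_cutoff = 200)
  expect_equal(out$scan, 10288L)
  expect_equal(out$area, 2e6)
  counts <- attr(out, "counts")
  expect_equal(counts$no_area, 1L)
  expect_equal(counts$low_score, 1L)
})

test_that("raising the score cutoff never adds rows", {
  set.seed(5)
  ident <- tibble::tibble(scan = 1:50, score = runif(50, 0, 1200),
                          sample = "s1")
  areas <- tibble::tibble(scan = 1:45, area = runif(45, 1e5, 1e7))
  kept <- vapply(c(0, 200, 1000),
                 function(cut) nrow(join_and_filter(ident, areas, cut)),
                 numeric(1))
  expect_true(all(diff(kept) <= 0))
})

test_that("the highest-area PSM represents each glycoform group", {
  psms <- dplyr::bind_rows(
    psm(area = 2e6, scan = 1001L),
    psm(area = 5e5, scan = 1002L))  # duplicate of the same precursor
  uniq <- select_unique_psms(psms, "site")
  expect_equal(nrow(uniq), 1)
  expect_equal(uniq$area, 2e6)

  # equal areas: higher score, then lower scan
  tie <- dplyr::bind_rows(
    psm(area = 1e6, score = 300, scan = 1001L),
    psm(area = 1e6, score = 500, scan = 1002L),
    psm(area = 1e6, score = 500, scan = 1000L))
  u <- select_unique_psms(tie, "site")
  expect_equal(u$scan, 1000L)
})

test_that("different calculated m/z values (charge states) are distinct keys", {
  psms <- dplyr::bind_rows(
    psm(calc_mz = 1029.42, area = 2e6),
    psm(calc_mz = 686.62, area = 1e6, scan = 1003L))
  uniq <- select_unique_psms(psms, "site")
  expect_equal(nrow(uniq), 2)
  # ... and their areas then sum into one glycoform AUC at the site
  cells <- aggregate_auc(uniq, "site")
  expect_equal(nrow(cells), 1)
  expect_equal(cells$auc, 3e6)
  expect_equal(cells$anchor, "N180")
})

test_that("unique-PSM selection is idempotent and order-invariant", {
  set.seed(9)
  psms <- dplyr::bind_rows(lapply(1:30, function(i) {
    psm(glycan = sample(c("HexNAc(2)Hex(3)", "HexNAc(4)Hex(3)Fuc(1)"), 1),
        calc_mz = sample(c(700.1, 900.2), 1),
        area = runif(1, 1e5, 5e6), score = runif(1, 200, 600),
        scan = 1000L + i)
  }))
  u1 <- select_unique_psms(psms, "site")
  expect_identical(select_unique_psms(u1, "site"), u1)
  shuffled <- psms[sample(nrow(psms)), ]
  expect_identical(select_unique_psms(shuffled, "site"), u1)
})

test_that("site mode merges peptide variants covering the site", {
  # a missed-cleavage variant of the same site
  psms <- dplyr::bind_rows(
    psm(seq = "EEQYNSTYR", pep_start = 176L, area = 2e6),
    psm(seq = "GEEQYNSTYR", pep_start = 175L, area = 1e6, scan = 1002L,
        calc_mz = 1093.95))
  cells <- quantify_cells(psms, "site")
  expect_equal(nrow(cells), 1)
  expect_equal(cells$auc, 3e6)

  # peptide mode keeps proteolytic forms separate
  cells_p <- quantify_cells(psms, "peptide")
  expect_equal(nrow(cells_p), 2)
  expect_setequal(cells_p$anchor, c("EEQYNSTYR@176", "GEEQYNSTYR@175"))
})

test_that("unglycosylated peptides anchor to known glycosites they span", {
  psms <- dplyr::bind_rows(
    psm(glycan = "HexNAc(4)Hex(3)Fuc(1)", area = 3e6),
    psm(glycan = "HexNAc(2)Hex(3)", area = 1e6, scan = 1002L,
        calc_mz = 752.2),
    psm(glycan = "", area = 4e6, scan = 1003L, calc_mz = 520.1),
    # unglycosylated peptide elsewhere in the protein: no known site spanned
    psm(glycan = "", seq = "LLDNWDSVTSTFSK", pep_start = 20L, area = 9e6,
        scan = 1004L, calc_mz = 800.0))
  cells <- quantify_cells(psms, "site")
  expect_equal(nrow(cells), 3)  # two glycoforms + unglycosylated at N180
  with_unglyc <- cells[cells$glycan == "", ]
  expect_equal(with_unglyc$auc, 4e6)
  expect_equal(with_unglyc$anchor, "N180")

  # worked proportions: {A 3e6, B 1e6, unglyc 4e6}
  a <- cells[cells$glycan == "HexNAc(4)Hex(3)Fuc(1)", ]
  expect_equal(a$proportion_without, 0.75)
  expect_equal(a$proportion_with, 0.375)
  expect_equal(unique(cells$occupancy), 0.5)
  expect_true(is.na(with_unglyc$proportion_without))
  expect_equal(with_unglyc$proportion_with, 0.5)
})

test_that("proportions normalise and occupancy is bounded", {
  # no unglycosylated form -> both proportion variants agree, occupancy 1
  psms <- dplyr::bind_rows(
    psm(glycan = "HexNAc(4)Hex(3)Fuc(1)", area = 3e6),
    psm(glycan = "HexNAc(2)Hex(3)", area = 1e6, scan = 1002L,
        calc_mz = 752.2))
  cells <- quantify_cells(psms, "site")
  expect_equal(sort(cells$proportion_with), c(0.25, 0.75))
  expect_equal(cells$proportion_with, cells$proportion_without)
  expect_equal(unique(cells$occupancy), 1.0)

  # single glycoform -> proportion 1 both ways
  single <- quantify_cells(psm(area = 5e5), "site")
  expect_equal(single$proportion_with, 1.0)
  expect_equal(single$proportion_without, 1.0)

  # randomized normalization property
  set.seed(13)
  for (rep in 1:10) {
    n <- sample(2:5, 1)
    forms <- c(replicate(n, format(as_composition(random_counts()))), "")
    many <- dplyr::bind_rows(lapply(seq_along(forms), function(i) {
      psm(glycan = forms[[i]], area = runif(1, 1e5, 1e7),
          scan = 1000L + i, calc_mz = 600 + i)
    }))
    cells <- quantify_cells(many, "site")
    expect_equal(sum(cells$proportion_with), 1, tolerance = 1e-9)
    expect_equal(sum(cells$proportion_without, na.rm = TRUE), 1,
                 tolerance = 1e-9)
    occ <- unique(cells$occupancy)
    expect_true(occ >= 0 && occ <= 1)
  }
})

test_that("the wide table has sample blocks, blanks for unobserved cells", {
  psms <- dplyr::bind_rows(
    psm(sample = "s1", glycan = "HexNAc(4)Hex(3)Fuc(1)", area = 3e6),
    psm(sample = "s1", glycan = "HexNAc(2)Hex(3)", area = 1e6,
        scan = 1002L, calc_mz = 752.2),
    psm(sample = "s1", glycan = "", area = 4e6, scan = 1003L,
        calc_mz = 520.1),
    psm(sample = "s2", glycan = "HexNAc(4)Hex(3)Fuc(1)", area = 2e6,
        scan = 2001L))
  cells <- quantify_cells(psms, "site")
  wide <- build_wide_table(cells, samples = c("s1", "s2"))
  expect_equal(nrow(wide), 3)   # 2 glycoforms + unglycosylated
  expect_equal(names(wide)[1:4], c("master_id", "protein", "anchor",
                                   "glycan"))
  expect_setequal(
    setdiff(names(wide), c("master_id", "protein", "anchor", "glycan")),
    as.vector(outer(c("auc", "proportion_with", "proportion_without"),
                    c("s1", "s2"), paste, sep = ".")))
  # unglycosylated row first, then compositions
  expect_equal(wide$glycan[1], "")
  # key absent from sample 2 -> NA, not zero
  expect_true(is.na(wide$auc.s2[wide$glycan == "HexNAc(2)Hex(3)"]))
  expect_equal(wide$proportion_with.s2[
    wide$glycan == "HexNAc(4)Hex(3)Fuc(1)"], 1.0)

  # protein name comes only from the offline map; blank when unknown
  expect_equal(unique(wide$protein), "")
  named <- build_wide_table(cells, protein_names = c(P10001 = "IgG1"),
                            samples = c("s1", "s2"))
  expect_equal(unique(named$protein), "IgG1")

  empty <- build_wide_table(cells[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("peptide and site mode agree for one-site peptides", {
  set.seed(17)
  psms <- dplyr::bind_rows(lapply(1:3, function(i) {
    dplyr::bind_rows(
      psm(seq = c("EEQYNSTYR", "LVNATSAK", "GTNGTSR")[i],
          pep_start = c(176L, 118L, 76L)[i],
          site_prot = c(180L, 120L, 78L)[i],
          master_id = c("P1", "P1", "P2")[i],
          glycan = "HexNAc(2)Hex(3)", calc_mz = 700 + i,
          area = runif(1, 1e5, 1e7), scan = 1000L + 2L * i),
      psm(seq = c("EEQYNSTYR", "LVNATSAK", "GTNGTSR")[i],
          pep_start = c(176L, 118L, 76L)[i],
          master_id = c("P1", "P1", "P2")[i],
          glycan = "", calc_mz = 500 + i,
          area = runif(1, 1e5, 1e7), scan = 1001L + 2L * i))
  }))
  site_cells <- quantify_cells(psms, "site")
  pep_cells <- quantify_cells(psms, "peptide")
  expect_equal(nrow(site_cells), nrow(pep_cells))
  key <- function(df) df[order(df$master_id, df$anchor_sort, df$glycan),
                         c("proportion_with", "proportion_without",
                           "occupancy", "auc")]
  expect_equal(key(site_cells), key(pep_cells))
})
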