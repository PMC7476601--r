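# Glycan composition parsing, rendering, mass calculation and site
# assignment.

test_that("composition strings parse to the expected counts", {
  c1 <- parse_glycan_composition("HexNAc(5)Hex(6)NeuAc(3)")
  expect_equal(unclass(c1)[["HexNAc"]], 5L)
  expect_equal(unclass(c1)[["Hex"]], 6L)
  expect_equal(unclass(c1)[["NeuAc"]], 3L)
  expect_equal(unclass(c1)[["Fuc"]], 0L)

  # blank means unglycosylated
  expect_true(is_unglycosylated(parse_glycan_composition("")))
  expect_true(is_unglycosylated(parse_glycan_composition("   ")))

  # several glycans on one row, comma or semicolon separated
  multi <- parse_glycans("HexNAc(2)Hex(3); HexNAc(1)")
  expect_length(multi, 2)
  expect_equal(format(multi[[2]]), "HexNAc(1)")

  # dHex is a synonym for Fuc, names are case-insensitive
  expect_equal(format(parse_glycan_composition("hexnac(4)hex(3)dHex(1)")),
               "HexNAc(4)Hex(3)Fuc(1)")
})

test_that("malformed composition strings raise informative parse errors", {
  expect_error(parse_glycan_composition("HexNAc(5)Hex"),
               class = "glycoquant_parse_error")
  expect_error(parse_glycan_composition("Foo(2)"),
               class = "glycoquant_parse_error", regexp = "Foo")
  expect_error(parse_glycan_composition("HexNAc(-1)"),
               class = "glycoquant_parse_error", regexp = "[Nn]egative")
  expect_error(parse_glycan_composition("HexNAc()"),
               class = "glycoquant_parse_error")
})

test_that("canonical rendering is order-stable and round-trips", {
  # same multiset, different input order -> identical canonical strings
  a <- glycan_composition(NeuAc = 1, Hex = 5, HexNAc = 4)
  b <- glycan_composition(HexNAc = 4, NeuAc = 1, Hex = 5)
  expect_identical(format(a), format(b))
  expect_identical(format(a), "HexNAc(4)Hex(5)NeuAc(1)")

  set.seed(42)
  for (i in 1:25) {
    comp <- as_composition(random_counts())
    expect_identical(parse_glycan_composition(format(comp)), comp)
  }
})

test_that("composition mass matches the elemental-formula oracle", {
  expect_equal(composition_mass(glycan_composition(HexNAc = 2, Hex = 3)),
               oracle_glycan_mass(c(HexNAc = 2, Hex = 3)), tolerance = 1e-9)
  # values at the precision the field quotes them
  expect_equal(composition_mass(glycan_composition(HexNAc = 2, Hex = 3)),
               892.3172, tolerance = 1e-4)
  expect_equal(
    composition_mass(glycan_composition(HexNAc = 4, Hex = 3, Fuc = 1)),
    1444.5339, tolerance = 1e-4)
  expect_identical(composition_mass(glycan_composition()), 0)
})

test_that("composition mass is additive over composition union", {
  set.seed(7)
  for (i in 1:30) {
    ca <- random_counts()
    cb <- random_counts()
    joint <- tapply(c(ca, cb), names(c(ca, cb)), sum)
    expect_equal(
      composition_mass(as_composition(ca)) +
        composition_mass(as_composition(cb)),
      composition_mass(as_composition(joint)),
      tolerance = 1e-9)
  }
})

test_that("glycans are assigned to the residue whose delta matches", {
  p <- parse_byonic_peptide("R.EEQYN[+1444.5339]STYR.V", start = 176)
  res <- assign_glycan_sites(
    p, parse_glycans("HexNAc(4)Hex(3)Fuc(1)"), tol = 0.05)
  expect_equal(res$peptide_pos, 5L)
  expect_equal(res$protein_pos, 180L)

  # non-glycan modifications are untouched and retained
  p2 <- parse_byonic_peptide("K.N[+892.3172]VS[+15.9949]VK.R")
  res2 <- assign_glycan_sites(p2, parse_glycans("HexNAc(2)Hex(3)"),
                              tol = 0.05)
  expect_equal(res2$peptide_pos, 1L)
  expect_true(is.na(res2$protein_pos))
  remaining <- attr(res2, "non_glycan_mods")
  expect_equal(remaining$delta, 15.9949)

  # no glycans -> empty assignment, all mods retained
  res3 <- assign_glycan_sites(p2, list(glycan_composition()), tol = 0.05)
  expect_equal(nrow(res3), 0)
  expect_equal(nrow(attr(res3, "non_glycan_mods")), 2)
})

test_that("unassignable and ambiguous glycans raise typed errors", {
  p <- parse_byonic_peptide("K.NVSVK.R")  # no mods at all
  expect_error(
    assign_glycan_sites(p, parse_glycans("HexNAc(2)Hex(3)")),
    class = "glycoquant_unassignable_error")

  # two residues carrying the identical delta: exact tie -> ambiguity
  tie <- parse_byonic_peptide("K.N[+892.3172]VN[+892.3172]SK.R")
  expect_error(
    assign_glycan_sites(tie, parse_glycans("HexNAc(2)Hex(3)")),
    class = "glycoquant_ambiguous_site_error")

  # a closer delta wins when both are inside the tolerance
  near <- parse_byonic_peptide("K.N[+892.3100]VN[+892.3170]SK.R")
  res <- assign_glycan_sites(near, parse_glycans("HexNAc(2)Hex(3)"),
                             tol = 0.05)
  expect_equal(res$peptide_pos, 3L)
})

test_that("site assignment is invariant to mod order and decoy mods", {
  set.seed(11)
  cases <- simulate_assignment_cases(n = 60, seed = 11)
  for (i in seq_len(nrow(cases))) {
    p <- cases$peptide[[i]]
    res <- assign_glycan_sites(p, cases$glycan[i], tol = 0.05)
    expect_equal(res$peptide_pos, cases$true_pos[[i]])

    # shuffling the modification list must not change the assignment
    p_shuf <- p
    perm <- sample(nrow(p$mods))
    p_shuf$mods <- p$mods[perm, , drop = FALSE]
    res_shuf <- assign_glycan_sites(p_shuf, cases$glycan[i], tol = 0.05)
    expect_equal(res_shuf$peptide_pos, res$peptide_pos)
  }
})
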