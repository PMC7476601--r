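# In-code PSM fixtures for the quantification tests: rows in the shape
# produced by assign_psm_sites(), built directly so each test controls the
# exact areas and keys.

psm <- function(sample = "s1", master_id = "P10001", seq = "EEQYNSTYR",
                pep_start = 176L, glycan = "HexNAc(4)Hex(3)Fuc(1)",
                calc_mz = 1029.42, site_prot = 180L, site_res = "N",
                area = 1e6, score = 400, scan = 1000L) {
  tibble::tibble(
    sample = sample, master_id = master_id, seq = seq,
    pep_start = as.integer(pep_start), glycan = glycan, calc_mz = calc_mz,
    site_prot = if (nzchar(glycan)) as.integer(site_prot) else NA_integer_,
    site_res = if (nzchar(glycan)) site_res else NA_character_,
    area = area, score = score, scan = as.integer(scan))
}

quantify_cells <- function(psms, mode = "site") {
  compute_proportions(aggregate_auc(select_unique_psms(psms, mode), mode))
}
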