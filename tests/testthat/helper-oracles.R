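# Independent oracles used across tests. These never call package internals.

# Elemental-formula glycan mass oracle: monoisotopic atom masses summed over
# each residue's formula (HexNAc C8H13NO5, Hex C6H10O5, Fuc C6H10O4,
# NeuAc C11H17NO8, NeuGc C11H17NO9, Pent C5H8O4, Sulfo SO3, Phospho HPO3).
oracle_atoms <- c(C = 12, H = 1.0078250319, N = 14.0030740052,
                  O = 15.9949146221, S = 31.97207069, P = 30.97376151)

oracle_formulas <- list(
  HexNAc  = c(C = 8, H = 13, N = 1, O = 5),
  Hex     = c(C = 6, H = 10, O = 5),
  Fuc     = c(C = 6, H = 10, O = 4),
  NeuAc   = c(C = 11, H = 17, N = 1, O = 8),
  NeuGc   = c(C = 11, H = 17, N = 1, O = 9),
  Pent    = c(C = 5, H = 8, O = 4),
  Sulfo   = c(S = 1, O = 3),
  Phospho = c(H = 1, P = 1, O = 3))

oracle_residue_mass <- function(name) {
  f <- oracle_formulas[[name]]
  sum(oracle_atoms[names(f)] * f)
}

# counts: named integer vector (monosaccharide -> count)
oracle_glycan_mass <- function(counts) {
  sum(vapply(names(counts), oracle_residue_mass, numeric(1)) * counts)
}

# Closed-form pooled-variance (Student) two-sample t statistic and p value.
oracle_student_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, p = 2 * pt(-abs(t), df = na + nb - 2))
}

# Random composition over the full monosaccharide alphabet.
random_counts <- function(max_count = 6) {
  names <- c("HexNAc", "Hex", "Fuc", "NeuAc", "NeuGc", "Pent", "Sulfo",
             "Phospho")
  n <- sample(1:4, 1)
  chosen <- sample(names, n)
  setNames(sample(1:max_count, n, replace = TRUE), chosen)
}

as_composition <- function(counts) {
  do.call(glycan_composition, as.list(counts))
}
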