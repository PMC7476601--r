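# Glycan monosaccharide compositions and theoretical monoisotopic masses.
#
# A composition is a multiset of monosaccharide residue classes; its mass is
# the sum of residue (dehydrated) monoisotopic masses, i.e. the delta mass the
# glycan adds to a peptide. The residue mass table is fixed here; values are
# the standard monoisotopic residue masses derived from the elemental formulas
# (HexNAc C8H13NO5, Hex C6H10O5, Fuc C6H10O4, NeuAc C11H17NO8, NeuGc C11H17NO9,
# Pent C5H8O4, Sulfo SO3, Phospho HPO3).

# Canonical ordering: HexNAc, Hex, Fuc, NeuAc, NeuGc, then the rest
# alphabetically. Equal compositions must render to identical strings.
MONOSACCHARIDE_MASSES <- c(
  HexNAc  = 203.079372530,
  Hex     = 162.052823429,
  Fuc     = 146.057908807,
  NeuAc   = 291.095416524,
  NeuGc   = 307.090331146,
  Pent    = 132.042258744,
  Phospho = 79.966330408,
  Sulfo   = 79.956814556
)

MONOSACCHARIDE_SYNONYMS <- c(dhex = "Fuc")

#' Monosaccharide residue mass table
#'
#' Monoisotopic residue masses (Da) used for theoretical glycan mass
#' calculation, named by monosaccharide class in canonical order.
#'
#' @return A named numeric vector.
#' @export
#' @examples
#' monosaccharide_masses()[["HexNAc"]]
monosaccharide_masses <- function() MONOSACCHARIDE_MASSES

# Resolve a user-supplied monosaccharide name (case-insensitive, synonyms
# allowed) to its canonical name, or NA if unknown.
.resolve_mono <- function(name) {
  lw <- tolower(name)
  canon <- names(MONOSACCHARIDE_MASSES)
  hit <- match(lw, tolower(canon))
  out <- canon[hit]
  syn <- MONOSACCHARIDE_SYNONYMS[lw]
  out[is.na(out) & !is.na(syn)] <- syn[is.na(out) & !is.na(syn)]
  out
}

#' Construct a glycan composition
#'
#' A `glycan_composition` is a named integer vector over all supported
#' monosaccharide classes in canonical order. An all-zero composition denotes
#' the unglycosylated form and renders as the empty string.
#'
#' @param ... Named non-negative integer counts, e.g. `HexNAc = 4, Hex = 3`.
#'   Names are matched case-insensitively; `dHex` is accepted for `Fuc`.
#' @return A `glycan_composition` object.
#' @export
#' @examples
#' glycan_composition(HexNAc = 4, Hex = 3, Fuc = 1)
glycan_composition <- function(...) {
  counts <- c(...)
  if (is.null(counts)) counts <- integer(0)
  full <- setNames(rep(0L, length(MONOSACCHARIDE_MASSES)),
                   names(MONOSACCHARIDE_MASSES))
  if (length(counts)) {
    if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
      abort("All monosaccharide counts must be named.",
            class = "glycoquant_parse_error")
    }
    canon <- .resolve_mono(names(counts))
    if (anyNA(canon)) {
      abort(sprintf("Unknown monosaccharide name(s): %s",
                    paste(names(counts)[is.na(canon)], collapse = ", ")),
            class = "glycoquant_parse_error")
    }
    if (any(counts < 0) || any(counts != round(counts))) {
      abort("Monosaccharide counts must be non-negative integers.",
            class = "glycoquant_parse_error")
    }
    for (i in seq_along(counts)) {
      full[[canon[i]]] <- full[[canon[i]]] + as.integer(counts[[i]])
    }
  }
  structure(full, class = "glycan_composition")
}

#' @export
format.glycan_composition <- function(x, ...) {
  nz <- x[x > 0]
  if (!length(nz)) return("")
  paste0(names(nz), "(", unclass(nz), ")", collapse = "")
}

#' @export
print.glycan_composition <- function(x, ...) {
  s <- format(x)
  cat("<glycan_composition> ", if (nzchar(s)) s else "(unglycosylated)", "\n",
      sep = "")
  invisible(x)
}

#' @export
as.character.glycan_composition <- function(x, ...) format(x)

#' Is a composition the unglycosylated (all-zero) form?
#'
#' @param x A `glycan_composition`.
#' @return Logical scalar.
#' @export
is_unglycosylated <- function(x) {
  stopifnot(inherits(x, "glycan_composition"))
  all(unclass(x) == 0L)
}

#' Parse glycan composition strings
#'
#' Parses the long-form composition dialect used in Byonic's glycan column,
#' e.g. `"HexNAc(4)Hex(3)Fuc(1)"`. Several glycans on one row may be separated
#' by commas or semicolons; one composition is returned per glycan token
#' group. Blank input denotes the unglycosylated form and yields a single
#' all-zero composition.
#'
#' @param text A single glycan string (possibly empty).
#' @return A list of `glycan_composition` objects (length >= 1).
#' @export
#' @examples
#' parse_glycans("HexNAc(5)Hex(6)NeuAc(3)")
#' parse_glycans("")  # unglycosylated
parse_glycans <- function(text) {
  stopifnot(length(text) == 1)
  if (is.na(text) || !nzchar(trimws(text))) {
    return(list(glycan_composition()))
  }
  groups <- strsplit(text, "[,;]")[[1]]
  groups <- trimws(groups)
  groups <- groups[nzchar(groups)]
  lapply(groups, .parse_one_composition)
}

.parse_one_composition <- function(group) {
  token_re <- "([A-Za-z]+)\\((-?[0-9]+)\\)"
  m <- stringr::str_match_all(group, token_re)[[1]]
  residue <- stringr::str_remove_all(group, token_re)
  residue <- gsub("\\s+", "", residue)
  if (nzchar(residue) || nrow(m) == 0) {
    abort(sprintf("Malformed glycan composition near \"%s\" in \"%s\"",
                  if (nzchar(residue)) residue else group, group),
          class = "glycoquant_parse_error")
  }
  counts <- as.integer(m[, 3])
  if (any(counts < 0)) {
    abort(sprintf("Negative monosaccharide count in \"%s\"", group),
          class = "glycoquant_parse_error")
  }
  names(counts) <- m[, 2]
  do.call(glycan_composition, as.list(counts))
}

#' Parse a single glycan composition
#'
#' Like [parse_glycans()] but requires the text to describe exactly one
#' glycan.
#'
#' @inheritParams parse_glycans
#' @return A `glycan_composition`.
#' @export
parse_glycan_composition <- function(text) {
  out <- parse_glycans(text)
  if (length(out) != 1) {
    abort(sprintf("Expected a single glycan composition, got %d in \"%s\"",
                  length(out), text),
          class = "glycoquant_parse_error")
  }
  out[[1]]
}

#' Theoretical monoisotopic mass of a glycan composition
#'
#' Sum over monosaccharide classes of count times monoisotopic residue mass.
#' The all-zero (unglycosylated) composition has mass 0. Mass is additive over
#' composition union.
#'
#' @param x A `glycan_composition`.
#' @return Mass in Da (numeric scalar).
#' @export
#' @examples
#' composition_mass(glycan_composition(HexNAc = 2, Hex = 3))  # 892.3172
composition_mass <- function(x) {
  stopifnot(inherits(x, "glycan_composition"))
  sum(unclass(x) * MONOSACCHARIDE_MASSES[names(x)])
}
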