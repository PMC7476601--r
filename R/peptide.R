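# Byonic-style modified peptide strings and glycosylation-site assignment.
#
# Byonic prints peptides as "X.SEQ.Z" where X/Z are the flanking residues (or
# "-" at protein termini) and modified residues carry a bracketed delta mass,
# e.g. "R.EEQYN[+1444.5339]STYR.V". The export never says which modification a
# bracket is; glycans are recovered by matching each bracket's delta mass to
# the theoretical mass of a composition from the glycan column.

AMINO_ACIDS <- "ACDEFGHIKLMNPQRSTVWY"

#' Parse a Byonic-style modified peptide string
#'
#' @param text Peptide string in `"X.SEQ.Z"` form with optional bracketed
#'   delta masses (`"[+15.9949]"`, `"[-17.0265]"`) following modified
#'   residues. Flanks may be `"-"` at protein termini.
#' @param start 1-based position of the first peptide residue in the protein,
#'   or `NA` when unknown.
#' @return A `modified_peptide`: list with `flank_n`, `sequence`, `flank_c`,
#'   `mods` (tibble of 1-based `position` over unmodified residues and
#'   `delta`), and `start`.
#' @export
#' @examples
#' parse_byonic_peptide("R.EEQYN[+1444.5339]STYR.V", start = 176)
parse_byonic_peptide <- function(text, start = NA_integer_) {
  stopifnot(length(text) == 1)
  text <- trimws(text)
  m <- stringr::str_match(text, "^(.|-)\\.(.*)\\.(.|-)$")
  if (is.na(m[1, 1]) || !nzchar(m[1, 3])) {
    abort(sprintf("Peptide string \"%s\" is not in X.SEQ.Z form", text),
          class = "glycoquant_parse_error")
  }
  body <- m[1, 3]
  tokens <- stringr::str_match_all(
    body, "\\[([+-]?[0-9]+(?:\\.[0-9]+)?)\\]|([A-Za-z])")[[1]]
  consumed <- paste0(tokens[, 1], collapse = "")
  if (!identical(consumed, body)) {
    abort(sprintf("Unparseable modification syntax in peptide \"%s\"", text),
          class = "glycoquant_parse_error")
  }
  pos <- 0L
  seq_chars <- character(0)
  mod_pos <- integer(0)
  mod_delta <- numeric(0)
  for (i in seq_len(nrow(tokens))) {
    if (!is.na(tokens[i, 3])) {
      ch <- toupper(tokens[i, 3])
      if (!grepl(ch, AMINO_ACIDS, fixed = TRUE)) {
        abort(sprintf("Non-amino-acid residue \"%s\" in peptide \"%s\"",
                      ch, text),
              class = "glycoquant_parse_error")
      }
      pos <- pos + 1L
      seq_chars <- c(seq_chars, ch)
    } else {
      if (pos == 0L) {
        abort(sprintf("Modification before first residue in \"%s\"", text),
              class = "glycoquant_parse_error")
      }
      mod_pos <- c(mod_pos, pos)
      mod_delta <- c(mod_delta, as.numeric(tokens[i, 2]))
    }
  }
  if (pos == 0L) {
    abort(sprintf("Empty peptide sequence in \"%s\"", text),
          class = "glycoquant_parse_error")
  }
  structure(
    list(
      flank_n = m[1, 2],
      sequence = paste0(seq_chars, collapse = ""),
      flank_c = m[1, 4],
      mods = tibble(position = mod_pos, delta = mod_delta),
      start = as.integer(start)
    ),
    class = "modified_peptide"
  )
}

#' @export
format.modified_peptide <- function(x, ...) {
  chars <- strsplit(x$sequence, "")[[1]]
  if (nrow(x$mods)) {
    ins <- split(sprintf("[%+.4f]", x$mods$delta), x$mods$position)
    for (p in names(ins)) {
      i <- as.integer(p)
      chars[i] <- paste0(chars[i], paste0(ins[[p]], collapse = ""))
    }
  }
  paste0(x$flank_n, ".", paste0(chars, collapse = ""), ".", x$flank_c)
}

#' @export
print.modified_peptide <- function(x, ...) {
  cat("<modified_peptide> ", format(x),
      if (!is.na(x$start)) sprintf(" (start %d)", x$start), "\n", sep = "")
  invisible(x)
}

#' Render a modified peptide back to Byonic string form
#'
#' Delta masses are printed with sign and four decimals, the precision Byonic
#' exports use.
#'
#' @param p A `modified_peptide`.
#' @return Character scalar.
#' @export
render_byonic_peptide <- function(p) {
  stopifnot(inherits(p, "modified_peptide"))
  format(p)
}

#' Assign glycans to residues by delta-mass matching
#'
#' For each glycan composition, finds the peptide modification whose delta
#' mass lies within `tol` of the composition's theoretical mass; that residue
#' is the glycosylation site. Modifications not matching any glycan mass
#' (oxidation, deamidation, carbamidomethyl, pyro-Glu, ...) are left as
#' non-glycan modifications. When two modifications both fall within `tol`,
#' the closer delta wins; an exact tie is an error.
#'
#' @param p A `modified_peptide`.
#' @param glycans List of `glycan_composition` objects (all-zero entries are
#'   ignored). Each glycan is expected at most once per peptide.
#' @param tol Delta-mass tolerance in Da (> 0). Byonic prints deltas rounded
#'   to 3-4 decimals, so exact equality is unsafe; default 0.05.
#' @return A tibble with one row per glycan: `glycan` (canonical string),
#'   `composition` (list), `peptide_pos`, `protein_pos` (NA when the peptide
#'   start is unknown). Attribute `non_glycan_mods` holds the unmatched
#'   modifications.
#' @export
assign_glycan_sites <- function(p, glycans, tol = 0.05) {
  stopifnot(inherits(p, "modified_peptide"), tol > 0)
  glycans <- glycans[!vapply(glycans, is_unglycosylated, logical(1))]
  mods <- p$mods
  available <- rep(TRUE, nrow(mods))
  out <- vector("list", length(glycans))
  for (i in seq_along(glycans)) {
    g <- glycans[[i]]
    target <- composition_mass(g)
    diffs <- abs(mods$delta - target)
    diffs[!available] <- Inf
    cand <- which(diffs <= tol)
    if (length(cand) == 0) {
      abort(
        sprintf(
          "No modification within %.3g Da of glycan %s (%.4f Da) in peptide %s",
          tol, format(g), target, format(p)),
        class = "glycoquant_unassignable_error")
    }
    if (length(cand) > 1) {
      best <- min(diffs[cand])
      cand <- cand[diffs[cand] <= best + 1e-9]
      if (length(cand) > 1) {
        abort(
          sprintf(
            "Ambiguous site for glycan %s in peptide %s: positions %s tie at delta %.4f",
            format(g), format(p),
            paste(mods$position[cand], collapse = ", "), best),
          class = "glycoquant_ambiguous_site_error")
      }
    }
    pick <- cand[which.min(diffs[cand])]
    available[pick] <- FALSE
    out[[i]] <- tibble(
      glycan = format(g),
      composition = list(g),
      peptide_pos = mods$position[pick],
      protein_pos = if (is.na(p$start)) NA_integer_ else
        p$start + mods$position[pick] - 1L
    )
  }
  res <- if (length(out)) bind_rows(out) else
    tibble(glycan = character(0), composition = list(),
           peptide_pos = integer(0), protein_pos = integer(0))
  attr(res, "non_glycan_mods") <- mods[available, , drop = FALSE]
  res
}
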