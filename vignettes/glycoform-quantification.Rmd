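---
title: "Quantifying site-specific glycosylation from search-engine and precursor-area exports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying site-specific glycosylation from search-engine and precursor-area exports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycoquant)
```

## The problem

Protein glycosylation is heterogeneous in two distinct ways. A given
sequon may or may not carry a glycan at all (*macroheterogeneity*, or
occupancy), and when it does, different molecules of the same protein can
carry different glycan structures at that site (*microheterogeneity*).
Both axes respond to physiology and disease, so profiling them across
conditions is a common goal of quantitative glycoproteomics.

A typical data-dependent LC–MS/MS workflow leaves the analyst with two
half-answers. A glycopeptide search engine (Byonic and its kin) reports
*which* peptide carries *which* monosaccharide composition, with a score,
a scan number, and the modified peptide string — but no abundance. A
proteomics quantification tool (Proteome Discoverer's precursor-area
detector and its kin) reports the MS1 area under the curve (AUC) of each
fragmented precursor, keyed by scan number — but knows nothing about
glycans. `glycoquant` joins the two exports on the scan number and carries
the combined evidence through to per-sample glycoform proportion and
occupancy tables.

## The model

The quantitative model is deliberately simple and fully determined by the
data. Let $A(a, g, s)$ be the summed unique-PSM area for anchor $a$,
composition $g$ and sample $s$, where an anchor is either a glycosylated
protein residue (site mode) or a proteolytic peptide form (peptide mode),
and $g = 0$ denotes the unglycosylated form. Then

$$\pi_{\mathrm{with}}(g) = \frac{A(a,g,s)}{\sum_{g'} A(a,g',s)}, \qquad
\pi_{\mathrm{without}}(g) = \frac{A(a,g,s)}{\sum_{g' \neq 0} A(a,g',s)}, \qquad
\phi(a,s) = 1 - \pi_{\mathrm{with}}(0).$$

The central assumption is that glycosylation status does not
quantitatively affect detection: a site's glycoforms and its
unglycosylated peptide are taken to ionise and be sampled comparably, so
AUC ratios estimate molar ratios. This is a strong assumption — glycans
alter retention, charge and ionisation efficiency — and it is the reason
the proportions should be read as *relative* measures that are comparable
across samples for the same glycoform, rather than as absolute molar
fractions. Occupancy inherits the same caveat, and is additionally biased
wherever sample preparation enriched glycopeptides (the unglycosylated
form is then underrepresented and occupancy overestimated).

## From exports to unique PSMs

**Filtering.** Decoy entries (the `>Reverse` tag) and contaminants (a
configurable marker list, default `"Common contaminant"`) are removed
before anything else. The UniProtKB accession is extracted from the
protein name with the published accession regular expression; when no
accession matches, the whole name is kept, so custom constructs still
group correctly. Because isoform accessions share the parent accession,
isoform entries collapse into one master id. Rows with no recorded area
and rows below the score cutoff are dropped and counted; every stage's
removal count lands in the run log.

**Score cutoff (default 200).** This is the conventional threshold for a
confident glycopeptide identification on the Byonic score scale; it is a
user parameter, and the filter is monotone by construction (raising it
can only remove rows).

**Site assignment (tolerance 0.05 Da).** The export marks a modified
residue only with a bracketed delta mass. The theoretical monoisotopic
mass of the reported composition is computed from a fixed residue-mass
table (HexNAc 203.079373, Hex 162.052824, Fuc 146.057909, NeuAc
291.095417, NeuGc 307.090331, Pent 132.042259, Sulfo 79.956815, Phospho
79.966331 Da; values stored at full precision of the underlying elemental
formulas) and matched against the deltas. Exports print deltas rounded to
3–4 decimals, so exact equality would be brittle; 0.05 Da is narrow
enough to separate any two library compositions (the closest pair of
residue masses that could be confused, Sulfo vs Phospho, differs by
0.0095 Da and neither appears alone on a peptide in the supported path)
while absorbing printing error with orders of magnitude to spare. When
two modifications both fall inside the tolerance the closer delta wins;
an exact tie is reported as an ambiguity error and the row is excluded
and counted, never silently dropped. Peptides listing more than one
glycan are parsed but flagged and excluded from quantification: the
supported search configuration allows each glycan at most once per
peptide, and distributing one AUC over several sites would require an
arbitrary split.

**Deduplication.** Data-dependent acquisition happily fragments the same
precursor several times, so PSM counts exaggerate abundance. PSMs sharing
unmodified peptide sequence, composition, calculated m/z and — in site
mode — assigned site are grouped per sample; the highest-area PSM is the
group's unique PSM (ties break to higher score, then lower scan number,
making the choice deterministic and order-invariant). Non-glycan
modifications are ignored by the grouping on purpose: an oxidised and an
unoxidised copy of the same glycopeptide are the same glycoform.
Different charge states have different calculated m/z, so they survive as
separate unique PSMs — and are then *summed* by the aggregation step,
which is the only reading under which the glycoform total reflects all
the signal attributed to it.

**Anchoring.** In site mode, all peptide variants covering a site (missed
cleavages, ragged ends) merge into that site's total. Unglycosylated
peptides carry no site of their own; they contribute to occupancy at
every *known* glycosite they span, where "known" means observed
glycosylated somewhere in the experiment. Unglycosylated peptides
spanning no known site are not quantifiable anchors and are left out. In
peptide mode each proteolytic form is its own anchor, and the analogous
rule applies: only peptides seen glycosylated at least once are anchors.
This keeps the two modes exactly equivalent whenever every peptide
contains one site — a property the test suite checks — and keeps
occupancy a statement about glycosylation rather than about every peptide
the instrument happened to see.

## The statistics layer

Glycoform quantities are compared between two groups of replicate samples
with an unpaired two-tailed t-test per glycoform, Student's
equal-variance version by default (the usual choice at n = 3 per group)
with Welch's version behind a flag. No multiple-testing correction is
applied and missing values are not imputed: a glycoform absent from a
sample contributes nothing, and rows with fewer than two values in either
group are reported untested. Groups with zero variance (a real occurrence
with noiseless simulated data) yield a "degenerate variance" note rather
than a number. The default tested quantity is the proportion among
glycosylated forms ($\pi_{\mathrm{without}}$), the quantity usually
plotted as "relative glycoform abundance"; occupancy, the
unglycosylated-inclusive proportion, or raw AUC can be selected instead.
Proportions are tested untransformed. The suite verifies the
implementation against an independently coded pooled-variance closed form
and checks its type-I error calibration under a simulated null
(10,000 repetitions of N(0.5, 0.05²) in both groups at n = 3).

## The simulator

`generate_fixture_files()` writes the same two export dialects the
readers consume, from a planted truth model, so every pipeline claim is
testable against a known answer. Per sample it emits one primary PSM per
(glycoform, charge state) whose areas are exact shares of the site total
(split 70/30 over charges 2 and 3), then layers in the artefacts a real
export contains: duplicate PSMs of the same precursor with strictly
smaller areas (so max-area deduplication is exercised non-trivially, one
duplicate per precursor by default), decoy and contaminant rows, rows
with no recorded area, and rows below the score cutoff. Glycan deltas are
printed at four decimals, the dialect's precision, and therefore agree
with the theoretical composition masses well within the matching
tolerance. Identification scores for genuine rows are drawn from 250–600,
entirely above the default cutoff, so score randomness never perturbs
quantification.

The default truth model is three proteins with six sites, two to four
glycoforms per site plus an unglycosylated form, profiled in two
conditions (healthy, disease) with three replicates each; the disease
condition carries lower sialylation and lower occupancy at several sites.
Site totals sit in the 8×10⁶–3.2×10⁷ area range typical of mid-abundance
plasma glycopeptides. With the default noise level of zero, recovered
proportions equal planted ones exactly (floating-point summation aside),
which is the basis of the end-to-end tests; a multiplicative log-normal
noise term is available for exercising the statistics layer.

What the simulator does **not** emulate is worth stating: chimeric
spectra, co-eluting isobaric glycoforms, in-source fragmentation of
sialylated species, charge-state-dependent ionisation bias, retention
drift between runs, and incorrect identifications. Passing tests on
fixtures therefore demonstrate that the bookkeeping — joining, filtering,
assignment, deduplication, aggregation, normalization — is correct, not
that real exports are free of upstream error. Search output should be
curated before quantification, exactly as with any pipeline of this kind.

## Numerical and design choices

- Tables are written with numbers at six significant digits, so repeated
  runs on identical inputs produce byte-identical files; internal
  computation is double precision throughout.
- Deterministic ordering everywhere: unique-PSM selection sorts on a full
  key (area, score, scan within groups; sample, protein, sequence,
  composition, m/z, site across groups), so input row order never
  influences any output byte.
- Duplicate scan numbers inside the area export collapse to the maximum
  area, mirroring the max-area preference of deduplication and avoiding
  double counting a precursor; areas of exactly zero are treated as
  absent, since exporters write 0 for failed integrations.
- Canonical composition rendering (HexNAc, Hex, Fuc, NeuAc, NeuGc, then
  others alphabetically) guarantees equal compositions always collide in
  grouping keys; `dHex` is accepted as a synonym for `Fuc` and names are
  case-insensitive.
- Empty inputs yield empty, well-formed outputs and a warning, not an
  error; configuration problems (missing files, duplicate labels, unknown
  mode) fail before any output is written.
- Test and simulation problem sizes (six samples, ~140 quantified cells,
  200 randomized assignment cases, 10,000 null repetitions) were chosen
  as the smallest sizes at which each property is convincingly exercised.

## Known limitations

Composition is the finest glycan resolution: linkage, antennarity and
other topological detail are outside the identification evidence this
pipeline consumes, so isomeric structures fold into one glycoform.
Site assignment trusts a single delta-mass match within one peptide;
peptides with several plausible acceptor residues and one glycan are
assigned by the search engine's placement of the bracket, which CID/HCD
fragmentation often cannot confirm — peptide mode exists precisely for
that situation. Quantification is within-sample relative; no
between-protein or absolute quantification is attempted, and no
retention-time matching transfers identifications across runs.
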