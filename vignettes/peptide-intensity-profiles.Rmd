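---
title: "Methods: per-residue peptide intensity profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: per-residue peptide intensity profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepprofile)
```

## The model

`pepprofile` treats a bottom-up proteomics experiment as a table of peptide
observations: one row per (peptide form, replicate), carrying up to three
abundance metrics — PSM count (spectral counting), precursor intensity, and
LFQ peak area. Label-free quantification columns from every supported search
engine are read onto the `area` metric, since that is what they estimate.

The core quantity is the per-residue profile. For a sample group $g$ the
group value of a peptide is its metric summed over the group's replicates
(`combine = "sum"`), or that sum divided by the *number of replicates in the
group* (`combine = "mean"`). The mean deliberately counts non-observations
as zero, so that mean = sum / n and the two modes order residues
identically; averaging only over replicates where the peptide was detected
would instead up-weight sporadically observed peptides. This is a design
choice: search engines do not distinguish "absent" from "not sampled", and
the package follows the zero-signal reading throughout (missing and blank
metric cells are likewise read as 0, not NA).

Each peptide is placed at **every** exact-substring occurrence on the
target, overlapping occurrences included, and each placement contributes the
peptide's full group value to every residue it covers. Splitting the value
across placements was rejected because it would make the stacked-peptide
and uniqueness views inconsistent with the trace (a peptide's row colour
would no longer be its abundance). Matching is exact after uppercasing, with
no isoleucine/leucine equivalence — exactness is verifiable, and I/L
folding would silently merge distinct database entries. Modified and
unmodified forms of the same bare sequence are aggregated for profiles; PTM
positions are carried separately and only surface in annotation tracks.

Assumptions worth stating plainly: the profile is a *visualization*
statistic, not an estimator with error bars. Summing intensities of
overlapping peptides double-counts shared residues by construction — that
is what makes coverage "hot spots" visible — so profile heights are
comparable along one protein within one metric, not across proteins or
metrics. No normalization across runs, protein inference, or FDR filtering
is applied; the package expects its input tables to be already filtered to
the user's satisfaction.

## Comparisons and their degenerate cases

Difference and fold-change views compare two group profiles residue by
residue. Fold change divides two non-negative numbers, so three degenerate
cases need conventions, all of which are displayed rather than dropped:

* signal only in the numerator → positive infinite, drawn at
  1.25 × the maximum finite plotted value (in green);
* signal only in the control → negative infinite, drawn at $y = 0$
  (in red);
* signal in neither → undefined, drawn as a gap. Inventing a number here
  (0, 1, NA-as-zero) would fabricate signal, so the residue is simply not
  plotted.

When a fold-change profile has *no* finite residue, the 1.25 × rule has no
reference; the package uses 1.25 × 1 so that the display remains
deterministic. On logarithmic axes, zero values become gaps for the same
reason.

## The peptide volcano

For two groups the package computes, per distinct bare peptide sequence,
the log2 fold change of the mean metric over nonzero replicate
observations, and a two-sided Welch t-test on log2-transformed nonzero
values. The test is the package's own choice: Welch (unequal variances) is
the standard default for label-free peptide comparisons, the log2 transform
brings multiplicative noise close to normal, and `min_obs = 2` nonzero
observations per group is the smallest count for which a variance exists.
Peptides observed in exactly one group are flagged *infinite* instead of
tested; peptides reaching `min_obs` in one group but stuck at 1 ≤ n <
`min_obs` in the other are flagged *compromised*, and a switch controls
whether they are emitted at all, since their evidence is asymmetric.

Two numerical edge cases are defined explicitly. If both groups have zero
log2 variance and equal means, the package reports p = 1 (no evidence of
change); with zero variance and unequal means the Welch statistic is
undefined and p is reported as NA rather than an out-of-domain 0. No
multiple-testing correction is applied by default (an optional
Benjamini–Hochberg column is available); the plot is exploratory, and the
per-peptide test's statistical rigor should not be over-read — correlated
peptides from one protein are not independent tests.

## Annotations

Motif scanning reports **overlapping** matches by restarting the scan one
residue after each match start; standard regex engines skip overlaps, which
would hide the second site in a sequence like `NNSS`. The predefined
library covers the N-glycosylation sequon `N[^P][ST]` and protease sites
(tryptic K/R and chymotryptic F/W/Y, both excluding a following proline;
Glu-C E/D); the protease entries are point features at the residue
N-terminal to the cut. PTMs are lifted to protein coordinates as
`match_start + offset − 1`, once per placement, deduplicated across
replicates at 0.01 Da — two decimals is what the supported engines print,
so finer comparison would be false precision. The PTM dictionary's
deamidation entry is +0.98 Da, the monoisotopic Asn→Asp shift left by
PNGase F, and the glycosite report intersects deamidation events with
sequon intervals under that ±0.01 Da filter.

## Stacked layout

"Stacked" peptide rows are packed by a deterministic greedy first-fit:
matches sorted by start, then descending length, then sequence, each taking
the lowest level that keeps at least one free residue (`gap = 1`,
configurable) from the level's occupants. First-fit does not minimize the
number of levels in general; what the package guarantees — and what the
tests assert — is layout validity (the gap is respected on every level) and
determinism. Identical repeated placements necessarily land on distinct
levels. One row is laid out per peptide *occurrence*, not per distinct
peptide, so a repeated peptide is visibly repeated.

## The synthetic-data generator

`generate_fixture()` emulates the structure of a small label-free
experiment so that every module is testable without any external download:
random proteins over the 20-letter alphabet (default 3 entries of 150–250
residues, the first being the target), tryptic-like peptides (cut after
K/R, ≤ 2 missed cleavages, 5–30 residues, 40 per protein), two groups of
three replicates, and per-observation abundances drawn log-normally
(meanlog 14 ≈ 1.2 × 10⁶, sdlog 0.3 — a typical LFQ-like spread). A
`nonspecific` digestion mode samples uniform random substrings, mimicking
the dense overlapping coverage of HDX-style digests. Dropout defaults to 0
so that written files and ground truth agree exactly; it can be raised to
emulate missingness. Regional effects multiply the observations of every
target peptide whose interval *overlaps* the configured region — under
that convention every contribution to an in-region residue is scaled, so
the expected in-region fold change equals the configured effect exactly,
up to replicate noise. A companion `two_domain_fusion_fixture()` builds
the classic fusion-protein demonstration in which each group's peptides
are confined to one half of the sequence.

The generator writes the same observations in every supported dialect
(modified peptides rendered in parenthetical mass-delta notation), plus a
ground-truth profile computed by an independent naive per-residue scan.
What it does **not** emulate: retention times and spectra, charge states,
shared peptides engineered between proteins (they arise only by chance),
intensity-dependent missingness, batch effects, or FDR-controlled
identification error. Passing tests on these fixtures therefore
demonstrate correctness of the *computation*, not robustness to every
pathology of real data.

Problem sizes used by the test-suite and the acceptance script — hundreds
of observations per fixture, 100 seeded random cases for the brute-force
oracle comparisons, 6 replicates per group for effect recovery — were
chosen as the smallest sizes at which the stochastic properties are stable.

## Interfaces and conventions

Coordinates are 1-based inclusive everywhere, including exports. The
per-dialect header → field mapping ships as an editable CSV
(`inst/extdata/dialect_map.csv`) rather than code, because vendors rename
columns between versions; dialect auto-detection requires exactly one
dialect's signature to match and errors otherwise rather than guessing.
The generic CSV format is long (one row per peptide per sample) with
columns `peptide`, `sample`, and at least one of `psm`, `intensity`,
`area`, plus an optional `ptm` column of `offset:delta:name` triples —
long format makes regex-based sample grouping uniform across dialects.
Flanking-residue notation (`K.PEPTIDE.R`) is recognized by exactly one dot
on each side; anything else is treated as sequence and must validate as
residues. CSV exports carry `#`-prefixed metadata lines and numbers at 12
significant digits, so export → import → export is byte-identical.

## Known limitations

The uniqueness view tests substring sharing against the *supplied*
database only — a peptide unique within a reduced FASTA may not be unique
in the full proteome. Static PNG rendering replaces the interactive
hover/zoom of browser-based tools; the `peptides_at_position()` query and
the CSV exports are the scriptable equivalents. Isobaric labelling (iTRAQ/
TMT) and DIA quantities have no dedicated reader and would need to be
mapped onto the generic CSV by the user.
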