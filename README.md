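# pepprofile

Quantitative per-residue visualization of bottom-up proteomics data for a
single protein of interest.

Bottom-up proteomics identifies and quantifies peptides, not proteins, and a
protein's peptide evidence is rarely uniform across its sequence: domains,
proteoforms, modification sites and digestion behaviour all leave footprints
in where the signal lands. Standard sequence-coverage maps show *whether* a
residue was observed but not *how much* signal it carries. `pepprofile` turns
peptide-level database-search results (PEAKS, MSFragger/FragPipe, MaxQuant,
MetaMorpheus, Proteome Discoverer, or a generic CSV) plus a FASTA database
into per-residue intensity profiles, and builds the comparison, annotation
and layout views that practitioners use around them.

## The core quantity

For a target protein of length $L$ and a sample group $g$, every peptide $p$
observed in the experiment is mapped to all of its exact-substring placements
on the protein. Each residue $i$ is assigned

$$I_g(i) \;=\; \sum_{p,\;o \,:\, i \in [s_{p,o},\,e_{p,o}]} v_g(p)$$

the sum over peptide placements $o = [s_{p,o}, e_{p,o}]$ covering $i$ of the
peptide's group value $v_g(p)$ — its metric (PSM count, intensity, or LFQ
area) summed or averaged over the group's replicates (a replicate where the
peptide was not observed counts as 0 in the mean). Residues covered by no
peptide have $I_g(i) = 0$.

On top of the profile the package computes:

- **Sequence coverage** — percent of residues covered by ≥ 1 peptide.
- **Uniqueness classes** — each residue coloured by whether a covering
  peptide also occurs in another database entry (`shared_other`), repeats
  within the target (`repeated_within`), or neither (`unique`).
- **Group comparisons** — overlay, difference $I_a - I_{ctrl}$, and fold
  change $I_a / I_{ctrl}$ with explicit infinity handling: residues with
  signal only in the numerator are positive-infinite and drawn at 1.25× the
  maximum finite value (green); signal only in the control is
  negative-infinite, drawn at y = 0 (red); 0/0 is undefined and drawn as a
  gap.
- **Peptide volcano** — per peptide, log2 fold change of the mean metric
  over nonzero replicate observations and a two-sided Welch t-test on log2
  values (≥ 2 nonzero observations per group), with flags for peptides seen
  in only one group ("infinite") and peptides testable in only one group
  ("compromised").
- **Annotations** — sequence motifs located by regex with overlapping hits
  reported (predefined: the `N[^P][ST]` N-glycosylation sequon, tryptic
  K/R-not-before-P sites, chymotryptic and Glu-C sites) and search-reported
  PTMs lifted from peptide to protein coordinates; their intersection
  reports candidate glycosites (deamidation +0.98 Da inside a sequon).
- **Stacked peptides** — every peptide placement laid out greedily into
  non-overlapping levels, coloured by its metric value.

Every view renders to PNG (`render_png()` / `autoplot()`) and exports its
backing data as CSV (`export_csv()`).

## Worked example

The package ships a seeded generator that writes a complete synthetic
experiment — a FASTA database and one peptide table per supported dialect —
with known ground truth:

```r
library(pepprofile)

fx       <- generate_fixture(fixture_config(seed = 42), "demo")
proteome <- read_fasta(fx$paths$fasta)
tab      <- read_peptides(fx$paths$msfragger)   # dialect auto-detected
groups   <- resolve_sample_groups(tab, c(ctrl = "^ctrl_", trt = "^trt_"))

target <- proteome[1, ]
m      <- map_peptides(target, tab)
prof   <- residue_profile(target, m, tab, groups[groups$name == "ctrl", ], "area")
glance(prof)
#> # A tibble: 1 × 8
#>   accession group metric length covered coverage_percent       total       max
#>   <chr>     <chr> <chr>   <int>   <int>            <dbl>       <dbl>     <dbl>
#> 1 P00001    ctrl  area      198     198              100 2125487921. 23768688.
```

The 198-residue target is fully covered; `total` is the summed per-residue
area and `max` the hottest residue's value. A two-group peptide volcano from
the same table:

```r
v <- peptide_volcano(tab, groups, "area", matches = m)
glance(v)
#> # A tibble: 1 × 8
#>   group_a group_b metric n_peptides n_tested n_significant n_infinite
#> 1 ctrl    trt     area          104      104             4          0
tidy(v)[1:3, c("bare_sequence", "log2_fc", "p_value", "infinite")]
#> # A tibble: 3 × 4
#>   bare_sequence                 log2_fc p_value infinite
#> 1 ACCMQCCLFLTTFDQQAFDPMYTYEYMTK  -0.637   0.331 FALSE
#> 2 AIWIYWCYWMR                     0.227   0.422 FALSE
#> 3 AIWIYWCYWMRVILCETNYWHK         -0.404   0.134 FALSE
```

104 peptides were quantifiable in both groups; with no true effect in this
fixture, 4 reach p < 0.05 (about the 5% false-positive rate expected).
Render or export any view:

```r
render_png(prof, "ctrl_trace.png", annotations = list(find_motifs(target, "nglyco")))
export_csv(prof, "ctrl_trace.csv")
```

A command-line wrapper over the same functions lives at
`inst/cli/pepprofile` (subcommands `profile`, `stacked`, `unique`,
`coverage`, `compare`, `volcano`, `annotate`, `fixture`).

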