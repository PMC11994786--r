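---
title: "Methods: dual-tag AP-MS quantification, the three-control purge, and the switchable tag cassette"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-tag AP-MS quantification, the three-control purge, and the switchable tag cassette}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(RITEproteomics)
```

This vignette explains the statistical model behind the package, the
parameters that matter, what the synthetic-data generator does and does not
emulate, and the numerical conventions adopted where the procedure left a
choice open.

## The experimental design the package assumes

A RITE (Recombination-Induced Tag Exchange) knock-in allele carries a
3xHA epitope flanked by lox sites, followed by a V5 epitope; Cre expression
swaps the tag in a defined cell population. The analysis design pairs each
knock-in (TURNX) animal with a wild-type (WT) littermate (`couple`), and
pulls each animal's lysate down with anti-HA, anti-V5 and isotype IgG beads
in replicate. The default `StudyDesign()` — 4 couples x 2 genotypes x 3 IP
arms x 4 replicates = 96 fractions, 24 per couple — is the layout the
pipeline was validated on. Everything downstream is driven by the declared
(genotype, arm) groups of the sample sheet, never by column order.

For each tag the case group is (TURNX, tag arm) and there are exactly three
negative controls:

* (WT, same arm) — binders of the anti-tag antibody itself, present
  whether or not the bait is tagged;
* (TURNX, IgG) and (WT, IgG) — bead and isotype background.

The same-arm WT control is the one that matters most: antibody
cross-reactive proteins are genuinely enriched on their arm in *both*
genotypes, so both IgG comparisons flag them as significant and only the
same-arm comparison exposes them.

## Protein quantification: pairwise-ratio geometric median

For protein $P$ with peptides $k = 1 \dots K$, let $a_{ki}$ be the
intensities observed in case samples and $b_{kj}$ in control samples. Each
peptide observed on both sides contributes

$$ r_k = \operatorname{gmed}_{i,j}\left( a_{ki} / b_{kj} \right), \qquad
   R_P = \operatorname{gmed}_k (r_k), $$

where $\operatorname{gmed}$ is the geometric median. For positive scalars
the Euclidean geometric median degenerates to the ordinary median, so it is
computed as the median of log-ratios, exponentiated. Two conventions are
fixed deliberately:

* **Even counts** take the midpoint of the two central log-ratios — the
  geometric mean of the two central ratios. This makes inversion symmetry
  exact: $R(\text{case}, \text{ctrl}) \cdot R(\text{ctrl}, \text{case}) = 1$.
* **Cross-pair enumeration** (all $a_i/b_j$) rather than index-matched
  pairs, because replicates are unpaired across animals.

The rollup is scale-equivariant (multiplying every case intensity by $k$
multiplies the uncapped ratio by exactly $k$) and is property-tested against
a brute-force enumeration with an explicit sort-based median.

### Saturation and presence/absence conventions

Published AP-MS tables saturate: ratios are capped at 100 (floor 0.01) and
p-values are floored at 1e-17. `QuantConfig()` carries these constants.
Presence/absence is handled explicitly rather than by imputation: a protein
detected in at least `minPresentReplicates` (default 3) case fractions and
in **no** control fraction is a `CASE_ONLY` call reported at the ratio
ceiling with the floored p-value; the mirror case is `CONTROL_ONLY` at the
floor. The threshold of 3 guards presence calls against single-replicate
contamination; the underlying acquisition software's exact rule is not
public, so this is a package convention, configurable and documented.

## Significance: Welch t per control group, on mouse means

The purge tests log2 protein abundances (per-sample sums of peptide
intensities) of the case group against each control group separately with a
two-sided Welch (unequal-variance) t-test. Welch is chosen over the pooled
test because the three control groups differ in composition. Two replicate
units are offered:

* `MOUSE_MEAN` (default): the fractions of one animal are averaged on the
  log2 scale into one value — IP replicates of one lysate are not
  independent animals, so the default is the conservative unit (4 values
  per group under the default design);
* `FRACTION`: every fraction is an observation (16 per group), for users
  who regard the replicates as independent.

Degenerate cases follow the saturation conventions: two constant groups
with equal values give $p = 1$, with different values the floor; a protein
quantified in >= 3 case units and absent from a control group gets the
floored p (the presence-only convention); anything else with fewer than two
values in a group is untestable and excluded (counted in the run summary).
The closed-form Welch statistic is implemented directly because the stock
test errors on constant data, which the degenerate rules must handle; it is
verified against `stats::t.test` to 1e-10.

## The purge and its calibration

A protein detected in the case group is retained iff

* its ratio against the three control groups **pooled** is at least
  `minFold` (default 1: enrichment direction only), and
* the **maximum** of its three per-control p-values is at most `alpha`
  (default 0.05).

The printed tables of this kind of study report one ratio against a single
control denominator while the text demands three significance comparisons;
pooling the controls for the ratio and testing per group reproduces both.
No multiple-testing correction enters the decision, mirroring the stated
raw-p procedure; a Benjamini-Hochberg column is emitted for information.
Output ordering (descending ratio, then ascending p, then accession) is
fixed so reruns are byte-identical.

Two calibration properties are enforced by the test suite at the default
study conditions:

* **Null**: with no true enrichment anywhere (fold 1), the fraction of
  proteins surviving the full purge stays at or below `alpha`
  (20 simulation seeds).
* **Recovery**: at 8-fold enrichment with 4 replicates, >= 90% of the
  spiked core-complex and tag-specific proteins survive, per tag
  (10 seeds).

One property of the raw-p procedure deserves emphasis: for an antibody
cross-reactive binder the same-arm comparison is *null* (the protein is
equally enriched in both genotypes), so the procedure retains it whenever
that comparison lands below `alpha` by chance — about an `alpha`-sized
false-retention rate that no amount of data removes. The tests therefore
assert that every cross-reactive removal is attributable specifically to
the same-arm WT comparison and that the removal rate matches the
$1 - \alpha$ expectation, rather than a removal rate of exactly 100% that
the procedure cannot deliver.

## The synthetic-data generator

`simulateDataset()` draws peptide-level intensities for the whole design
with known ground truth. Its classes mirror the populations the purge must
separate: bead background (uniform across all fractions, 500 proteins),
anti-HA and anti-V5 cross-reactive binders (enriched on their arm in both
genotypes, 30 each), a core complex (enriched in the case group of both
tags, 11), tag-specific interactors (40 per tag), and optionally absent
proteins (never detected).

The intensity model is standard for label-free data: log-normal peptide
intensities around a class-and-group-dependent mean,

* baseline log2 intensity 20, protein-level spread (SD 1.5 log2 units) and
  peptide-level ionization spread (SD 1.0) shared across samples;
* biological coefficient of variation 0.25 on the natural scale
  (log2 SD $\sqrt{\ln(1 + 0.25^2)}/\ln 2 \approx 0.36$);
* true enrichment multiplies the mean by `foldEnrichment` (default 8,
  which places purged ratios in the ~2-100 range seen in published tables
  of this design);
* missingness is censoring at a detection floor (log2 16,
  missing-not-at-random) plus a 5% uniform dropout — this is what produces
  genuine presence-only proteins;
* peptides per protein are $1 + \mathrm{Poisson}(3)$, i.e. mean 4.

One global seed drives a single generator stream, so identical
configurations reproduce tables bit-for-bit. The generator does **not**
simulate spectra, retention times, shared/razor peptides, batch effects or
between-run normalization drift; passing tests demonstrate that the purge
logic and the rollup behave correctly under the assumed intensity model,
not that real acquisitions meet that model.

## The cassette model

The shipped 292-nt donor oligo encodes homology arms, a lox site, three HA
repeats with a stop, a second lox site, a 2-base linker and the V5 epitope
with its stop. Conventions:

* Coordinates are 1-based inclusive. Excision runs from lox start to lox
  start, retaining exactly one lox copy, which makes the arithmetic exact:
  the donor's sites start at 51 and 172, so recombination removes 121 nt.
* The 13-bp lox arms are mutual reverse complements, so an arm-based
  pattern (`arm5 + N8 + arm3`) cannot distinguish orientation
  structurally; each position is reported once, labelled by the strand on
  which the scan reads arm5 -> arm3, and the 8-bp spacer is exposed.
  Direct-vs-inverted classification for excision is decided from the
  spacers (equal = direct repeat; reverse-complementary = inverted,
  refused). The donor's spacer (GCCTACAT) is a variant of canonical loxP,
  which the arm-based detector finds without special-casing.
* The retained lox (34 nt) plus the linker (2 nt) is 12 codons, so the
  downstream tag stays in frame — translation from the first lox start
  yields the three HA nonamers before excision and the V5 peptide after.
* Genotyping sizes of the recombined allele are derived from printed
  anchors (WT 256 bp, knock-in 455 bp digesting to 317 + 138 bp with
  TaqαI, cut convention T^CGA) minus the excised length, deliberately
  avoiding any reconstruction of the unprinted genomic flanks: the WT
  amplicon plus the donor-derived insert over-determines the knock-in size
  by a few bases (the design likely reuses the original stop codon), so
  only excision-difference arithmetic, which is flank-independent, is
  modeled.

## Problem sizes and runtime choices

Validation uses the full 96-sample design with the default 651 proteins:
20 seeds for the null calibration, 10 for recovery, and 1000 random tables
for the rollup oracle — sizes at which every property is stable while the
whole suite completes in a few minutes on a single core. Unit tests use a
reduced protein panel with the same intensity model.

## Known limitations

* The t-test's replicate unit in the original acquisition software is
  undocumented; both offered units are reasonable, and they can disagree
  near the threshold.
* No between-sample normalization is applied before ratio computation; if
  loading differed systematically between runs, ratios absorb it.
* The purge inherits the raw-p procedure's `alpha`-level false retention
  of cross-reactive binders (see above) and of background proteins.
* Accession comparison is verbatim by default; the isoform-merging switch
  relies on a user-supplied accession-to-symbol map.
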