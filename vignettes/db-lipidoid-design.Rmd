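---
title: "Designing and screening degradable branched lipidoids in silico"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and screening degradable branched lipidoids in silico}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dblipidoid)
```

## The chemistry being modelled

Degradable branched (DB) lipidoids are ionizable lipids assembled by a
one-pot, two-step, three-component reaction. An amine headgroup first
opens two terminal alkyl epoxides under neat conditions; each
ring-opening is an SN2 attack of the amine nitrogen on the terminal,
less hindered CH2 carbon of the epoxide, so every body tail is attached
as N–CH2–CH(OH)–alkyl with a *secondary* alcohol. The two hydroxyls are
then acylated by acyl chlorides, each acylation forming one ester bond
and formally eliminating one HCl. The product is named `x-m-n`: amine
number `x`, body-tail carbons `m` (the full epoxide carbon count),
branch-tail carbons `n` (the full acyl carbon count *including* the
carbonyl carbon — this convention is required for the tail-carbon sums
used throughout).

Because the linkers are esters, the branch tails detach under
esterase-type hydrolysis. `degrade()` models this: each cleavage
consumes one water, releases one fatty acid and regenerates a hydroxyl;
cleaving both esters returns the aminoalcohol, the non-degradable
metabolite whose average mass (and its < 500 Da flag) `metabolite_mass()`
reports. Element and mass balance are exact by construction and are
enforced by tests over the full 500-member factorial:
amine + 2 epoxide + 2 acyl = product + 2 HCl, and
product + 2 H2O = aminoalcohol + 2 fatty acids.

All structures are handled as hydrogen-suppressed graphs; parsing,
canonicalization (stereochemistry-free — the products are racemic) and
SMARTS cross-checks go through Open Babel via ChemmineR/ChemmineOB.
Salt-form inputs are neutralized and stripped of counter-ions on load,
so registries always hold the free base. Masses come from the IUPAC
principal-isotope table (monoisotopic, used for MS comparison) and
conventional atomic weights (average, used for metabolite filtering and
formulation arithmetic).

## Building blocks and library designs

The default registry holds 20 amines, five linear alkyl epoxides
(C6–C14, even) and five linear saturated acyl chlorides (C6–C14, even).
Two canonical designs are provided: Library 1 fixes the headgroup at
amine 1 (3-(dimethylamino)-1-propylamine) and crosses all five body
tails with all five branch tails (25 lipidoids); Library 2 fixes the
tails at the optimal C10 body / C8 branch pair and varies all 20
headgroups (20 lipidoids, sharing 1-10-8 with Library 1, hence 44
unique candidates in the pooled screen). The full factorial crosses
everything (500 lipidoids).

Amine 1 is fully specified by the published description and amine 11
(1-(2-aminoethyl)pyrrolidine, C6H14N2) is pinned down by its class
(pyrrolidinyl, two-carbon spacer) together with the printed product
formula C42H82N2O4, which the enumerator reproduces. The structures of
the remaining amines are not printed in the main text; the package
ships curator-provided synthetic stand-ins
(`inst/extdata/amines_2_20_synthetic.csv`) chosen to realize the
published class composition — primary monoamines (2, 3, 6), hydrazines
(4, 5), diamines with ideal headgroups and two- or three-carbon spacers
(7, 9, 10, 12), diamines with non-ideal spacers or tertiary forms
(8, 13, 14, 15), and di-secondary diamines (16–20) — under the
constraint that every amine can attach exactly two body tails (a
requirement of the library design, operationalized as: total
substitutable N–H on sp3 non-amide nitrogens equals 2). Conclusions
that depend on these stand-ins (e.g. the pooled hit list) test the
classifier logic against the published class structure, not the
identity of the actual reagents.

## Descriptors and the potency rules

For a tail pair (m, n) the package computes the total carbon number
TC = m + n, the tail symmetry s = n/(m−2) and its deviation d = |s − 1|.
The −2 is applied exactly as defined with no structural
reinterpretation; s is displayed rounded to one decimal (1.7, 0.6, 3)
but every comparison uses the unrounded value. The headgroup classifier
counts primary/secondary/tertiary sp3 non-amide nitrogens, identifies
the tertiary form (dimethylamino = exactly two N-methyls;
diethylamino = exactly two N-ethyls; pyrrolidinyl = N in a saturated
all-carbon five-ring; anything else, including piperidinyl and
morpholino, is conservatively "other"), measures the carbon spacer
between the primary and tertiary nitrogen along the shortest bond path
(any heteroatom on the path disqualifies it) and flags hydrazines via
N–N bonds.

A candidate is predicted potent when all three structural criteria
hold: TC = 18; d ≤ `d_max`; and an efficacious headgroup (one primary
plus one ideal tertiary amine, spacer 2–3, no hydrazine). No numeric
symmetry cutoff is published, so `d_max` is a package decision exposed
in `rule_config()`. The default 1.0 admits the near-symmetric pairs
(d = 0, 0.4, 2/3) and rejects the strongly imbalanced 6/12 pair (d = 2);
any value in (2/3, 2) selects the same candidates on the shipped
registry, and 1.0 is the midpoint-stable choice on the log-deviation
scale. The continuous rank score d + 100·|TC−18| + 100·[headgroup fail]
orders candidates so that any criterion violation outranks any
compliant candidate; ties break lexicographically by name. Hit rates
are reported as round(100 · hits / unique candidates) after
deduplication by name.

## The packing parameter

The lipid shape statistic P = V/(A·L) is computed from a single
minimized conformer:

* **Embedding.** General-purpose 3D generators in this toolchain draw
  from a process-global random stream that cannot be seeded from R, so
  the package embeds deterministically itself: heavy atoms grow as a
  seeded self-avoiding walk on a tetrahedral (diamond) lattice, which
  gives ideal sp3 bond lengths (1.54 Å) and angles while the seeded
  choice among free lattice directions samples torsional space;
  hydrogens fill the remaining lattice directions. Rings are closed and
  sp2 centres relaxed by the subsequent minimization: up to 4000 steps
  of MMFF94 (Open Babel), which is deterministic for a fixed starting
  geometry. The same structure, seed and step count therefore always
  reproduce identical coordinates; different seeds give independent
  conformers.
* **V** is the van der Waals molecular volume: the union of atomic
  spheres (Bondi radii, hydrogens included) integrated on a grid with
  0.2 Å default spacing (halving the spacing changes V by under 1%;
  an exact two-sphere union is reproduced to 1%).
* **A** is the polar-head cross-section: the head atoms — the
  ionizable nitrogens, every heavy atom within two bonds of them, and
  the ester oxygens — are projected on the plane perpendicular to the
  first principal axis of the tail atoms, each contributing its vdW
  circle, and A is the convex-hull area of those circles. The head
  convention is a package choice (the literature convention behind
  printed P values is not restated in the source describing them) and
  both selections can be overridden.
* **L** is the mean through-space distance from each tail's attachment
  atom to its terminal carbon. Tails are found automatically: removing
  the head leaves components whose terminal carbons at graph distance
  ≥ 4 from the attachment each define one tail (four for a DB-lipidoid:
  two body, two branch; two for the dilinoleyl benchmark).

Because the published P values were obtained with a proprietary force
field and an unstated head convention, the package does not aim at
those numbers; the reproducible claim is the *ordering* — the branched
lead is more cone-shaped than the MC3 benchmark, with both above 1 —
which the acceptance test checks on medians over five seeds.

## The synthetic screen generator

`simulate_screen()` emulates the statistical structure of the
two-channel screen so that every analysis stage is testable without
animal or cell data. In vivo, log10 total flux is a background of 6.7
(below the 10^7 p/s efficacy line) plus, for rule-compliant lipidoids,
a boost drawn uniformly from 1–3 orders of magnitude, minus graded
penalties of 0.8 log10 per unit symmetry deviation (capped at d = 2)
and 0.5 log10 per unit |TC − 18|, plus Gaussian noise (0.3 log10).
In vitro, log10 RLU is a baseline 2.5 raised by 1.8 for two-branch
molecules, plus Gaussian noise (0.5 log10), independent of the in vivo
channel by default (`rho = 0`). Both channels are log-normal because
luminescence readouts span orders of magnitude. Hits are records at or
above a configured benchmark reference (background + 2.5 orders), and
each hit's in vitro latent is rejection-resampled until it clears the
10,000-RLU threshold — the generator's mechanism for the observed
threshold phenomenon, which makes the threshold necessary but not
sufficient by construction. The slope and penalty values are package
choices on the log scale, sized so that compliant and non-compliant
candidates separate by roughly the published one-to-three orders of
magnitude; with a 2.5-order hit reference and boosts of 1–3 orders,
only well-boosted compliant lipidoids become hits, so individual seeds
can yield few or (rarely) no hits — the tests therefore evaluate
hit-conditional properties across a seed panel rather than on a single
draw. `recover_parameters()` closes the loop: a least-squares fit of
log10 flux on compliance, d and |TC − 18| recovers the generating
slopes, with percentile bootstrap intervals (1000 resamples, seeded).

What the generator does *not* emulate: replicate structure within a
formulation, dose–response, biodistribution, formulation failures of
bulky-tail candidates, or any correlation mechanism between channels
beyond the optional latent coupling. Passing tests therefore
demonstrate that the analysis stack recovers the designed structure
from data with the published summary statistics, not that it would
recover biology from a real screen.

## SAR analytics and formulation arithmetic

Heat maps and contour tables summarize cells by the *median* log10
readout (robust to log-normal tails); missing (never-screened) cells
are absent, not zero. The contour binning defaults —
TC breaks every 2 carbons, deviation breaks {0, 0.25, 0.5, 1, 2, ∞} —
separate the characteristic deviations 0, 0.4, 0.7 and 2 of the
canonical tail pairs; no binning is published, so these are package
choices. The correlation test is a plain two-tailed Pearson test on the
log10 channels (t distribution, n − 2 df); p-values are reported, never
thresholded internally, and no multiplicity correction is applied since
each analysis runs one planned test.

`weight_to_molar()` / `molar_to_weight()` convert LNP recipes between
weight ratios and mole percentages (inverses of each other to 1e-9).
Two cholesterol percentages circulate for the optimized lead recipe
(48.5 and 48.8); only 40/10/48.5/1.5 sums to 100, so the shipped
`optimized_formulation()` uses 48.5 and `formulation_spec()` rejects
molar ratios off 100 by more than 0.1.

## Problem sizes and reproducibility

The shipped tests enumerate the 25-member Library 1, the pooled
44-candidate two-library screen and the 500-member factorial; the
packing acceptance check embeds two molecules at five seeds each with
the full 4000-step minimization; the screen-recovery checks use 20–50
seed replicates at n = 44 and one bootstrap fit at n = 500. Every
stochastic element — embedding, simulation, bootstrap — takes an
explicit seed and restores the caller's RNG state, and
`run_pipeline()` with a fixed configuration reproduces its output files
byte for byte.

## Known limitations

* The enumerator covers the designed chemistry (terminal epoxides,
  linear saturated acyl chlorides, amines with exactly two
  substitutable N–H); it does not attempt general reaction prediction,
  regio- or stereochemistry beyond the documented SN2 convention, or
  yields.
* Amines 2–20 are synthetic stand-ins (above); per-amine conclusions
  other than for amines 1 and 11 attach to the class, not the reagent.
* The packing parameter is a single-conformer, grid-and-hull estimate
  with a declared head convention; it supports shape *comparisons*
  under identical settings, not absolute literature values.
* The rule engine is a binary structural filter with a deterministic
  tie-break; it neither regresses potency quantitatively nor learns
  from screening data.
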