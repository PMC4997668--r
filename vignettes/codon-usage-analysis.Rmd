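---
title: "Codon usage bias analysis: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon usage bias analysis: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonuse)
library(dplyr)
```

`codonuse` analyses synonymous codon usage in cohorts of protein-coding
sequences, with the analysis design used for viral gene families such as the
envelope glycoprotein genes of nuclear polyhedrosis viruses (NPV, a
baculovirus genus): per-gene usage indices, mutation-versus-selection
diagnostics, multivariate structure, and codon-usage-based trees. This
vignette explains the models behind each stage, the conventions and tunable
parameters, how the synthetic cohort generator works, and the limits of what
passing tests on synthetic data demonstrate.

## The 59-codon synonymous universe

All indices operate on the 59 *sense* codons: the standard code minus Met
(AUG), Trp (UGG) — which have no synonyms — and the three stops. The
six-fold amino acids (Leu, Ser, Arg) are kept as single families of six, so
the degeneracy classes contain 9 two-fold, 1 three-fold (Ile), 5 four-fold
and 3 six-fold families. By default the leading AUG and the terminal stop of
each CDS are excluded before counting, and codons containing N are dropped
(never imputed — the indices are ratio-based, and imputation would bias
them). Internal stop codons trigger a warning but are kept and counted as
stops, i.e. excluded from all sense-codon analyses; permissiveness is safer
for user data than silent rejection.

Sequences are held internally in the DNA alphabet; every report prints RNA
codons (UUU, not TTT), the convention of published codon-usage tables.

## Per-gene indices

**RSCU.** The relative synonymous codon usage of codon $c$ in family $F$ is
its count divided by the family's mean count,
$\mathrm{RSCU}(c) = n_c / \bar n_F$, so values average 1 within each family.
A codon absent from a gene while its family is used scores 0; a family
entirely unused yields `NA` ("undefined"), deliberately distinct from 0.
Rounding (2 decimals, half-up) happens only in report writers, never in
computations.

**ENC.** Wright's effective number of codons estimates, per family with
$n \ge 2$ observations, the codon homozygosity
$\hat F = (n\sum \hat p_i^2 - 1)/(n-1)$, averages $\hat F$ within each
degeneracy class, and composes
$$\mathrm{ENC} = 2 + \frac{9}{\bar F_2} + \frac{1}{\bar F_3} +
  \frac{5}{\bar F_4} + \frac{3}{\bar F_6},$$
capped into $[20, 61]$ so that the analytic bounds (20 = one codon per
amino acid, 61 = fully even usage) are exact. Conventions, chosen to match
the classical CodonW behaviour: families with $n < 2$ or $\hat F \le 0$
(possible at tiny $n$) are skipped; an empty three-fold class is imputed as
the mean of $\bar F_2$ and $\bar F_4$; any other empty class takes the mean
of the observed class averages. A gene too short to estimate any family
returns `NA` with a warning rather than aborting a whole cohort table.

**CAI.** The codon adaptation index is the geometric mean, over a gene's
sense-codon occurrences, of relative adaptiveness weights
$w_c = n_c / \max_{c' \in F} n_{c'}$ derived from a reference set of highly
expressed genes. Zero-count reference codons get a floor of 0.01 of the
family maximum so the geometric mean never degenerates. The reference is
injectable ([cai_weights()] accepts any count table); the package ships a
deterministic *synthetic* reference (`synthetic_cai_reference()`) — one
optimal codon per family at 900 counts, the rest at 100 — because no real
highly-expressed reference set is bundled. CAI values computed against it
are internally consistent but not comparable to values computed against an
organism's true ribosomal-gene reference.

**Composition.** GC, GC1, GC2, GC3 are computed over all analysis codons;
GC12 is the mean of GC1 and GC2. The silent-site set A3s/T3s/C3s/G3s and
GC3s restrict third positions to the 59-codon universe, so GC3 and GC3s
genuinely differ (GC3 includes Met/Trp/stop third positions). Whether
three-fold Ile belongs in the silent universe varies between codon-usage
programs; here it is included, and the universe is documented rather than
configurable per call — both GC3 variants are reported side by side.

## Mutation-versus-selection diagnostics

**ENC plot.** Observed ENC is compared with the expectation under pure
directional mutation pressure at silent-site GC content $s$,
$$\mathrm{ENC}^* = 2 + s + \frac{29}{s^2 + (1-s)^2},$$
the standard curve of ENC-plots. Genes are classified on / below / above
the curve with an "on" band of ±1 ENC unit — at gene lengths around 500
codons, multinomial sampling alone moves ENC by a fraction of a unit, so a
tighter band would misclassify unbiased genes.

**Neutrality plot.** GC12 is regressed on GC3 by ordinary least squares for
the pooled cohort and per group. The slope is read as the mutational
contribution: slope 1 means all three codon positions drift together
(mutation pressure dominates), slope 0 means first/second positions are
held while the third drifts (selection dominates);
`mutation_pct = 100·slope` and `selection_pct = 100·(1 − slope)` sum to 100
by construction. Groups with fewer than 3 genes or no GC3 variance are
skipped with a warning; the pooled fit must always be estimable. Outputs
are labelled by group explicitly, since a bare list of slopes is ambiguous.

**Correlation table.** Pairwise Pearson correlations (SPSS-style, two-sided
t-based p-values, stars at 0.05 and 0.01) among length, the composition
indices, ENC, CAI and the first two correspondence axes. Raw p-values are
reported without multiple-testing correction, matching how such tables are
conventionally published; zero-variance variables yield `NA`, flagged
rather than fabricated.

## Correspondence analysis of RSCU

The genes × 59 RSCU matrix is treated as a contingency-style table (the
"COA on RSCU" convention): normalise to proportions $P$, form the
chi-square standardised residuals
$S = D_r^{-1/2}(P - rc^\top)D_c^{-1/2}$, and decompose by SVD. Genes and
codons are reported in principal coordinates; each axis carries a fraction
of total inertia equal to its squared singular value over the sum.
Numerical choices: undefined RSCU entries are imputed as 0 with a message;
all-zero codon columns are dropped (their mass is undefined); singular
values below $10^{-8}$ of the largest are discarded as numerical noise; a
rank-0 matrix (identical row profiles) returns an explicit "no variation"
result with zero axes rather than an error. Axis signs are arbitrary in CA,
so the package fixes the codon with the largest absolute coordinate on each
axis to be positive — outputs are deterministic and testable. The first
`min(10, rank)` axes are reported; Axis 1 and Axis 2 feed the correlation
table.

## Distances, clustering and trees

Gene-to-gene distances are Euclidean on the 59-dimensional RSCU vectors
(undefined entries imputed as 0 so all profiles share one universe).
Hierarchical clustering defaults to average linkage — the published
dendrograms in this literature name only "Euclidean distance", so the
linkage is an explicit, configurable choice — and the flat `k = 2` cut
provides the two-group partition. Cluster trees are serialised as
ultrametric dendrograms whose leaf-to-merge path length is half the merge
height (cophenetic distance equals merge height).

The neighbor-joining tree uses the Saitou–Nei agglomeration (via `ape`) on
the same RSCU distance by default, though any distance matrix is accepted.
Two caveats are deliberate: published NJ trees for such cohorts are
typically *sequence*-based, while alignment is out of scope here, so
NJ-versus-dendrogram comparisons are qualitative; and NJ can produce small
negative branch lengths on noisy (non-additive) distances, which are
clamped to zero with the deficit pushed onto the adjacent branches (raw
lengths are kept in an attribute). Midpoint rooting is used only for
display and for extracting a two-group partition; the NJ tree itself is
unrooted. Newick output orders children lexicographically by smallest
descendant leaf label and quotes labels per Newick rules, so serialisation
is deterministic.

## The synthetic cohort generator

Because the original 18 glycoprotein sequences are not retrievable from
printed accession-free tables, every stage is exercised on synthetic
cohorts with planted, known structure. The generator is a first-class,
tested module, not a fixture.

A `usage_regime()` has three knobs:

* `gc3_target` — third-position GC pressure, as a fraction. Within each
  family, G/C-ending codons share weight `gc3_target` and A/U-ending codons
  share `1 − gc3_target` (each split evenly within its class). When a
  family skew is applied, the G/C-versus-A/U split is recalibrated in
  closed form so the family's *expected* third-base GC still equals the
  target exactly; skew then only redistributes mass within each third-base
  class. Realised GC3 therefore tracks the target up to multinomial noise
  (well under one percentage point at 500-codon genes).
* `family_skew` — a Dirichlet concentration for within-family preferences
  beyond the base pressure. Smaller values give stronger, more
  idiosyncratic codon preferences (lower ENC); `Inf` disables skew.
* `gc12_coupling` — ties amino-acid choice (hence first/second-position
  composition) to the same pressure. Amino acids are reweighted by
  $p^{g}(1-p)^{2-g}$, where $g$ is the family's expected G+C count at
  positions 1–2, and $p$ is calibrated by root finding so that the expected
  GC12 equals $g_0 + \kappa\,(\mathrm{GC3}_t - g_0)$ ($g_0$ = baseline GC12
  of the unweighted composition, $\kappa$ = the coupling). The
  neutrality-plot slope of a cohort then equals $\kappa$ in expectation:
  `mutation_dominated` ($\kappa = 1$) cohorts fit slopes near 1,
  `selection_dominated` ($\kappa = 0$) near 0, which is exactly the
  contrast the neutrality plot interprets.

The default `cohort_spec()` reproduces the study conditions of the 18-gene
NPV glycoprotein cohort: 18 genes of 1500–1593 nt in two groups of 11 and
7; per-gene GC3 targets spread evenly over each group's published range
(48.4–77.5 % and 51.9–66.7 %); `gc12_coupling = 0.1`, matching the weak
mutational contribution (slopes ≈ 0.07–0.11) reported for this system; and
one family-skew vector per group, shared by its genes, drawn at
concentration 3. The shared draw is what makes groups separable by RSCU
profile; concentration 3 was chosen once, as a realism setting, so that
per-gene ENC stays in the weak-bias envelope (above 35) while genes still
sit clearly below the mutational-pressure curve. The cohort-level
amino-acid composition is drawn once per cohort from a Dirichlet centred on
uniform over the 18 families (concentration 50). A single seeded RNG stream
drives the whole cohort, so spec + seed regenerate byte-identical FASTA.

**What the generator does and does not emulate.** It reproduces the
statistical structure the analyses assume — controlled GC3 gradients,
tunable within-family bias, coupled or decoupled GC12, two-group profile
structure — under i.i.d. codon sampling. It does not emulate phylogenetic
autocorrelation along a tree, amino-acid composition differences between
genes, dinucleotide or context effects, or length–bias correlations.
Passing the planted-structure tests therefore shows the estimators recover
known signal of realistic magnitude; it does not certify behaviour on real
sequence cohorts, whose published summary statistics additionally depend on
the exact sequences, which are not desk-reproducible. The one fully real
anchor is the published pooled codon-count table (shipped in
`inst/extdata/`), whose 59 printed RSCU values and preferred-codon census
the package reproduces exactly.

## Pipeline and reporting conventions

`run_pipeline()` is a pure function of (input, configuration, seed): it
stages all outputs in a temporary directory and copies them over only on
success, so a failed run leaves no partial bundle and aborts naming the
failed stage. The index report appends mean and standard-deviation rows
computed from the per-gene rows; the SD is the sample standard deviation
(n − 1) — the convention is stated here because published tables rarely
say which was used. Preferred codons are flagged strictly (`RSCU > 1.0`),
with a second tier at `RSCU > 1.5` for strong preference. Report tables
round half-up at 2 decimals; trees and coordinate tables keep more digits.
Group labels come from the input when present, from a user grouping table
when given, and otherwise from the k = 2 cluster cut.

## Problem sizes used by the test suite

The suite validates estimators against independent oracles (brute-force
homozygosity for ENC, eigen decomposition for CA inertia, normal equations
for OLS, exhaustive agglomeration for average linkage, additive matrices
for NJ) and runs a 100-cohort Monte-Carlo per regime (18 genes × ~1.5 kb
each) for the slope-recovery property, with ≥95 % of cohorts required in
the documented slope ranges ([0.8, 1.2] mutation-dominated, [−0.1, 0.2]
selection-dominated). These sizes keep the whole suite at a few minutes on
one core while leaving the Monte-Carlo tight enough to detect calibration
errors of a few percent.

## Known limitations

* CAI against the synthetic reference is a self-consistent index, not an
  expression predictor; supply a real highly-expressed reference for
  biological use.
* The NJ tree on RSCU distances is a usage tree, not a phylogeny; branch
  lengths are in RSCU units.
* No parity (PR2) analysis, translational-selection indices, codon-pair or
  dinucleotide bias, and no multiple-testing correction in the correlation
  table.
* The correspondence analysis imputes undefined RSCU as 0, which slightly
  inflates the inertia of genes with unused families; such genes are rare
  at realistic lengths but common in toy examples.
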