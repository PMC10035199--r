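---
title: "Methods: co-abundance modules, cross-cohort validation and cell-type enrichment"
author: "protmod"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-abundance modules, cross-cohort validation and cell-type enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

protmod implements a systems-level analysis chain for label-free
DIA/SWATH tissue proteomics: peptide reports are rolled up to a
normalized protein-by-sample matrix; pairwise differential abundance is
tested with a beta-binomial likelihood-ratio test whose p-value
distribution is calibrated into FDR thresholds by a beta-uniform mixture;
co-abundance modules are detected from a soft-powered correlation
network; each module is scored for dysregulation, mined for a hot
subnetwork by network propagation, validated across independent cohorts
with a permutation statistic (GESS), and profiled for cell-type
composition by bootstrap expression-weighted enrichment. This vignette
explains each model, its assumptions, the tunable parameters and the
numerical choices, and what the synthetic-data generator does and does
not emulate.

## Quantification

A peptide report is a long table of (sample, fraction, peptide, protein,
abundance, Q-value) records. Four steps produce the protein matrix:

1. **Quality filter.** Within each fraction, a peptide is discarded when
   its Q-value exceeds 0.01 in strictly more than half of the cohort's
   samples. The strictness matters at the boundary: failing in exactly
   half of 26 samples keeps the peptide.
2. **Fraction combination** by summation of same-peptide abundance per
   sample. A peptide mapping to two proteins is rejected as ambiguous
   rather than resolved heuristically.
3. **Top-5 rollup.** Each protein's peptides are ranked once by total
   abundance across all samples (ties broken by peptide id for
   determinism) and the same top-5 set is summed in every sample, so a
   protein's value is comparable across samples. The ranking uses
   fraction-combined totals. A peptide absent from a sample contributes
   zero, consistent with summation semantics for long-format input.
4. **Total-count normalization.** Each sample is scaled to a common
   total (default: the mean of the input totals). LC-MS/MS measures
   relative abundance, so all downstream statistics are invariant to the
   target; the default merely keeps values on a familiar scale.

The container is a `SummarizedExperiment` with assay `"abundance"` and a
`group` column, so the matrix travels with its sample annotation.

## Differential abundance

Intensities are continuous but the test operates on pseudo-counts: the
matrix is rescaled so the median sample total is about $10^6$ and
rounded. Per protein, counts $y_s$ out of sample totals $n_s$ follow a
beta-binomial with mean proportion $\pi$ and precision $\theta$, with a
common $\theta$ across groups; the null fits one $\pi$, the alternative
one $\pi$ per group, both by bounded quasi-Newton maximization on
$(\mathrm{logit}\,\pi, \log\theta)$.

The likelihood-ratio statistic $\Lambda$ is, by default, referred to its
small-sample F transform $F = (N-2)(e^{\Lambda/N}-1) \sim F_{1,N-2}$,
the transformation that is exact for Gaussian likelihoods. At the
cohort sizes this package targets (5-15 subjects per group) the
asymptotic $\chi^2_1$ tail is measurably liberal — about 0.08 empirical
type-I error at nominal 0.05 on the synthetic null — while the F tail
is calibrated (0.04, and Kolmogorov-Smirnov-uniform); `tail = "chisq"`
restores the asymptotic convention. Log2 fold changes use group means
of normalized abundance with a pseudocount of 0.5 against division by
zero; the test is invariant to global rescaling and anti-symmetric
under swapping the contrast.

**FDR calibration.** The p-values of one contrast are fitted with the
beta-uniform mixture $f(p) = \lambda + (1-\lambda)\,a\,p^{a-1}$
($\lambda \in [0,1]$, $a \in (0,1]$) by maximum likelihood from five
fixed starts (a guard against the mild multimodality of the likelihood;
best fit wins, so the result is deterministic). With
$\pi_{ub} = \lambda + (1-\lambda)a$ bounding the null proportion, the
estimated false-discovery proportion at cutoff $\tau$ is
$\pi_{ub}\,\tau / (\lambda\tau + (1-\lambda)\tau^{a})$, and the
FDR-to-threshold map has the closed form
$\tau = [\mathrm{fdr}(1-\lambda)/(\pi_{ub} - \mathrm{fdr}\,\lambda)]^{1/(1-a)}$,
verified in the tests against numerical root finding to $10^{-6}$. A
signal-free fit ($\pi_{ub}\approx 1$) maps every FDR level to $\tau=0$
with a warning.

## Co-abundance modules

The similarity is $s_{ij} = |r_{ij}|^\beta$ with $\beta = 7$ by default;
`pickSoftThreshold()` reproduces the scale-free criterion (signed $R^2$
of the log-log regression of binned connectivity frequency) when a
data-driven power is preferred. The unsigned network treats co- and
anti-regulation alike.

Proteins are clustered by average linkage on $1-s$ and the tree is cut
adaptively: the cut height is a fraction of the tree's own maximum merge
height (0.95 at the default `deep_split = 2`; 0.90/0.93/0.97 at levels
0/1/3), maximal branches joining above the cut become module candidates,
and candidates below `min_size = 15` fall into the leftover class M00.
Judging separation relative to the tree's own scale matters because the
7th power compresses weak correlations toward similarity zero: noise
proteins and chance inter-module correlations all join in a thin band
just below the maximum height, while genuine modules complete well below
it. `min_size = 15` is chosen so that module landscapes with smallest
modules of about 18 members remain resolvable (the WGCNA-tutorial
default of 20 would censor them). Labels are M01, M02, ... by strictly
decreasing size, ties broken by first protein id; M00 is not a module.

**Dysregulation.** Per module and contrast, a two-sided one-sample t
test of the members' log2 fold changes against zero, with
Benjamini-Hochberg correction across the modules of that contrast
(contrasts are separate families); `p_bh < 0.05` flags dysregulation.
Note a structural caveat: members of a co-abundance module are not
independent, and the shared component (subject-level eigengene
difference between small groups, or a compositional shift introduced by
total-count normalization) moves the whole distribution, so the test is
intrinsically anticonservative for tight modules. This is a property of
the module-mean design, visible in the synthetic runs, and one reason
the cross-cohort validation below exists at all.

## Hot subnetworks

Within one module, the graph has an edge where $|r| \ge 0.5$ (threshold
exposed; 0 gives the complete weighted graph), weighted by $|r|$. Vertex
scores are $-\log_{10} p$ of the primary contrast, capped at 16 so a
vanishing p-value cannot dominate. The random-walk-with-restart matrix
$F = \beta(I - (1-\beta)W)^{-1}$ uses the column-normalized weighted
adjacency ($\beta = 0.5$, mid-range of published settings; isolated
nodes keep their mass, so $F$ stays column-stochastic). The exchanged
similarity $S_{ij} = F_{ij}\,score_j$ is symmetrized as
$\min(S_{ij}, S_{ji})$ and thresholded at every level $\delta$ occurring
in it; connected components across levels form a hierarchy, computed in
one pass as single-linkage clustering (connectivity at $\delta$ equals a
single-linkage cut).

$\delta$ is selected by comparing the observed largest-component
trajectory with its mean over score permutations within the module. The
selection maximizes the *relative* excess $L_{obs}(\delta) / \bar
L_{perm}(\delta)$: the absolute difference grows monotonically toward
small $\delta$, where near-complete components are trivially larger
than permuted ones, and would never report a compact hot set. Among
thresholds within 15% of the maximal excess the smallest $\delta$ wins,
so the reported component is the most complete version of the anomaly
rather than a clipped core. Components with at least two nodes are
reported largest-first with an empirical permutation p-value
$(1+\#\{L_{perm} \ge L_{obs}\})/(1+n_{perm})$; structureless scores
(all equal, or all zero) report nothing with p = 1. The whole procedure
is invariant to positive rescaling of the scores.

## Cross-cohort validation (GESS)

For module $m$ and threshold $t$, the concordance fraction is
$$F_{m,t} = \frac{\sum_{P\in m} 1\left[p_{P,d} < t \wedge p_{P,v} < t
\wedge FC_{P,d}\cdot FC_{P,v} > 0\right]}{N_m},$$
with strict inequalities (a log2FC of exactly zero is non-concordant).
Module members absent from one cohort are excluded from both numerator
and denominator by default (`missing = "fail"` counts them against the
module instead), mirroring the partially overlapping universes of real
cohorts.

The null reassigns the validation cohort's (p, log2FC) pairs to protein
labels by a uniform permutation of the shared universe — globally, not
within the module, since within-module shuffling would leave $F_{m,t}$
invariant. Restricted to one module this is a uniform draw of $N_m$
pairs without replacement, which is how it is computed. Each threshold
in $\{0.1, 0.2, 0.5, 0.8\}$ receives a one-sided p-value; the GESS
score is their mean, and a module validates when GESS < 0.05.

Three per-threshold p-value modes are provided. The default is the
empirical permutation estimate $(1+\#\{F^{perm}\ge
F^{obs}\})/(1+n_{perm})$, which is calibrated by construction: on 200
null modules of 50 proteins the validated fraction stays below 5%. A
z-score mode standardizes the observed fraction by the permutation mean
and standard deviation. The literal one-sample t-test of the permuted
fractions against the observed value is also available (`mode =
"ttest"`) but is documented as degenerate: its standard error shrinks
with $n_{perm}$, so it collapses to a 0/1 indicator of whether the
observed fraction exceeds the permutation mean and validates roughly
half of all null modules; it is kept for comparability, not for use.

## Cell-type enrichment

Specificity of gene $g$ in cell type $c$ is $g$'s mean expression in
$c$ divided by its total over all cell types (rows sum to 1). For a
target list, `ewceBootstrap()` compares the mean specificity per cell
type against `n_boot = 20000` uniform same-size lists drawn without
replacement from the background (the full quantified proteome), giving
a standardized z and the positively biased empirical p
$(1+k)/(1+n)$ that avoids zero p-values. Sampling is uniform, without
expression-level binning, matching the cited default for unsigned
lists. The directional per-module summary compares the log2 fold
changes of a cell type's markers inside a module against the other
members with a two-sided Wilcoxon rank-sum test, labels the direction
by the median difference, and BH-corrects across cell types; a single
in-module marker is reported but flagged low-power. The packaged
marker list names seven CNS classes (astrocytes, endothelial cells,
excitatory and inhibitory neurons, microglia, oligodendrocytes, OPCs).

## The synthetic cohort

The generator emulates the structure of a three-group neuropathology
cohort — two case groups (n = 6 and n = 15) and controls (n = 5) — over
1800 proteins, 17 planted modules from 272 down to 18 members plus 125
background proteins. Protein log2 abundance follows one Gaussian factor
per module:
$$x_{ps} = b_p + L\,\sigma_f\, f_{m(p),s} + \delta_{m(p),g(s)}(1 +
0.3\,z_{m,s}) + \varepsilon_{ps}.$$
Defaults: baseline $b_p \sim N(13, 1)$ (log2 intensity), loading
$L = 0.9$, factor amplitude $\sigma_f = 0.45$ log2 units
($L\sigma_f \approx 0.4$ of between-subject co-regulation), residual
noise $\sigma = 0.15$. These amplitudes are the regime in which a
cohort of this size can both detect hundreds of differential proteins
and show strong co-abundance structure: per-protein within-group
variation around 0.4 log2 units, within-module correlation near 0.85. Planted module
shifts are 0.4-0.8 log2 units (13 modules shifted in the first case
group, mostly down; 9 in the second at 60% strength), with 30%
subject-level jitter so effect patterns are not rigid group offsets and
do not correlate modules with each other. Hot chains are 6 members of
four modules with twofold-amplified effects. Proteins expand into
$1+\mathrm{Poisson}(5)$ peptides with fixed lognormal ionization
multipliers, a primary chromatographic fraction with occasional 70/30
spill into a neighbour, and multiplicative peptide noise; 5% of
peptides receive Q-values in (0.011, 0.5) in a random majority of
samples, making them filterable on purpose. Validation cohorts are
generated at the statistics level — concordant modules reproduce the
planted effect sign with mean z of $4|\delta|$, everything else is
uniform — because the validation statistic consumes (p, log2FC) pairs
only; 3.5% of proteins drop out, emulating partially overlapping
universes.

What the generator does **not** emulate: missing peptide values and
intensity-dependent detection, shared peptides between proteins,
batch effects, heavy-tailed or outlier-prone abundance errors,
correlated (non-factor) residual structure, and any raw-spectrum-level
artefact. Passing tests therefore demonstrate that the implementations
are correct and calibrated under a clean factor model at realistic
sizes, not that the pipeline is robust to all the pathologies of real
data.

Two deliberate consequences of realism are visible in synthetic runs:
total-count normalization introduces a small compositional shift when
the planted effects do not balance (the cases' totals drop, so null
proteins acquire a slight apparent up-shift), and the module
dysregulation t-test flags nearly every module because member fold
changes share that shift plus the factor's group difference. Both
phenomena affect the real procedure in exactly the same way; the
calibrated quantities are the per-protein test and the GESS validation.

## Problem sizes and determinism

The test suite and the acceptance script run the full default cohort
(1800 proteins, 26 samples), a 1000-protein null for type-I error, 200
null modules of 50 proteins with 1000 permutations each for GESS
calibration, 20 replicates of hot-chain recovery, and 20000-list
bootstraps — sizes chosen to match the study conditions while keeping a
complete run in minutes on one CPU. Every stochastic step takes an
explicit seed; the pipeline derives per-stage sub-seeds from one global
seed, and rerunning a configuration reproduces byte-identical artifacts
(verified by digest comparison in the tests).

## Known limitations

- Protein inference is intentionally naive: shared peptides are an
  error, not a model; no imputation is provided.
- The beta-binomial's count conversion (median total $10^6$) is a
  convention; the F-calibrated tail is validated for 5-15 subjects per
  group and has not been studied here for much larger cohorts, where
  `tail = "chisq"` is equally valid.
- The dynamic tree cut is the static-height variant with an adaptive
  scale; it does not implement branch-shape criteria (core scatter,
  cluster gap) of the full hybrid algorithm.
- GESS treats the validation cohort's statistics as exchangeable across
  proteins under the null; structured validation noise (e.g. shared
  batch direction) would inflate concordance for all modules alike.
- The module dysregulation t-test ignores member correlation (see
  above); its BH family is the modules of one contrast.
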