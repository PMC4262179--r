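---
title: "Methods: measuring transgressive segregation after secondary contact"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: measuring transgressive segregation after secondary contact}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contactzone)
```

## The scientific problem

When two formerly allopatric lineages of one species meet again, admixture
can recombine alleles of opposing effect that each lineage had accumulated
under stabilising selection. Hybrid offspring may then display phenotypes
outside the range of either parent — transgressive segregation. This
package implements the full analysis chain used to demonstrate that effect
in a riverine cichlid system: geometric morphometrics of common-garden
crosses with a bootstrap range-extension test, the contact-zone population
genetics that establishes the two lineages and their admixture (haplotype
networks, a diagnostic restriction screen, pairwise FST), and the
mate-choice analysis that shows the lineages interbreed (exclusion
paternity plus exact binomial tests). Every input can be simulated, so the
whole pipeline is testable end to end without external data.

## Shape analysis

Specimens are digitised as $k = 25$ two-dimensional landmarks (TPS files,
read by `read_tps()`). Generalized Procrustes analysis (`gpa()`) centres
each configuration, scales it to unit centroid size
$\mathrm{CS} = \sqrt{\sum_i \lVert x_i - \bar{x} \rVert^2}$, and rotates it
(proper rotations only; reflections are biologically meaningless for
lateral-view landmarks) onto an iteratively re-estimated consensus. The
iteration stops when the consensus moves less than `tol = 1e-10`, far
below digitising noise; 100 iterations is an ample cap (typical runs
converge in well under ten). Aligned shapes are projected orthogonally
onto the tangent plane at the consensus, where Euclidean analysis is
valid.

Relative warps (`relative_warps()`) are the principal components of the
centred tangent coordinates. With the warp-weighting exponent at zero and
the uniform component retained — the default configuration of the standard
morphometric software — relative warps coincide exactly with this PCA, so
no thin-plate-spline machinery is needed. PCA axis signs are arbitrary;
each axis is oriented so its largest-magnitude loading is positive, which
makes results reproducible across platforms. All axes are returned, their
variance fractions sum to one, and the decomposition reconstructs the
tangent coordinates exactly.

Shape typically retains a small allometric dependence on size even in
common-garden material. `allometry_residuals()` regresses every axis score
on centroid size by OLS and carries the residuals forward. The regression
is pooled across all specimens by default — the cross design shares a
common growth environment, and a pooled fit is the natural reading of
"residuals of scores on size" — with a per-group option for users who
prefer within-group correction (no claim of equivalence is made for that
option).

## The transgression statistic

For one axis, with hybrid scores $H$ and pooled parental scores $P$,

$$ T = 100 \times \frac{\max(0, \max H - \max P) + \max(0, \min P - \min H)}
  {\max P - \min P} $$

i.e. the percentage of the parental range by which hybrids exceed it,
counting both tails (hybrids overshoot the parents in both directions on
several axes, so one-tailed novelty would understate the effect). Because
range statistics grow with sample size, hybrid groups are bootstrapped to
the parental sample size: each of $B = 500$ replicates draws $n = 50$
hybrids with replacement and computes $T$ against the fixed pooled
parental sample of 50. The reported quantities per axis and cross are the
median $T$ across replicates, the support (proportion of replicates with
$T > 0$), and $p = 1 - \mathrm{support}$; stars mark support 0.95/0.99/
0.999. The fixed-parents reading follows the design's stated purpose of
equalising sample sizes against the parental pool; the alternative reading
(bootstrapping the parents against fixed hybrids) is available via
`resample = "parents"` but is not the default. A single integer seed
drives the whole table through per-cell substreams derived from
(seed, axis, group), so any cell can be reproduced in isolation.

**A known limitation.** The support statistic is a measure of evidence
within the bootstrap scheme, not a calibrated frequentist test. Under a
null in which hybrids and parents are drawn from the same distribution, a
replicate shows $T > 0$ whenever it draws any hybrid value outside the
parental sample range, and support $\ge 0.95$ already occurs when three or
more hybrid values fall outside that range — an event with probability
near 0.3 for equal samples of 50. Simulation (200 null datasets) puts the
per-cell star rate near 0.2–0.3 rather than 0.05. Starred cells should
therefore be read as "consistently extended range under resampling", and
cross-axis patterns (several crosses starred on the same axis, large
medians) carry more weight than any single star.

## Synthetic morphometric data

`gen_landmarks()` builds shape variation in an explicit score space: six
orthonormal deviation axes of a fish-like template, orthogonal to
translation, scaling and rotation, so scores map linearly to landmarks and
ground truth is well defined. The defaults mirror the common-garden
design: 25 specimens per parental line (pooled parents = 50), 50 per
hybrid cross, parental means separated by a Procrustes distance of 0.08
along axis 1, within-group score standard deviations falling from 0.020
to 0.0035 across axes (well separated, so the PCA recovers the generating
axes), digitisation noise of 0.001 per coordinate, lognormal centroid
sizes (mean 250 image units, log-sd 0.15) and an allometric slope of 0.25
within-axis standard deviations per standard deviation of log size, which
keeps size under 10% of score variance as observed in this kind of
material. Backcrosses segregate 3:1 toward the recurrent parent on the
divergence axis and F2 1:1, so with no injected transgression the F2
score distribution equals the parental mixture — the natural null.

Transgression is injected last: on a chosen axis, hybrid scores are
replaced by a uniform draw over the pooled parental empirical range
widened by the configured percentage, after the allometric effect has been
added. Injecting before allometry would let the size effect smear the
hybrid range and inflate the realized extension by 10–15 points; injecting
last makes the configured percentage the exact population-level truth.
What the generator does not emulate: developmental plasticity, measurement
operators beyond isotropic noise, correlated landmark error, or
non-Gaussian within-group variation — so passing recovery tests show the
statistical machinery is faithful, not that real fish behave this simply.

## Contact-zone genetics

Alignment columns containing a gap, `N` or any IUPAC ambiguity in any
record are removed before haplotype collapsing (`filter_alignment_sites()`,
idempotent); identical sequences then merge with counts
(`collapse_haplotypes()`, labels ordered by frequency with ties broken by
sequence so record order is irrelevant). Pairwise Hamming distances feed a
minimum spanning tree built by Kruskal's algorithm with deterministic
lexicographic tie-breaking; every non-tree pair whose distance equals the
bottleneck (maximum edge) on its tree path is reported as an alternative
equal-length connection, the convention of haplotype-network software.

The in-silico restriction screen (`rflp_assign()`) defaults to the HpaI
recognition site GTTAAC, which is its own reverse complement, so scanning
the forward strand suffices. An `N` inside a window that could otherwise
match makes the call indeterminate (an error for single sequences, `NA`
with a warning in the vectorised screen); other ambiguity codes are
degraded to `N` before scanning.

Pairwise differentiation uses the Weir–Cockerham (1984) multiallelic
$\theta$, combining loci as the ratio of summed variance components, with
per-locus complete-case handling of missing genotypes; negative estimates
are reported as computed. Significance comes from permuting individuals
between the two populations with the add-one rule
$p = (1 + \#\{\theta^* \ge \theta\})/(B + 1)$, the standard
assumption-light analogue of exact tests. The genotype simulator draws
population allele frequencies around flat-Dirichlet ancestral frequencies
with Balding–Nichols concentration $(1-F)/F$, giving an analytic FST
target; recovery within $\pm 0.05$ at 20 loci and 50 diploids per
population is verified in the tests.

The sequence simulator separates two haplogroups by 10 fixed differences
(one inside the diagnostic motif), concentrates private mutations at a
small per-haplogroup pool of hypervariable sites with fixed alternative
bases — the recurrent-mutation structure that makes control-region
haplotypes shared among individuals — and seeds gap/ambiguity columns at a
rate (0.115) chosen so a 403-bp alignment filters to roughly 357 bp.
Fixed sites and the motif window are protected from both private mutation
and column corruption, so the diagnostic screen and the haplogroup split
survive filtering by construction.

## Mate choice

Paternity is assigned by exclusion: a candidate explains a fry at a locus
if one fry allele can come from the mother and the other occurs in the
candidate. The mismatch tolerance defaults to 0 (strict exclusion;
configurable to 1 to absorb a genotyping error). A single surviving
candidate is assigned; several leave the brood ambiguous; none triggers a
greedy split of the fry between at most two sires — mouthbrooders can show
multiple paternity — with both matings flagged. With 5 loci of 8 uniform
alleles and 8 fry per brood, the true sire is recovered in over 95% of
simulated broods.

Assortative preference is tested per replicate with the exact one-sided
lower-tail binomial probability $P(X \le k \mid n, 1/2)$ on the
heterotypic count, computed by explicit summation of the binomial mass.
The one-sided tail is used because the experiment tests a directional
preference hypothesis; the printed per-replicate p-values of the study
system (0.0059, 0.0195, 0.0351) are exactly one-sided tails
($12/2048$, $10/512$, $9/256$), which also fixes the reconstructed
$(n, k)$ pairs. A two-sided option is provided. The mate-choice simulator
defaults to an assortment probability of 0.805 — 19.5% heterotypic matings
in expectation — with 4 replicates of 6 females and 3 males per lineage.

## Problem sizes and numerical choices

The test suite exercises the chain at deliberately modest sizes chosen to
make Monte-Carlo assertions stable: 100 random datasets for Procrustes
invariance (tolerance 1e-8 on pairwise distances), 500 random instances
against exhaustive spanning-tree enumeration, 50 seeds for FST recovery,
20 seeds for end-to-end transgression recovery (tolerance ±10 percentage
points on the median), 1000 simulated broods for paternity, and 200 null
datasets for the calibration check discussed above. Degenerate inputs
error early and by name: coincident landmarks, zero parental ranges,
all-equal centroid sizes, monomorphic locus sets, empty alignments after
filtering.
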