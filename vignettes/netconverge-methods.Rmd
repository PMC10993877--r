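---
title: "Methods: network construction, similarity, and the synthetic cohort model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network construction, similarity, and the synthetic cohort model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models and procedures the package implements, the
parameters that matter, the generative model behind the synthetic cohorts, and
the numerical decisions taken where the methodology left genuine freedom.

## The four group networks

All four estimates live on the same parcellation of N regions and are
symmetric N×N matrices with an exactly-zero diagonal (`WeightedNetwork`).

**Structural connectivity (SC).** Per subject, the streamline count n_ij
between two regions is divided by the mean interface surface area of the pair,
w_ij = n_ij / ((A_i + A_j)/2), in streamlines per mm² — streamline counts
scale with the available seeding surface, and this normalization removes that
geometric effect. The denominator could equally be the sum of the two areas;
any fixed positive scale is absorbed by the subsequent rank-based steps, and
the average is kept for interpretability. Each subject's nonzero weights are
then resampled to a standard Gaussian via their average ranks,
Φ⁻¹((r − 0.5)/m) — tractography weight distributions are heavy-tailed over
orders of magnitude, and rank-Gaussian resampling makes the across-subject
average a rank-consensus rather than a mean dominated by a few extreme
connections. Zeros are structural absences, not low ranks: they are excluded
from the resampling and contribute zero to the group average. Finally, the
group average retains a connection only if it is present (nonzero raw count)
in *strictly more than* a fraction c of subjects — c = 0.75 by default, the
strict inequality being the literal reading of "more than 75%". The average
runs over all subjects, absent connections contributing zero; averaging only
over possessing subjects would up-weight rarely seen connections, which is
exactly what the consistency threshold is meant to guard against.

**Functional connectivity (FC).** Pipeline order is fixed: nuisance
regression, then band-pass, then correlation. Each regional signal is
replaced by its OLS residual on the supplied WM- and CSF-like components plus
an intercept (all-zero nuisance columns are dropped, reducing to plain
demeaning; duplicated columns are an error). The band-pass (default
0.009–0.080 Hz) is a second-order Butterworth applied forward and backward
(`signal::filtfilt`), i.e. zero-phase, standard resting-state practice; the
filter family and order are a package choice, as is the
regression-before-filter order, which avoids re-introducing out-of-band
energy through the regression step. Per-subject Pearson matrices are averaged
across subjects through Fisher's z (atanh — mean — tanh), with |r| clipped at
1 − 1e−15 so degenerate inputs cannot produce infinities; group values are
therefore strictly inside (−1, 1).

**Covariance networks (FDGcov, GMVcov).** These are group-level constructs:
one value per region per subject, correlated *across subjects*. For uptake,
each subject's row is first divided by that subject's mean grey-matter
uptake; without voxel data the package offers the volume-weighted mean of
regional uptakes (default — the closest region-level analogue of a
whole-grey-matter mean) and the simple mean, and the choice is logged. For
volume, each region is regressed across subjects on the subject's total
grey-matter volume (the sum of its regional volumes — the only total
available at region level) with an intercept, and residuals are correlated.
If a region is *fully* explained by total volume, its residual column is
numerically pure rounding noise; the package zeroes such columns
(residual SD < 1e−8 of the raw SD) so that the correlation step fails loudly
instead of correlating floating-point noise.

## Similarity: strength and space

**Strength.** Spearman correlation between the weight vectors of a pair over
a chosen edge set — by default the edges present in the reference SC network
("structurally consistent connections"), optionally all E = N(N−1)/2 pairs,
optionally restricted to positive proxy weights. P-values use the asymptotic
t-approximation (`cor.test(..., exact = FALSE)`) and are Bonferroni-adjusted
by the number of pairs in the report (3 for the SC–proxy comparisons, 6 when
proxy–proxy pairs are included). In the distance-controlled variant the
correlation is the first-order partial correlation on ranks with centroid
Euclidean distance as covariate.

**Space.** Sparsity of a network is the fraction of exactly-zero
upper-triangle entries over E. Binarization at sparsity s keeps exactly
k = round((1−s)·E) edges, the k strongest by *signed* weight (negative
connections drop out first, consistent with keeping "the strongest"
connections). Two numerical rules make this deterministic and well-anchored:
ties break lexicographically by (row, column) index, and exact zeros —
structural absences — rank below every present connection, including
negative ones. The latter matters for SC: its averaged rank-Gaussian weights
are roughly centered on zero, and without the rule, binarizing SC at its own
sparsity would not return its own support (the property that anchors the
lower end of the sweep). Dense proxy matrices contain no exact zeros and are
unaffected.

The convergence ratio of two binarized networks is |A∩B| divided by the mean
edge count — identical to the Dice coefficient. CR is swept over an
inclusive sparsity grid with step 0.005 (both endpoints always included,
fine enough that the grid mean tracks the range midpoint); the reported
summary is the unweighted mean over grid points. The grid's lower bound
defaults to the SC sparsity; the upper bound is the largest grid sparsity at
which *every* network's binarization remains a single connected component
(checked with `igraph`), capped at 0.80. Because the retained edge sets are
nested as s grows, connectedness is monotone and the scan from the top down
is exact.

**Chance level.** For two independent uniformly random edge sets of equal
size k, the expected intersection is k²/E, so the expected CR is k/E = 1−s;
the chance level of a sweep is the mean density over the grid. This closed
form is exact in expectation, and the package retains a Monte-Carlo
estimator (sampling actual edge-set pairs) as an independent validation
oracle; the two agree within Monte-Carlo error across problem sizes in the
test suite.

**Distance residualization.** Brain networks are spatially embedded, so
inter-region distance is a shared driver of all four estimates. The variant
regresses each network's weights on centroid distance (over its support for
SC, over all pairs for the dense proxies) and recomputes CRs from the
residuals, alongside partial rank correlations. Residualization can break
connectedness at every grid point; in that case the report keeps the
configured [s_min, 0.80] range and flags the fallback rather than failing.

## The synthetic cohort model

The generator exists so that every stage has a testable ground truth; its
defaults mirror the reference study's scale: 56 subjects, 106 regions (78
cortical), 209 retained volumes at TR = 2.26 s.

**Regions.** Two mirror-image hemispheric blocks (every paired region has
exactly one homotopic partner at the mirrored centroid) plus a small midline
vermis block; lobes are assigned by spatial blocks around anatomically
plausible anchors; interface areas (log-normal around 600 mm²) and volumes
(log-normal around 6000 mm³) are positive by construction.

**Ground truth.** Edges are sampled without replacement until the target
density (default 0.342, matching the thresholded group-SC density) is hit
exactly, with probability decaying exponentially in centroid distance
(default scale 40 mm), a homotopic-pair inclusion probability of 0.9, and a
3× boost for intra-lobe pairs — the stylized facts of macroscale connectomes
(distance dependence, strong homotopic and intra-lobe connectivity). Weights
are positive, log-normal around the same exponential distance decay, doubled
on homotopic edges.

**Streamline counts.** True edges draw from a gamma-Poisson (negative
binomial-like) mixture with mean proportional to ground-truth weight times
mean interface area — so the surface normalization has a real effect to
undo — shifted by one: a *detected* connection carries at least one
streamline, and failed detection is modelled explicitly by the dropout rate
(default 0.1) rather than implicitly by Poisson zeros. Non-edges acquire a
small spurious count with probability 0.02.

**Planted covariance.** Regional features and time series share one spatial
correlation model: a communicability (matrix-exponential diffusion) kernel
R = cov2cor(expm(β·Â)), where Â is the ground-truth weight matrix rescaled
to unit spectral radius and β = coupling/(1 − coupling). This is the
network-diffusion account of how structure shapes functional covariance:
signals propagate along walks of the planted graph, inducing strong
correlations on direct edges and weaker ones on indirect paths. The kernel
is positive definite for every coupling in [0, 1) and reduces to
independence at coupling 0. A simpler additive model (identity plus the
rescaled weights) was evaluated and rejected: at realistic density its
per-edge correlations are bounded near coupling/mean-degree ≈ 0.02, an order
of magnitude below the 0.2–0.6 edge correlations seen in empirical FC and
covariance networks, which would make the generator unrepresentative of the
data the pipeline targets. At the default coupling 0.8 the kernel yields
mean edge correlations around 0.3, non-edge correlations around 0.1.

Uptake tables are drawn from this kernel around a baseline of 100 (regional
SD 10) and multiplied by a per-subject log-normal global scale (SD 0.2 on
the log scale — the dose/global-metabolism confound the normalization step
must remove). Volume tables are drawn around each region's volume
(heteroscedastic, SD proportional to size — diagonal scaling leaves the
correlation structure intact) plus a per-subject additive factor
proportional to regional volume (SD 0.1), so total volume genuinely varies.
Time series are white draws from the kernel smoothed by a first-order
recursion with coefficient 0.5 (a bounded-spectrum temporal autocorrelation
that, being the same linear filter in every region, provably preserves the
planted spatial correlation), plus per-region linear drift, a 0.15 Hz
out-of-band sinusoid, and two slow nuisance components that contaminate all
regions with subject-specific loadings and are returned as the measured
nuisance matrix.

**What the generator does not emulate.** No voxel data, no hemodynamic
forward model, no subject motion, no partial-volume effects, no atlas or
registration error, and no claim that the synthetic parcellation matches any
real atlas's region list. Passing tests therefore demonstrate that the
pipeline's inference is correct *given* its stated data model — not that the
pipeline is robust to every artifact of real acquisitions.

## Reproducibility and problem sizes

Every generator function takes an explicit seed and is bit-reproducible; the
pipeline derives stage seeds from one root seed, writes every artifact as
labeled tab-separated text, and regenerates files byte-identically. The test
suite validates the oracle equivalences (CR = Dice, Spearman and partial
Spearman against definitional computations) on hundreds of random cases,
the published chance-CR values of the four sweep ranges, and
planted-structure recovery on the full default cohort over five seeds;
smaller properties run on 16–20-region cohorts, which preserve every
qualitative behaviour at a fraction of the cost.

## Known limitations

Connection weights across modalities have different natural scales and sign
conventions; only rank-based and overlap-based comparisons are offered,
deliberately. The chance-CR closed form assumes independent uniform edge
sets — networks with shared spatial embedding exceed it by construction, a
point the distance-residualization variant exists to probe. The
connectedness upper bound depends on all supplied networks, so reports from
different network subsets are not directly comparable unless the grid is
fixed manually. Finally, the Bonferroni family is the number of reported
pairs, not the number of all comparisons ever made in an analysis session.
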