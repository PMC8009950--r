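---
title: "Evaluating feed substrates: protein quality, growth kinetics and multi-criteria synthesis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating feed substrates: protein quality, growth kinetics and multi-criteria synthesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nutrieval)
library(dplyr)
```

nutrieval implements the complete evaluation stack used to judge whether a
candidate animal-feed substrate — here a semiterrestrial isopod meal,
benchmarked against Antarctic krill meal and white fish meal — is worth
rearing and feeding: protein-quality indices, growth-curve kinetics, the
replicate-panel comparison statistics that produce significance letters, an
analytic hierarchy process (AHP) synthesis of expert judgment, and a
rank-based radar summary. This vignette explains each model, its assumptions,
and the design decisions taken where the methodology left room.

## Data model: replicate panels and censoring

Composition data arrive as replicate panels: each substrate is assayed in
triplicate per analyte, and every measurement is either observed, not
detected (`ND`), below a quantification limit (`<x`), or the analyte is
absent from the substrate's profile altogether (`None` in published fatty
acid and mineral tables). We distinguish the last two deliberately: `ND`
means the assay ran and found nothing, `None` means the analyte is not part
of the substrate's profile. Non-detects and below-limit values enter group
statistics as zero — the convention of the source tables — while the limit is
retained so `<x` strings survive a round trip through `write_panel()`.

Replicates are summarised as mean ± the half-width of a t-based 95%
confidence interval, $t_{0.975,\,n-1}\, s/\sqrt{n}$; with the study's $n = 3$
the multiplier is $t_{0.975,2} = 4.3027$, so printed half-widths of 0.05
correspond to a replicate standard deviation near 0.02.

The bundled fixtures (`load_fixture()`) carry every printed cell of the
published composition tables — amino acids, reference patterns, printed
scores, fatty acids, vitamins, minerals, growth check points — digit for
digit, including the significance letters and censoring tokens. Two printed
artefacts are preserved rather than repaired: the krill potassium value is
typeset as "2378.68.15" in the source and is stored as 2378.68, and the
printed amino acid aggregates (e.g. isopod ΣEAA 19.57) do not exactly equal
the sums of their per-acid rows (19.41 for the ten essential-flagged acids).
`aa_summaries()` recomputes sums from per-acid contents; the printed
aggregates stay available in the fixture. We do not reconcile the two.

## Protein quality: AAS, CS, EAAI

Scores compare a sample's essential amino acid content with a reference
pattern, both in mg of amino acid per g nitrogen. Contents in g/100 g dry
weight are converted by the factor 62.5 (nitrogen-to-protein factor 6.25 ×
10), treating the printed contents as g per 100 g protein-equivalent with no
re-normalisation by crude protein — the convention that reproduces every
printed score. Methionine+cysteine and phenylalanine+tyrosine are pooled
*before* conversion, giving the eight scoring categories:

$$\mathrm{AAS}_c = \frac{aa_c}{AA^{\mathrm{FAO/WHO}}_c}, \qquad
  \mathrm{CS}_c = \frac{aa_c}{AA^{\mathrm{egg}}_c}, \qquad
  \mathrm{EAAI} = \left(\prod_{c=1}^{8} 100\,\mathrm{CS}_c\right)^{1/8}.$$

The EAAI is the geometric mean of the egg-relative ratios: 100 means
egg-equivalent balance, and a zero in any category sends the index to zero.
Although the index is often described over nine essential amino acids, only
the eight pooled categories above reproduce the published values (34.13,
45.16, 55.93 for isopod, krill and fish meal); the category list is an
argument, so other conventions remain available when matching reference
contents are supplied. The limiting amino acid is the category with the
smallest chemical score, ties broken alphabetically and flagged as
co-limiting.

Two numerical conventions matter. Display rounding is half away from zero to
2 decimals (`round_half_up()`), not banker's rounding; and all tests compare
unrounded values, because the published table was itself computed from
unrounded assay data — one cell (fish meal valine CS, recomputed 0.524,
printed 0.53) differs in the second decimal for exactly that reason, while
remaining within ±0.01 of the recomputation.

Taurine, a non-protein amino acid abundant in the isopod, is counted in the
total and flavor sums by default (`include_taurine = FALSE` gives the
protein-only convention); it never enters the essential-amino-acid scores.

## Growth kinetics

Juvenile growth is modelled as a power law $BW = a\,t^{b}$ fitted by ordinary
least squares on $(\ln t, \ln BW)$ — the spreadsheet "power trendline"
convention, which assumes multiplicative lognormal noise. The reported
$r^2$ is that of the linear fit on the transformed scale (primary, matching
the trendline), with an original-scale $1 - SSE/SST$ also computed. The
birth check point $t = 0$ cannot enter a log-log fit and is excluded with a
warning; it still anchors the weight-gain endpoints:

$$\mathrm{WGR} = \frac{BW_f - BW_i}{BW_i} \times 100\%, \qquad
  \mathrm{SGR} = \frac{\ln BW_f - \ln BW_i}{\Delta t} \times 100\%/\mathrm{day}.$$

From the printed endpoints (0.24 mg, 31.06 mg, 70 d) the SGR is 6.95%/day.
The published 6.97%/day corresponds to an unrounded initial weight of
≈ 0.2366 mg, recoverable from the published WGR of 13026.76%; both paths are
asserted in the test suite to document the rounding provenance. Similarly,
only 6 of the trial's 15 check points are printed, so the published
trendline ($a = 0.1479$, $b = 1.8022$, $r^2 = 0.9466$) is reference metadata
(`growth_reference()`), not a reproducible target: the fit on the six
printed means gives $b \approx 2.21$.

`residual_normality()` standardises the log-scale residuals and applies
Shapiro–Wilk, passing at $p > 0.05$ — supporting (not proving) the lognormal
noise assumption.

## Group comparisons and significance letters

Every analyte is compared across substrates by the same decision chain the
letters in the composition tables encode:

1. **Levene's test** (mean-centred: ANOVA on $|x - \bar
   x_g|$) gates on variance homogeneity at $\alpha = 0.05$.
2. Homogeneous → **one-way ANOVA**, post hoc **Duncan's multiple range
   test**. Heterogeneous → **Welch's ANOVA**, post hoc **Dunnett's T3**.
3. Pairwise decisions are summarised as a compact letter display; groups
   sharing a letter do not differ at $\alpha$.

Duncan's least significant ranges use studentized-range quantiles at the
protection level $\alpha_p = 1-(1-\alpha)^{p-1}$ for a span of $p$ means,
with the pooled error mean square and the harmonic mean group size when
unbalanced (with a warning). The step-down applies the classical protection
rule: a difference is only significant when every range containing the pair
exceeds its own least significant range. Dunnett's T3 uses per-pair
Welch–Satterthwaite degrees of freedom against studentized-maximum-modulus
critical points; since no closed form exists, `qsmm()` evaluates
$P(\max|T| \le q) = \int_0^\infty (2\Phi(qu)-1)^k f_\nu(u)\,du$ by adaptive
quadrature and inverts by root finding. Letters come from the insert–absorb
algorithm applied to the pairwise decision matrix, which guarantees the
letters encode exactly the pairwise decisions even when those are
non-transitive (possible under T3).

Two design choices deserve justification:

* **Omnibus protection.** Post-hoc letters only differ when the omnibus test
  is significant at $\alpha$. Unprotected Duncan on three groups tests its
  widest range at $\alpha_2 = 0.0975$, so the familywise error of the
  pipeline would exceed 7% under the null; with protection the measured rate
  over 2000 null simulations is ≈ 0.05. The gate can be disabled
  (`protect = FALSE`) to study the raw procedures.
* **Letter orientation.** Letter `a` goes to the *smallest* mean by default,
  matching the published amino acid table (the isopod's lowest values carry
  `a`). The published mineral table's manganese row is inconsistent with
  this convention; the fixture stores its letters verbatim rather than
  silently reconciling. `letters = "desc"` flips the orientation.

Fisher's LSD against a designated control substrate is provided as the
cross-check the original analysis used (`lsd_pairwise()`), with the pooled
error mean square and t critical values.

Reconstructing replicate spread from printed intervals
($s = \mathrm{hw}\sqrt{n}/t_{0.975,n-1}$) is used only to build demonstration
fixtures in tests; per-analyte F statistics are printed in the source without
the raw replicates that produced them, so exact F reproduction is not
claimed.

## AHP: priorities, consistency, synthesis

Expert judgment enters as reciprocal pairwise matrices on the 1–9 scale.
Priorities are the principal right eigenvector, computed by power iteration
from the uniform vector with a $10^{-12}$ tolerance — deterministic and
bit-stable per platform, and agreeing with a dense eigensolver to $10^{-8}$
on random reciprocal matrices (a tested invariant). Consistency is judged by
$CI = (\lambda_{\max} - n)/(n-1)$ against Saaty's random indices, with
$CR = CI/RI < 0.1$ acceptable; `ahp_synthesize()` refuses inconsistent
models unless overridden, reporting every matrix's CR.

Group aggregation averages per-expert *priority vectors* arithmetically
(renormalised). The alternative reading — aggregating judgment matrices —
is offered as `aggregation = "matrix_geomean"` using the element-wise
geometric mean, which is the only matrix average that preserves
reciprocity; for identical experts the two coincide. Experts are equally
weighted by default, with optional weights.

The published global weights (fish meal 0.5407, isopod meal 0.2015) came
from three experts' unpublished matrices, so they cannot be recomputed; what
normalisation forces is the krill weight, $1 - 0.5407 - 0.2015 = 0.2578$.
The engine is instead validated by construction: consistent matrices built
from known weights are recovered exactly through the full synthesis chain,
and the published consistency ratios (0.0981, 0.0000, 0.0398) serve only as
plausibility references for what near-consistent expert matrices look like.

## Radar comparison and win counts

Six factors summarise the comparison: ΣFAA/ΣAA (%), ΣEAA/ΣAA (%), EAAI and
ΣPUFA enter with their actual values; vitamins and minerals enter as
50/40/30 rank scores from "highest mean" win counts. A parameter is
comparable only if it is observed in at least one substrate, absent from at
most one substrate's profile, and measured in a trace-concentration unit
(`exclude_units = "%"` drops bulk proximate-style measures such as total
phosphorus; the heterogeneous mass-per-mass vitamin units are all retained
because each comparison is within-parameter). These defaults reproduce the
published counts — nine mineral parameters won 6/2/1 and eight vitamin
parameters won 5/2/1 by isopod, krill and fish meal — and are exposed as
arguments because the published exclusion list is implicit, not stated.
Ties split wins fractionally and share averaged rank scores (two substrates
tied for last share 35 points each), always summing to 120, and are flagged
rather than broken arbitrarily.

## Synthetic data: what it emulates, and what it does not

The generators provide ground-truth data for every stage: `gen_panel()`
draws replicate panels with additive normal noise floored at zero and
limit-based censoring; `gen_growth()` draws power-law trajectories with
multiplicative lognormal noise (weights stay positive, spread grows with
size); `gen_expert_matrices()` perturbs consistent judgment matrices on the
log scale, symmetrised to preserve reciprocity and clipped to $[1/9, 9]$.
All are deterministic given a seed.

They emulate the study's *structure* — triplicates, censoring, 15-point
growth design, three experts — but not inter-analyte correlation, seasonal
or provenance variation in composition, assay-specific error shapes, or
systematic biases between laboratories. Passing tests on synthetic data
therefore demonstrate that the algorithms are correct under the stated noise
models, not that those models exhaust real assay behaviour.

Simulation sizes in the test suite (e.g. 2000 null pipelines for the type-I
rate, 200 growth replicates for exponent recovery, 100 random matrices for
the eigensolver agreement) were chosen to give stable Monte Carlo estimates
at fixed seeds while keeping the default test run fast.

## Known limitations

* No digestibility-corrected protein scores (PDCAAS/DIAAS) and no
  nitrogen-factor estimation; the ×62.5 conversion is taken as exact.
* No two-way or repeated-measures designs, and no multiplicity correction
  across analytes (the source analysis applied none).
* Duncan's test assumes balanced groups; the harmonic-mean correction for
  mild imbalance is a standard approximation, not exact.
* The AHP layer handles complete matrices up to $n = 10$ only; no
  interval/fuzzy judgments or incomplete-matrix completion.
* Wet↔dry basis conversion is the caller's responsibility.
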