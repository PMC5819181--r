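---
title: "Methods: communal-nursing decisions, relatedness and spatial structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: communal-nursing decisions, relatedness and spatial structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`nestshare` analyses female communal-nursing decisions in RFID-monitored
house-mouse colonies. This vignette documents the models, the conventions we
fixed where the field protocol leaves room, the synthetic colony the
package tests itself against, and the limitations of both.

## From antenna events to choice sets

The raw unit is a *stay*: one female (RFID tag) inside one nest box over a
half-open interval `[entry_s, exit_s)` of integer seconds (1 day = 86,400 s;
day 0 is the dataset epoch 2008-01-01). Stays of one female never overlap —
a mouse is in one box at a time — and this invariant is enforced by the
`ColonyDataset` validity method.

**Home area.** For a focal birth on day *d* we examine the tracking window
`[d − 30 d, d)`. The birth instant is excluded so post-birth cohabitation
cannot leak into pre-birth association. A box is *regularly used* when the
cumulated in-window stay time is at least 300 s; the threshold is inclusive
(the protocol excludes boxes entered *less than* 300 s, and the complement
of "< 300" is "≥ 300"). Stays that straddle a window boundary contribute
only their in-window part.

**Meetings and association.** A *meeting* is a maximal interval during
which two females are simultaneously inside the same box; association time
is the summed meeting duration over the focal's window. We chose the
maximal-overlap operationalisation (rather than entry-triggered counting)
because it is symmetric in the pair and robust to how a visit is split
across antenna reads; zero-length boundary contacts are not meetings. A
sweep over interval intersections implements this and is tested against a
1-second discretised brute force.

**Options, occupancy, outcome.** An *option female* gave birth within the
closed window `[d − 16 d, d]` in one of the focal's regular boxes: 16-day-old
pups are still nursing, weaning starts at day 17. Day-16 litters are
included (the closed right end also admits same-day cryptic litters, which
must be part of the window by construction). The occupancy proportion *P*
counts regular boxes holding at least one litter born in `[d − 16, d − 1]` —
boxes, not litters, and a box already hosting a communal nest still counts
once. The outcome is y = 1 exactly when the focal's own box already held a
qualifying litter; the decision belongs to the pregnant female who is about
to give birth, so a solitary-choosing female later joined by another remains
y = 0. Births with zero options are excluded from the decision analysis and
reported separately, preserving the bookkeeping identity
events + exclusions = births.

**Cryptic nests.** Two litters born the same day in the same box are
initially indistinguishable. One female is designated focal uniformly at
random under a stored seed; every dyadic attribute between the two is
symmetric, so the covariates do not depend on the designation. When a focal
joins an existing cryptic nest the chosen partner is ambiguous and the two
residents are replaced by a single pseudo-option carrying the arithmetic
mean of each covariate. Groups of more than two same-day litters (never
observed in the field data) are resolved the same way with a warning.

## The nest-availability power model

Let *P* be the occupancy proportion and *y* the communal outcome. Random
nest-box choice implies E[y | P] = P; deviations are captured by

  y ~ P^a,  a > 0,

a one-parameter family pinned to (0,0) and (1,1). *a* = 1 is the null;
*a* > 1 means communal nursing is rarer than availability predicts. We fit
*a* by nonlinear least squares — deliberately, to mirror the original
analysis, rather than by a binomial GLM — using a damped Newton iteration on
the scalar *a* started at 1 (convergence |Δa| < 1e−8, with a golden-section
fallback on (1e−6, 50) that in practice never triggers). The SE comes from
the linearised Jacobian ∂P^a/∂a = P^a log P (the P = 1 term is 0), the test
of *a* = 1 is a two-sided *t* with df = n − 1 (the protocol does not state a
df; we report ours explicitly). Events with P = 0 are excluded by default:
for them every a > 0 fits perfectly and they carry no curvature; a toggle
(`includeZeroP`) restores them. All-P = 1 data leave *a* unidentifiable and
raise an explicit error. The fit agrees with `nls()` to ~1e−6 in tests, and
under random-box simulation the test's type-I error is calibrated
(about 0.05–0.08 at n = 276).

## Relatedness

**Pedigree expected r** is the coefficient of relationship, computed by the
standard kinship recursion with founders unrelated and non-inbred
(equivalent to path counting over common ancestors), and checked against a
gene-dropping oracle. Dyad classes: full-sib and parent–offspring (r = 0.5),
half-sib (r = 0.25), and unrelated — contemporaneous (birth days within a
year) and sharing no grandparent. In a closed colony "no shared grandparent"
does not preclude deeper kinship; that is faithful to how such classes can
be built from any finite pedigree.

**Wang moment estimator.** At each locus a dyad falls into one of four
genotype-sharing categories (identical; homozygote–heterozygote sharing one
allele; two heterozygotes sharing one allele; no shared allele). With
reference allele frequencies, the expected category probabilities are linear
in the two-gene (φ) and four-gene (Δ) identity coefficients; writing
a2, a3, a4 for the frequency power sums, the no-IBD probabilities of
categories 1–3 are b = 2a2² − a4, d = 4(a3 − a4),
f = 4(a2 − a2² − 2a3 + 2a4), and the one-pair-IBD contrasts are
c = a2 − b, e = 2(a2 − 3a3 + 2a4), g = 1 − 7a2 + 4a2² + 10a3 − 8a4 (the two
derivations were done independently and agree algebraically). φ and Δ are
estimated jointly by least squares on the three category equations and
combined as r = φ/2 + Δ. Loci are pooled with weights 1/(2a2 − a3), which
up-weights polymorphic loci; monomorphic loci and loci missing in either
member are skipped (no imputation), and dyads with fewer than two usable
loci are flagged rather than estimated. Two documented toggles are off by
default: finite-sample unbiased power sums, and leave-dyad-out reference
frequencies (the default keeps the full cohort including the dyad, since
the field protocol is silent on exclusion). Simulation shows the estimator
unbiased for all four pedigree classes (means within 3 Monte-Carlo SEs of
0.5 / 0.5 / 0.25 / 0 at 500 dyads per class) with per-dyad SD ≈ 0.10 at
25 loci × 8 alleles.

**Queller–Goodnight** is the ratio-of-sums form: per direction, numerator =
mean focal-allele sharing minus the focal allele frequencies, denominator =
1 + focal homozygosity minus those frequencies; sums across loci, ratio,
then the two directions averaged. A printed 3-locus toy evaluated by hand
is frozen in the test suite.

**Estimator calibration.** The selection procedure draws 50 dyads per class
(seeded, without replacement), estimates each dyad with every candidate
estimator, and ranks estimators by the Pearson correlation between
class-expected and estimated r. The interface is pluggable: any function
`(genotypes, dyads, freqs) → data.frame(rhat = …)` can join the comparison.
On the default synthetic colony the Wang correlation is ≈ 0.90 with
Queller–Goodnight marginally behind. Field data gave a lower correlation
(≈ 0.8) for the winning estimator; the gap is expected, because a real
calibration inherits parentage-assignment errors (misclassified dyads,
cryptically related "unrelated" pairs) and less informative markers than
the clean simulated panel — with an error-free pedigree and 25 loci of
Dirichlet(1) 8-allele diversity, 0.90 is what the procedure honestly
yields. Parentage inference itself is outside this package's scope.

**Reference frequencies** are computed by allele counting over a cohort —
in the pipeline, the genotyped females of the focal year — with per-locus
sample sizes recorded; monomorphic loci are retained with frequency 1 and
skipped by the estimators.

## Spatial genetic autocorrelation

Each female is located at the box where she is found at a nest check (the
first check per month, 23 checks over two years, to reduce temporal
autocorrelation). Squared genetic distance between two multilocus genotypes
sums a per-locus pattern table (identical 0; AA–AB 1; AB–AC 1; AB–CD 2;
AA–BC 3; AA–BB 4 — the codominant metric of the GenAlEx lineage, which we
treat as normative since the field protocol names the tool but not the
table). Per check, the distance matrix is double-centred (row sums of the
resulting covariance vanish to ~1e−12, tested) and the autocorrelation of a
distance class is the ratio of summed in-class off-diagonal covariances to
the matching diagonal terms, pooled across checks by summing numerators and
denominators. Dyads are never formed across checks — that would pair a
female with herself at another time. Classes are the singleton {0} (same
box) and half-open rings (0,1 m], (1,2 m], …

The permutation null (999 shuffles by default) permutes genotypes among the
located records *within* each check; because genetic distances depend only
on genotypes, a permutation merely relabels matrix indices, so the null is
cheap and exact. Note the finite-sample null is not centred at zero but at
about −1/(n−1) per check — the package reports the permutation mean and the
2.5/97.5% band, and the one-tailed p for positive structure. Bootstrap CIs
resample in-class dyad contributions (1000 by default). The correlogram is
invariant to rigid motions of the coordinates (tested), but class counts
can flip when pair distances sit exactly on a class boundary, as they do on
perfectly regular grids; real layouts and the simulator's are effectively
generic.

## Choice models

The decision model is a plain binomial logistic regression (`glm`) of
communal vs solitary on event-level predictors, continuous ones z-scaled
with stored centre/scale. The original analysis used a GLMM with female
identity as a random effect; random effects are deliberately not fitted
here, so coefficients are comparable in sign and direction only. The
partner model is a conditional logit over each event's option set
(probability of option j ∝ exp(x_j β)), fitted by Newton–Raphson with
step-halving on the exact conditional likelihood; conditioning on the event
removes event-level intercepts by construction, which is our substitute for
the original event/female random effects. Single-option events carry no
contrast and contribute zero information; events whose chosen option lacks
covariates are dropped with a log entry. On 2-option events the fit reduces
algebraically to paired logistic regression on covariate differences, and
both that identity and agreement with `survival::clogit` are tested. The
event-nested permutation test (scenario labels shuffled at the event level,
so an event's options move together) replaces the original linear mixed
model for the option-relatedness comparison; the Wilcoxon–Mann–Whitney test
uses midranks with exact enumeration when min(n, m) ≤ 8 and the
tie-corrected normal approximation otherwise.

## The synthetic colony

The generator reproduces the study design: a 72 m² barn (850 × 850 cm) in
four sections of ten nest boxes (sections impose no movement barrier),
25 microsatellite loci with 8 founder alleles per locus at Dirichlet(1)
frequencies, Mendelian transmission (one known parent transmits one allele,
the other gene is drawn from the founder frequencies), a 2% missing-genotype
rate, gestation-scaled birth scheduling, litter sizes Poisson(5) truncated
at 1 (a free parameter — the field protocol does not state the
distribution), discovery ages uniform on 1–12 d (nest checks every
8–12 days), and observed litter size equal to birth size minus optional
pre-discovery deaths (rate 0 by default so litter-size effects can be
isolated in tests).

Settlement is kin-clustered: founder females settle uniformly; a daughter's
home centre is displaced from her mother's by an exponential distance
(mean 100 cm by default; 50 cm in the strong-clustering scenarios) in a
uniform direction, clipped to the barn. Nest boxes carry lognormal quality
weights (log-sd 3.0) shared by all females, and a female's home set (size
Poisson around 5, clamped 2–9) is drawn by quality × exp(−distance/60 cm).
The quality field is what concentrates breeding into favoured boxes: without
it, litters spread evenly over 40 boxes and a focal female's ~5 regular
boxes would capture far fewer recent litters than the field data show. The
local distance decay keeps the favoured boxes *near* the home centre, so
kin clustering survives the concentration. Within her home set a female
spreads visits fairly evenly (weights flattened to the ¼ power) — regular
use of every home box is what defines the set. Stays alternate with
exponential gaps (5 visits/day, mean stay 1800 s), so per-female intervals
never overlap by construction. With these frozen defaults one simulated
colony yields ≈ 300 litters over two years, ≈ 5.2 regular boxes per female,
≈ 270 choice events with at least one option, a mean of ≈ 3 options per
event (the field value is 3.55; the generator sits slightly under it, range
≈ 2.5–4.5 across seeds), ≈ 40% communal outcomes under random box choice,
and positive spatial genetic autocorrelation at the short distance classes.

Decision rules: `random_box` picks uniformly among the regular boxes
(communal iff the box is occupied — the mechanism behind the *y = P* null);
`power` draws communal with probability P^a and then a uniformly chosen
occupied (or empty) box; `preference` draws the communal decision from a
logit in the number of options and the partner from a conditional logit on
scaled covariates (pup age / 16 d, association time / 1800 s, pedigree
relatedness — fixed scalings recorded in the ground truth so recovery tests
compare like with like). Degenerate corners are explicit: a female forced
communal with no occupied box is recorded solitary with a flag, and a
solitary choice with every box occupied is recorded communal with a flag.
Every stage derives its own RNG stream from the master seed, so identical
configurations reproduce byte-identical datasets.

What the generator does *not* emulate: mortality and dispersal out of the
barn, infanticide (the field study's litter-size caveat), diurnal activity
rhythms (association times are therefore much shorter than the field
values, though comparably variable), genotyping error beyond missingness,
and parentage-assignment uncertainty. Passing tests therefore show that the
statistical machinery recovers known truth under the study's data
structure, not that the biological conclusions of any particular field
dataset are correct.

## Problem sizes and seeds used by the test suite

The suite fixes seeds throughout and scales simulations to what the checks
need: one default colony (~300 litters, ~750 tracked females) shared across
tests; 200 replicates of 276 events for the power-model null; 500 dyads per
class for estimator unbiasedness (300 in the unit test); 20 repeats of the
50 × 4 calibration; a dispersal-50 cm colony with 199 permutations for the
spatial checks (999 is the analysis default); 10,000 gene drops and 10,000
Mendelian offspring for the pedigree and transmission oracles. The whole
suite runs in about two minutes on one CPU.

## Known limitations

* The decision and partner models omit random effects; variance components
  and absolute effect sizes are not comparable to mixed-model output.
* The Wang estimator is implemented from its moment structure (categories,
  power-sum coefficients, joint least-squares identification, 1/(2a2 − a3)
  locus weighting); agreement with any particular legacy implementation is
  asserted via simulation recovery (unbiasedness per class, calibration
  correlation), not output-for-output.
* Parentage assignment is assumed done: the pipeline consumes a pedigree.
* Paired entry/exit records are the canonical input; `pairAntennaReads()`
  adapts bare single-antenna read streams by pairing consecutive same-box
  reads under a stay cap, but flags every capped or unpaired read — capped
  stays are an approximation, not a measurement.
* P is computed from observed litters; litters destroyed before discovery
  are invisible to both the field protocol and the package.
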