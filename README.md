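# nestshare

Communal nursing — two or more female house mice pooling their litters in one
nest and nursing all pups indiscriminately — is a canonical case of costly
cooperation. Whether it is an active choice or a mere by-product of sharing
nest sites can be decided from long-term monitoring data: RFID antennas at
nest-box entrances record every female's movements, regular nest checks
record every litter, and microsatellite genotypes give pedigrees and
pairwise relatedness. `nestshare` implements the full analysis pipeline for
such data, and ships an agent-based colony simulator that emulates the barn
study design so every inference can be validated against known ground truth.

The package is aimed at behavioural ecologists analysing RFID/nest-check
datasets of communally breeding rodents, and at methodologists who want a
tested, seeded re-implementation of the analysis chain.

## What it computes

* **Tracking** — per-female *home areas* (nest boxes entered for a cumulated
  ≥ 300 s in the 30 days before giving birth) and dyadic *association times*
  (total duration two females were simultaneously inside the same box).
* **Choice sets** — for each focal birth, the *option females* (litters born
  within the preceding 16 days in the focal's regular boxes), the occupancy
  proportion *P* (occupied regular boxes / regular boxes), the
  communal/solitary outcome, chosen vs non-chosen partners, and cryptic
  same-day nests (randomly designated focal; averaged covariates when a
  female joins a cryptic nest).
* **Nest-availability model** — the probability of a communal nest is
  modelled as *y ~ P^a* by nonlinear least squares. The curve is pinned to
  (0,0) and (1,1); *a* = 1 is the random-choice null, *a* > 1 means females
  nurse communally less often than nest availability alone predicts. The
  package reports *â*, its linearised SE, and a two-sided *t* test of
  *a* = 1 (df = n − 1).
* **Relatedness** — Wang (2002) and Queller–Goodnight moment estimators from
  cohort allele frequencies, pedigree expected *r* by path counting, and the
  estimator-selection calibration (50 dyads from each of four pedigree
  classes, Pearson correlation of expected vs estimated *r*).
* **Spatial genetic structure** — GenAlEx-style autocorrelation of
  multilocus genotypes over nest-box locations at monthly nest checks:
  squared genotype distances, double-centred covariance, distance classes
  {0}, (0,1 m], (1,2 m], …, permutation null bands and bootstrap CIs.
* **Choice models** — a binary logistic model of the decision to nurse
  communally and a conditional-logit model of partner choice within each
  event's option set, plus a Wilcoxon–Mann–Whitney rank-sum test and an
  event-nested permutation test of scenario differences.
* **Simulator** — seeded generators for pedigree (overlapping generations,
  re-mating, half-sib structure), Mendelian microsatellite genotypes from
  Dirichlet founder frequencies, kin-clustered settlement with shared
  favoured boxes, RFID event streams, and nursing decisions under
  `random_box`, `power` (*y = P^a*) or `preference` (conditional-logit)
  rules — with the generating truth recorded for every downstream check.

## Worked example

```r
library(nestshare)

colony  <- simulateColony(simConfig(seed = 1))   # default: random_box world
colony
#> ColonyDataset
#>   events:     946392 stays, 750 tagged individuals
#>   births:     307 litters by 111 mothers
#>   pedigree:   1628 individuals (32 founders)
#>   genotypes:  1628 x 25 loci
#>   layout:     40 nest boxes
#>   detections: 3052 records over 23 nest checks
#>   simulation ground truth attached

choices <- buildChoiceTable(colony, seed = 1)
choices
#> choiceTable: 268 choice events (117 communal, 151 solitary), 39 excluded births
#>   options per event: mean 3.03 (range 1-10); 0 incomplete events

fitPowerNull(choices$events$P, choices$events$y)
#> Nest-availability power model y ~ P^a (NLS, n = 268)
#>   a = 0.958 (SE 0.083); H0 a = 1: t = -0.51, df = 267, p = 0.6096

estimatorCalibration(colonyPedigree(colony), colonyGenotypes(colony), seed = 1)
#> Relatedness estimator calibration (expected vs estimated r)
#>  estimator correlation   n rank
#>       wang   0.9100750 200    1
#>         qg   0.9095489 200    2
```

Reading the output: under the default `random_box` rule females pick a nest
box uniformly among their regular boxes, so the fitted exponent *â* = 0.96
is statistically indistinguishable from the null *a* = 1 (p = 0.61) — the
model correctly reports that communal nursing in this world is a pure
by-product of nest availability. The calibration table ranks the bundled
relatedness estimators by how well they track pedigree expectations on this
colony (Wang narrowly first, as in the field study). Simulating instead with
`decisionMode = "power", powerA = 1.3` plants the avoidance of communal
nests the field data showed, and `decisionMode = "preference"` plants
conditional-logit partner choice whose weights the partner model recovers.

`runPipeline(simConfig(seed = 1), outDir = "run1")` executes the whole chain
(simulate → track → choice sets → relatedness calibration → correlogram →
models) and writes `choice_events.csv`, `options_long.csv`,
`navail_fit.json`, `calibration_report.csv`, `correlogram.csv`,
`decision_fit.csv`, `partner_fit.csv`, home areas, associations, GenePop
genotypes and a reproducible run manifest.

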