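---
title: "Shift-based team communication networks: models, metrics and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shift-based team communication networks: models, metrics and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shiftnet)
```

## The problem

Communication among emergency-department personnel is interdependent: who a
nurse approaches with a medication question depends on who else is on the
floor, which makes the usual independent-observations toolkit inappropriate.
Sociometric surveys handle this by asking every rostered person, at the end
of a shift, how many times they initiated communication toward each named
colleague (a 0--10+ frequency scale), separately for several relation types
-- here general problem solving, medication advice seeking, and general
socializing. Each shift then yields, per relation, a directed weighted
adjacency matrix over that shift's roster, and the analysis proceeds at the
level of whole networks observed repeatedly: weekly day and night shifts
over a study period.

`shiftnet` implements that pipeline: survey ingestion and matrix
abstraction, the three standard whole-network statistics, a permutation test
for association between relation networks, longitudinal stratified
reporting with sociogram export, and a seeded synthetic generator so that
every stage is testable without access to raw (confidential, typically
undeposited) survey data.

## The statistics

All three statistics are computed exactly as in the field's standard worked
examples; `network_density()` and `degree_centralization()` operate on the
symmetrized binary *dyadic* network, in-degree measures on the raw directed
binary matrix. That split is deliberate: the dyad-level arithmetic of the
classic density example counts unordered pairs on one side of the diagonal,
while in-degree is inherently directed (who is *targeted*).

**Density.** The fraction of observable dyads carrying at least one tie,
as a percentage. With 4 members and 5 of the 6 dyads tied, density is
$100 \cdot 5/6 = 83.3\%$.

**Freeman degree centralization.**
$$C = 100 \cdot \frac{\sum_i (d_{\max} - d_i)}{(n-1)(n-2)}$$
with $d_i$ the binary symmetric degrees. The denominator is the value the
numerator attains on a star, so $C$ is 0 for regular networks and 100 iff
the network is a perfect star. On the 4-member example (degrees 3, 3, 2, 2)
the numerator is $0+1+1 = 2$ and the denominator $(n-1)(n-2) = 6$, giving
$33.33\%$.

**In-degree centrality.** For member $j$, the count of potential senders
who reported communicating toward $j$, divided by the number of potential
senders (rostered members other than $j$ whose survey row was observed).
The network-level **in-degree centralization** uses the standard directed
Freeman denominator $(n-1)^2$:
$$C_{in} = 100 \cdot \frac{\sum_j (d^{in}_{\max} - d^{in}_j)}{(n-1)^2},$$
100 exactly when one member receives from everyone and nobody else receives
at all. The denominator is a convention choice (the worked examples in the
applied literature rarely print it); we use the standard directed form and
record it here.

**Stars and isolates.** Isolates are members with no tie in the symmetrized
network. Stars are all members attaining the maximal in-degree -- ties are
never broken arbitrarily; every maximizer is reported.

## The QAP test

Whether two relation networks on the same roster overlap cannot be tested
by treating cells as independent observations: rows and columns of a
network share actors, so cell errors are autocorrelated. The quadratic
assignment procedure (QAP) respects this by permuting *node labels*: each
permutation $\pi$ is applied simultaneously to the rows and columns of one
matrix ($Y_{\pi(i)\pi(j)}$), which preserves the network's internal
structure exactly while destroying its alignment with $X$. The observed
Pearson correlation over jointly observed off-diagonal cells is compared to
the permutation distribution.

Conventions, all recorded in the output:

- **Valued by default.** Frequencies are correlated as reported; a
  `binary` flag dichotomizes first. Every printed worked calculation in the
  density/centralization tradition is binary, but network *association* is
  about frequency profiles, so the valued form is the default.
- **p-values.** Monte-Carlo mode uses the conservative add-one estimator
  $p_{\ge} = (1 + \#\{r_{perm} \ge r_{obs}\})/(1 + N)$, never exactly zero;
  two-sided is $\min(1, 2\min(p_{\ge}, p_{\le}))$. For networks of 7 or
  fewer members all $n!$ relabelings are enumerated instead and exact
  proportions reported (`method = "exhaustive"`).
- **Missingness.** Nonrespondent rows stay attached to their nodes:
  permutations are drawn over all nodes and cells missing in either matrix
  *after* alignment are excluded pairwise. A test is refused (never NaN)
  when fewer than 3 jointly observed cells remain or either vector is
  constant.
- **Permutation count.** Default 1000; a seed is mandatory in Monte-Carlo
  mode and recorded in every result, so panels reproduce bit-for-bit.

`qap_panel()` applies the test to every shift-point and relation pair,
keeping day and night strata separate: a 12-week day/night design gives 24
correlations per pair, 72 in all. Failures (degenerate shift-points) are
reported in a `skipped` attribute, never dropped silently.

## The synthetic generator

No raw sociometric data are distributed with studies of this kind, so the
package ships a generator whose defaults encode the study design the
analysis assumes: 12 weeks x {day, night}, 19-member rosters drawn from
nine clinical roles (2 AMD, 3 RMD, 6 SRN, 1 TRN, 1 TRAMRN, 1 CRN, 3 PCT,
1 HUC, 1 RC), three relations per shift, and 18% per-person nonresponse
(the complement of the 82% response rate typical of end-of-shift survey
collection). Personnel are sampled each week from a fixed pool of 2.5x the
per-shift count per role, producing the repeat-respondent structure
(members recurring across weeks) that longitudinal designs rely on.

Ties are Bernoulli per ordered pair and relation $r$ with log-odds

$$\eta_{ij}^{(r)} = \beta_r + s^{(r)}_i + s^{(r)}_j + \lambda_r z_{ij} + \delta\,\mathbf{1}[\text{night}],$$

and positive ties receive weights $\min(10,\, 1 + \text{Poisson}(\mu - 1))$,
capped at 10 because the survey scale itself caps at "10+" (no information
beyond 10 exists, so none is generated).

This is the simplest mechanism that *independently* controls the four
features the analysis measures:

- $\beta_r$ (`base_logit`, defaults $-0.8, -2.0, -0.6$) sets per-relation
  density, ordered so medication advice is sparsest, matching the
  consistent empirical ordering in ED communication studies;
- $s^{(r)}_i \sim N(0, \sigma^2)$ (`sociability_sd`, default 0.6) creates
  degree heterogeneity, hence nonzero centralization;
- $z_{ij}$, a dyad-level standard-normal factor symmetric in $(i,j)$ and
  shared across relations, couples the relations: the product
  $\lambda_a \lambda_b$ governs the expected inter-relation correlation;
- $\delta \ge 0$ (`night_density_offset`, default 0.6) raises night-shift
  density, the direction reported for EDs where night volume dominates.

Sociability is drawn *per person per relation* rather than shared across
relations. This is deliberate: with shared sociability the three relations
would be correlated even at $\lambda = 0$ through their common senders and
receivers -- a node-level confound the QAP's node permutations do not
absorb -- and "zero overlap" would not mean "independent". Keeping
$\lambda_r z_{ij}$ as the *only* cross-relation coupling makes the
generator's overlap dial interpretable and makes the type-I calibration of
the test meaningful.

`calibrate_overlap()` tunes a common $\lambda$ to a target expected
correlation by simulating complete-data shifts over a loading grid and
interpolating along the (monotone) mean-correlation curve. With the default
density and weight parameters, expected valued correlations up to roughly
0.55 are reachable; a target of 0.4 calibrates to $\lambda \approx 3.7$.

**What the generator does not emulate.** Roster size is fixed per
configuration (no census fluctuation); weights are independent of the dyad
factor given the tie (association is carried by tie pattern, not by weight
magnitude); there is no role-assortative mixing (a charge nurse is no more
targeted than her sociability makes her), no temporal drift across weeks,
and no informative nonresponse (missingness is MCAR). Passing tests
therefore demonstrate correctness of the *measurement and testing*
machinery under a plausible data-generating process, not that real ED
communication follows this model.

## Numerical and format conventions

- **Tie threshold.** A reported frequency $\ge 1$ constitutes presence;
  the minimal reading of presence/absence. Configurable everywhere.
- **Symmetrization.** Union rule: a dyad is tied if either direction
  reaches the threshold among non-missing reports. A dyad with both
  directions missing is *excluded from the denominator* (and counted in
  `excluded_dyads`) rather than treated as absent -- treating it as absent
  would deflate density mechanically as nonresponse rises.
- **Missing vs zero.** A nonrespondent's outgoing row is missing, not
  zero; their incoming column entries from respondents are retained.
- **Rounding.** Percentages print at one decimal, half away from zero
  (base `round()`'s banker's rounding would turn 82.25 into 82.2).
- **Quartiles.** Boxplot summaries use the inclusive linear-interpolation
  convention (`stats::quantile` type 7) and the midpoint median; the
  convention is recorded in the summary's attributes and the run manifest.
- **CSV dialects.** UTF-8, comma-delimited, headers required. Roster:
  `shift_id,date,shift,person_id,role` (shift accepts `day`/`night` or the
  survey-block labels `AM`/`PM`). Surveys:
  `shift_id,respondent,relation,target,frequency`, with the literal `10+`
  accepted and parsed as 10; pairs not listed by a respondent who appears
  in the file default to 0; members with no rows are nonrespondents.
  Attendance: `shift_id,completed,refused,not_located`, with the pooled
  response rate computed from totals, not averaged over shifts.
- **Degenerate inputs.** Undefined metrics abort with a message (density
  needs $\ge 2$ members and $\ge 1$ observable dyad, centralization
  $\ge 3$ members, correlation $\ge 3$ jointly observed cells with
  variance); panel functions convert these aborts into `skipped` records.
- **Determinism.** Every random stage (generation, nonresponse, QAP
  sampling, layout) takes a seed; panel functions derive per-cell sub-seeds
  from one panel seed and record them in their outputs.

## Sociogram export

`export_sociogram()` emits GraphML and DOT with node attributes (role,
normalized in-degree, size, isolate flag, layout coordinates) and edge
attributes (weight, width). Node size is an affine map of in-degree on the
fixed domain $[0,1]$ into $[6, 30]$, edge width an affine map of frequency
on $[1,10]$ into $[0.5, 5]$ -- fixed domains so sizes are comparable across
shifts; the classic displays state proportionality only, so the constants
are package conventions. Isolates form a separate layout group stacked
beside the connected component, reproducing the familiar
"unattached members in the corner" reading. The text files are the
canonical output; `autoplot()` methods render them when graphics are
wanted.

## Verification problem sizes

The package's own checks exercise: exhaustive enumeration of all tie sets
on up to 5 nodes against loop-based oracles (1096 networks); full $n!$ QAP
enumeration against an independent Heap's-algorithm oracle at $n \le 6$ and
Monte-Carlo agreement at 10,000 permutations; a 500-replicate type-I
calibration of the two-sided test at $\alpha = 0.05$ on 19-member rosters
(499 permutations each, the count at which the add-one estimator's
two-sided size is 0.048); and recovery of a calibrated $r \approx 0.4$
overlap by the median of a 24-shift-point panel. These sizes give
Monte-Carlo error comfortably below the tolerances asserted while keeping
the default suite around two minutes.

## Known limitations

- Density and centralization treat excluded dyads by denominator removal;
  under heavy, non-random nonresponse both remain biased estimates of the
  complete-network values.
- The exhaustive QAP cap (n <= 7) is a compute guard, not a statistical
  boundary; above it the add-one Monte-Carlo p is conservative by
  construction.
- The weighted QAP correlates raw 1--10 frequencies; no rank-based variant
  is provided, so heavy-tailed reporting styles load on Pearson's
  sensitivity to extremes (the binary flag is the robust alternative).
- `run_pipeline()` exports one sociogram per run (the configured or
  maximal-density shift); batch export is a loop over
  `export_sociogram()` left to the user.
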