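---
title: "Methods: cost-benefit modelling for large SNP panel forensic databasing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cost-benefit modelling for large SNP panel forensic databasing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(figgcba)
```

## The question the model answers

National forensic DNA databases (CODIS/NDIS in the US) index short tandem
repeat (STR) profiles and return *hits* — direct matches between a crime-scene
profile and a reference or another crime-scene profile. Forensic investigative
genetic genealogy (FIGG) instead types thousands of SNPs and finds *kinship
associations* to relatives of the unknown donor, so it can generate an
investigative lead even when the donor has never been arrested. Sequencing a
large SNP panel costs more per sample than STR typing by capillary
electrophoresis. The package asks whether the system-level benefits — more
uploadable profiles, far higher lead rates, earlier identification of serial
offenders and therefore prevented victims — justify that cost.

`figgcba` implements three connected models:

1. a **deterministic bounding model** of leads, prevented victims and
   monetised savings per crime category;
2. a **Monte Carlo model** propagating triangular/uniform input uncertainty
   through the same chain, with one-at-a-time tornado sensitivity;
3. a **cost model** for reagents, caseload, instruments and cost per
   investigative lead.

## The multiplicative chain

Everything flows through one chain. For a pool of $N$ database profiles, an
upload increase $u$ (the extra profiles a more sensitive assay would push over
the upload threshold), a category share $p$ (fraction of profiles belonging to
the crime category), a kinship lead rate $h$, and a recidivism/victim-reduction
rate $r$:

$$
\text{leads} = N \,(1+u)\, p\, h, \qquad
\text{victims prevented} = \text{leads} \times r,
$$
$$
\text{savings}_\text{tangible} = \text{victims} \times C_t, \qquad
\text{savings}_\text{intangible} = \text{victims} \times C_i,
$$

with per-case tangible cost $C_t$ (medical, productivity, adjudication, ...)
and intangible cost $C_i$ (quality of life). Added police labor is reported as
its own line, $\text{leads} \times \text{hours} \times \text{rate}$, and never
netted from savings (no netted figure exists in the published summary
tables; `run_trials()` users can net it themselves from the trial table).

Scopes:

* **lifetime** — the chain runs separately on the pool of profiles that never
  hit ($1{,}144{,}255 - 587{,}773 = 556{,}482$) and on the lifetime hit pool
  ($587{,}773$), then sums;
* **annual** — the chain runs on the yearly upload stream (114,426 profiles),
  with no hit/no-hit split;
* **murder** — its own front end: reported murders $\times$ uncleared fraction
  ($17{,}284 \times 0.386 = 6{,}671.6$ unsolved/year), times a profile yield
  (0.30–0.50), accumulated over a 10-year horizon, then
  $\times (1+u) \times h$ and a serial-murder reduction rate (0.05–0.15).

### Why costs sit at the base case in the bounding model

The published low/high dollar chains pair endpoint *rates* with *base-case*
per-case costs (e.g. the murder bounds both use the \$2,658,319 base tangible
cost). `category_lifetime()`/`category_annual()` therefore move
$u, p, h, r$ (and labor inputs) to their endpoints while holding $C_t, C_i$
at the mode. The Monte Carlo model samples *all* inputs, so the containment
bound for simulated trials is computed separately by `static_envelope()`,
which pushes every input — costs included — to its endpoints; because the
chain is a product of non-negative factors, it is monotone in each input and
those are exact attainable bounds.

## Parameters

All inputs live in one JSON document (`default_config()`,
`inst/extdata/default_config.json`):

* per category (sexual assault, all other violent/property crimes combined,
  murder): tangible and intangible cost per case (USD), upload increase
  (fraction, triangular 0.05/0.10/0.20), upload ratio (fraction), annual case
  totals, investigative lead rate (triangular 0.59/0.76/0.88, from published
  kinship-association rates in consumer-genomics databases), victim-reduction
  rate, extra investigation hours (10/30/50 h) and police hourly rate
  (\$24/\$46/\$71);
* category shares known only as ranges (13.5–20% sexual assault, 80–86.5%
  other crimes) are uniform, matching how they were originally modelled;
  all other uncertain inputs are triangular with the stated base case as the
  mode — including *right-degenerate* triangles where the base case equals
  the maximum (victim-reduction rates 0.30/0.67/0.67 and 0.30/0.65/0.65),
  which are valid and handled exactly by the inverse-CDF sampler;
* database state: NDIS/SAKI counts (total forensic profiles 1,144,255;
  lifetime hits 587,773; kit chain 80,325 completed / 33,398 uploaded /
  15,784 hits / 10,550 serial hits) and the \$2–3B cumulative funding range;
* cost model: reagent kit prices (12-library SNP panel kit \$11,499;
  hypothetical 96-library kit \$23,000; run kits \$1,500 MiSeq / \$2,737
  NextSeq P2; microarrays \$49–\$255/sample), instrument purchases, and the
  two annual budget scenarios. Capital lines are straight-line amortised over
  10 years. All money is nominal USD — the underlying 2014–2022 sources are
  mixed without deflating, and the package follows suit.

## Monte Carlo model and its two wirings

Each trial independently samples every uncertain input and evaluates the
chain; 1,000 trials is the conventional default, and summaries report mean,
sd, extremes, the 2.5/25/50/75/97.5% quantiles and equal-width 30-bin
histograms (both counts configurable).

The published description leaves one wiring ambiguity: the input tables carry
both "total cases x upload ratio" rows and the annual-upload stream used by
the static annual arithmetic. Both readings are shipped:

* `variant = "annual_uploads"` (default): the annual chain
  $114{,}426 \,(1+u)\, p\, h\, r$, murder through its unsolved-case front end.
  Its closed-form expectations land within a fraction of a percent of the
  published best-estimate means for every outcome, so it is taken to be the
  wiring behind those figures.
* `variant = "total_cases"`: the tables-verbatim chain
  $\text{total cases} \times p \times \text{upload ratio} \times (1+u)
  \times h \times r$, which produces systematically larger outcomes
  (roughly 40% higher expected victims for sexual assault).

Inputs are sampled independently within and across categories; no
correlations are stated anywhere in the source material. The original
description counts "eighteen probability distributions" without saying which
are shared across categories; this implementation samples each category's
eight uncertain inputs separately (24 streams). Expected outcomes are
unaffected (products of independent means); only the spread of the
*combined* outcome could differ if, say, one lead-rate draw were shared by
all three categories.

### Sampling

Triangular draws use the closed-form two-branch inverse CDF,
$x = \ell + \sqrt{U (h-\ell)(m-\ell)}$ for $U < (m-\ell)/(h-\ell)$ and
$x = h - \sqrt{(1-U)(h-\ell)(h-m)}$ otherwise, which is exact for degenerate
modes on either bound; uniforms are affine transforms of $U(0,1)$. All
randomness flows through `stats::runif()`, so a single `set.seed()` (the
`seed` argument of `run_trials()`) makes results bit-reproducible. Inputs are
drawn column-wise in the fixed order of the configuration table, so adding
trials or reordering categories changes draws predictably.

## Tornado sensitivity

`tornado()` evaluates the deterministic model once per uncertain input at the
input's low and high bound with every other input at its base case, and ranks
inputs by the absolute outcome swing — the standard one-at-a-time tornado
computation. Point inputs yield zero swings; no variance-based (Sobol)
decomposition is attempted because the underlying analysis uses only
one-at-a-time sensitivity.

## Synthetic scenarios and oracles

`generate_scenario()` emulates the structure the analysis assumes —
independent triangular/uniform inputs feeding the multiplicative chain, plus
a database state satisfying all count orderings — so the whole pipeline is
testable without external data. Triangular modes are drawn uniformly inside
the bounds, with a 10% probability of sitting exactly on the upper bound to
exercise the degenerate-triangle path that the real inputs contain. What the
generator does *not* emulate: correlations between inputs, heavy-tailed cost
distributions, year-to-year trends, or any unit-level case data (there is
none to resample). Passing tests therefore demonstrate correct uncertainty
*propagation*, not that the input ranges themselves are right.

Two oracles check the engine:

* `oracle_expectation()` — the expectation of a product of independent
  factors is the product of their analytic means (triangular
  $(\ell+m+h)/3$, uniform midpoint); simulated means must converge to it;
* `oracle_enumeration()` — for discrete few-valued inputs the outcome
  distribution is enumerated exhaustively, and the empirical distribution of
  the same sampler must approach it in total variation.

## Numerical choices

* Full-precision propagation everywhere: intermediates are never rounded
  (the published chains demonstrably carry unrounded intermediates, e.g.
  20,015 profiles $= 6{,}671.624 \times 0.30 \times 10$); rounding happens
  only at display — counts to integers, per-sample prices to cents,
  per-lead/per-hit prices to whole dollars, aggregate tables to dollars with
  US thousands separators.
* Stochastic convergence tests compare simulated means to the closed-form
  oracle in standard-error units. A family of $k$ simultaneous 3-sigma
  checks is expected to see $0.0027k$ chance exceedances, so joint checks
  require every comparison within 4 SE and allow at most one in (3, 4] SE —
  the multiplicity-aware reading of a per-comparison 3-sigma rule.
* Histogram bins are equal-width over the observed range (30 by default);
  degenerate constant outcomes collapse to a single bin.
* Validation reports every violated invariant with the path of the offending
  field (`categories[murder].tangible_cost: ...`), and count orderings
  (hits $\le$ profiles; serial hits $\le$ hits $\le$ uploads $\le$ kits) are
  enforced on load.

## Known inconsistencies in the published figures

Three places where the published numbers cannot all be right are resolved as
follows (each is flagged in the fixture or tests):

* The database-work budget line is quoted as \$289,580,000 in prose
  ($10^6$ samples at \$289.58) but \$298,580,000 in the budget table, whose
  \$943,090,000 total — reused by the cost-per-lead table — is consistent
  only with the latter. The fixture carries the table value;
  `database_population_cost()` computes the correct product.
* The sequencer outlay (\$73.5M = \$36.2M + \$37.3M) is inconsistent with
  200 MiSeq systems at \$180,000 (\$36.0M). The fixture records both the
  printed unit prices and the printed line totals.
* The other-crimes *lifetime hit-pool* savings figures imply effective
  category shares of 0.768 (low) and 0.754 (high) rather than the stated
  0.80/0.865 — no composition of the stated inputs reproduces them, although
  the same chain reproduces every sexual-assault, murder, no-hit-pool and
  annual figure to well within 0.1%. The package computes the consistent
  chain; the affected published lifetime aggregates are asserted in the
  acceptance tests at face value and documented as failing. One published
  annual victim count (17,103 for other crimes, low) is a digit
  transposition of 17,013, the value implied by both of its companion
  dollar figures.

## Problem sizes

The test suite exercises the simulation at up to $10^5$ trials per run and
20 synthetic scenarios for oracle convergence, 300 seeds of generator
fuzzing, and 50,000 draws for the enumeration total-variation check; the
reproduction script runs the full static analysis plus one $10^5$-trial
simulation. These sizes give standard errors of roughly 0.1% on simulated
means, an order of magnitude below the differences the checks need to
resolve.

## Limitations

The model inherits the scope of its source analysis: savings count only
recidivism-avoided victims (no deterrence, adjudication downstream costs, or
wrongful-conviction effects); proportions of database profiles per crime
category are assumed equal to reported-crime proportions; all figures are
US-centric and nominal-dollar; and the murder chain monetises only
serial-offender victim reduction. The lead rate range (59–88%) is borrowed
from consumer-database kinship studies and may be optimistic for casework
samples. None of these can be tightened without data the forensic community
does not currently publish — which is, in part, the point the analysis
makes.
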