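---
title: "Causal pies, response types and SUTVA: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Causal pies, response types and SUTVA: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sccsutva)
```

## The model

A sufficient component cause (SCC) model represents disease causation as a
collection of "pies": minimal sets of conditions that jointly suffice for
the outcome. In this package a pie has two kinds of slices — *exposure
literals*, a manipulable variable held at a specific level (`E = exposed`,
`ride = hilly`, `I = others_exposed`), and *background components*, the
unmeasured causal partners an individual either carries or not (`U`, `W`,
`X`, ...). The binary end-of-study outcome of an individual with component
profile $P$ under exposure assignment $a$ is

$$Y(P, a) = \max_{\text{causes } c} \; \mathbf{1}\{\text{lit}(c)
  \subseteq a\} \cdot \mathbf{1}\{\text{comp}(c) \subseteq P\},$$

i.e. 1 iff some pie is completed. Three semantic commitments matter:

* **Timeless evaluation.** Only end-of-study component presence counts; no
  event ordering is modelled. An individual carrying both the exposure's
  causal partner and a background mechanism is *doomed* — the exposure has
  no effect on their end-of-study outcome even if, mechanistically, it
  would have acted first. This is the excess-effect (not etiologic-effect)
  convention of epidemiologic methods: always give priority to the doomed.
* **Partial literals.** A cause whose literals mention only some exposure
  variables fires whenever those literals match, whatever the other
  variables' levels (the background mechanism `X` ignores everything).
* **Preventive action is positional.** A protective exposure is encoded as
  a cause containing the *reference* level (e.g. `unexposed + W`), never as
  a negative weight; this stays inside SCC semantics. Causes with two
  levels of one variable are contradictions and are rejected by
  `validate_model()` rather than silently dead.

Profiles are distributed either as independent Bernoulli draws with
per-component prevalences, or by an explicit joint table when dependence
between partners matters. We deliberately allow *all* subsets as profiles —
e.g. carrying both the causal partner `U` and the preventive partner `W` —
and let prevalence settings (or a joint table) restrict the population;
nothing in pie semantics forbids coexistence.

## Response types, stability and monotonicity

`enumerate_response_types()` evaluates all $2^k$ profiles ($k \le 20$
components; beyond that the Monte Carlo engine is the tool) under a
condition set and groups profiles by their outcome vector. The outcome
vector *is* the response type: narrative categories like "those with U2
only" overlap across profiles, while the vector partition is well defined,
so types are keyed by vectors and narrative categories appear only as
annotations (labels, profile lists). For one binary contrast the four
vectors are the classic doomed/causal/preventive/immune taxonomy and

$$\mathrm{RD} = \Pr(\text{causal}) - \Pr(\text{preventive}).$$

The canonical condition order puts the exposed level before the reference
within a context and contexts in declaration order, making every table and
file byte-stable across runs.

**Monotonicity** ("the exposure is never preventive") is implemented
*distributionally*: `apply_monotonicity()` zeroes the prevalence of every
component that appears only in reference-level causes, leaving structure
intact. The "grey rows" stay printable with probability 0, the transform is
idempotent, and no outcome vector changes — only masses. The alternative,
structurally deleting preventive causes, would hide rather than zero them.

**Stability.** Given contrast groups — one (exposed, unexposed) pair per
version or interference context — a type has *stable potential outcomes*
iff its sub-vector is identical across groups, and a *stable causal effect*
iff the within-group difference is identical across groups. The first
implies the second; the converse fails (a type can be immune in one context
and doomed in another: outcomes unstable, effect stably null).
`unstable_profile_mass()` is the total probability of unstable-outcome
types: it is exactly 0 when SUTVA holds, and it is the lever that makes the
identified effect depend on the version/context mix. One wrinkle worth
stating: `unstable_type_count` counts distinct outcome vectors with
positive mass, not narrative profile categories; in the packaged
interference model the two coincide (three unstable vectors), but they need
not in general.

## Effects as mixtures

When versions or contexts vary, `mixture_effect()` computes per-stratum
risk differences and their weighted average. The implemented regime assigns
versions/contexts *independently of profiles*, as randomization does; then
the overall risk difference is exactly $\sum_s w_s \mathrm{RD}_s$ and is
invariant to relabelling strata. Version distributions correlated with
profiles (versions as confounders) are out of scope and refused by the
interface rather than approximated.

Interference is handled by treating the influential-others variable as a
context stratifier shared population-wide within a stratum. Pairwise
(spousal) interference is expressed by *recoding to four exposure
conditions* — own exposure crossed with the partner's
(`interference_conditions()`) — not by simulating a network.

## The synthetic-data generator and the trial engine

`sample_population()` realizes the hypothetical study population: $n$
individuals, profiles i.i.d. from the model's distribution. The packaged
models carry these defaults, chosen once so that every response type with a
role in the taxonomy has visibly nonzero mass and risks stay mid-range:

| model | prevalences |
|---|---|
| `basic` | U = 0.3, W = 0.1, X = 0.2 |
| `versions` | U1 = 0.5, U2 = 0.5, W = 0.1, X = 0.2 |
| `interference` | U1 = 0.3, U2 = 0.2, U3 = 0.2, W1 = 0.05, W2 = 0.05, X = 0.1 |

All are free parameters of the spec files, exposed for overriding; analyses
that need a particular configuration (e.g. asymmetric version effects
U1 = 0.5, U2 = 0.2, X = 0 to make the mixture line move) set it explicitly.

`run_trial()` is an *idealized* randomized controlled trial: Bernoulli
assignment with full compliance, no loss to follow-up, outcomes read
directly off the model. Exposed individuals draw a version when the spec
provides a version distribution; the interference context is *global per
trial run* — either fixed, or set by a threshold rule on the realized share
assigned to exposure ("influential by number"). Partial-context mixing
(some individuals facing exposed others, some not, in one run) is not
supported; grids over context distributions are realized by combining
fixed-context runs with the grid weights. Because the simulation knows each
individual's profile, it knows their true response type, and
`exchangeability_diagnostic()` can report the total-variation distance
between arm-specific type distributions — a quantity fundamentally
unobservable in real data.

What the generator emulates is therefore the *assumptions* of the
potential-outcomes argument, not real studies: no confounding by design, no
measurement error, no non-compliance, no time-to-event structure, no
social-network topology (influential others act population-wide or not at
all). Passing tests show the arithmetic of effects and SUTVA violations is
right; they say nothing about how large such violations are in any real
population.

### Randomness and reproducibility

One root seed drives everything. Each stage (population, arm assignment,
version draws, each grid-point replicate) derives its own sub-seed by a
deterministic affine map kept below $2^{31}-1$, so stages are independently
reproducible and identical `(model, n, spec, seed)` give bit-identical
results; the global RNG state is saved and restored around every draw.
Probability validations use a tolerance of $10^{-12}$ (weights and joint
tables must sum to 1 within $10^{-9}$ and $10^{-12}$ respectively); printed
probabilities carry 6 decimal places with no locale dependence.

### Problem sizes

Exact enumeration covers the packaged models trivially (at most $2^6$
profiles). The simulation checks in the test suite use populations of
100,000 individuals across 20 seeds for effect recovery (Monte Carlo
tolerance: four standard errors of the estimated risk difference) and
20,000 individuals with 10 replicates per grid point for the mixture-line
sweeps; the exchangeability diagnostic concentrates well below 0.02 at
these sizes. These sizes make the binomial noise a small fraction of the
effects being verified while keeping a full run in tens of seconds.

## Design notes and limitations

* For a model with *no* SUTVA violation there is no version or context to
  sweep, so invariance of the estimand is demonstrated across assignment
  probabilities (`mode = "assignment"` in `sutva_bias_experiment()`)
  instead — the estimand is a population quantity and must not move with
  the design.
* Only excess (end-of-study) effects are computed; etiologic effects would
  require component timing, which the representation deliberately omits.
* Risk differences only; ratio measures would need the same machinery but
  are not implemented.
* The CLI is a thin wrapper over the exported functions; stochastic
  subcommands refuse to run without an explicit `--seed` so that no output
  is ever silently irreproducible.
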