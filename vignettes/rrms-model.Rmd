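---
title: "A lattice model of Teff–Treg cross-regulation in relapsing-remitting MS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A lattice model of Teff-Treg cross-regulation in relapsing-remitting MS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrmsim)
```

## The biological picture

Relapsing-remitting multiple sclerosis alternates episodes of neurological
worsening (relapses) with partial or full recovery (remission). The package
models the local cellular mechanism hypothesised to drive this course: a
predator–prey-like cross-regulation between autoreactive effector T cells
(Teff, the "prey-like grower" feeding on myelin) and regulatory T cells
(Treg, the predator that suppresses activated Teff and is stimulated to
proliferate by doing so), with a ubiquitous latent virus (EBV-like) as the
environmental trigger that activates both populations through molecular
mimicry. Genetic predisposition is represented by the continual thymic output
of self-reactive T cells; the disease phenotype by a breakdown of the
cross-regulation — Tregs whose maximum duplication rate is a quarter of the
Teffs' ("hill" patients) instead of equal to it ("healthy" patients).

The model deliberately omits antigen-presenting cells, cytokine fields,
lymphoid compartments and the blood–brain barrier: activated Teff and Treg
are the only agents that interact with the tissue, so all other interactions
can be imagined to occur elsewhere.

## State, rules and schedule

The tissue is a toroidal `grid_size × grid_size` lattice (51 × 51 by
default). Toroidal wrapping avoids edge artifacts that a bounded patch of
white matter would introduce and matches the default behaviour of the
modelling environments this class of model is usually built in. Coordinates
are 0-based `(row, col)`; all radius tests use toroidal Euclidean distance
with an inclusive boundary; neighbourhoods are Von Neumann (4 orthogonal
patches).

Each patch starts with `init_mye` = 100 myelin units. An attack removes
`eat_mye` = 5 units (floored at zero); while a patch retains any myelin it
regrows `rec_mye` units per step up to `init_mye`; a patch at zero is a
permanent lesion. Damage is accounted in myelin units: the deficit of
non-zero patches is recoverable damage, and each lesioned patch contributes
`init_mye` units of unrecoverable damage, giving a lattice ceiling of
`grid_size²·init_mye` = 260100 units. This convention is chosen because the
cohort medians this model family reports are in the tens of thousands,
consistent with a myelin-unit scale rather than a patch-count scale (max
2601).

One step is 2.4 h of simulated time (3650 steps/year; 18250 steps = 5
years — fine enough to resolve single relapses, coarse enough to simulate
years cheaply). The per-step schedule is fixed:

1. **Pulses.** One Bernoulli trial per species (Teff, Treg, virus, in that
   order) with probability `pulse_prob` = 100/365; each success drops
   `agents_per_pulse` agents on uniformly random patches. T cells arrive
   resting; every agent's life counter is drawn uniformly from
   1..2·`hlife`.
2. **Agent turns**, in a freshly shuffled order (emulating randomised
   `ask`-style scheduling while keeping random-stream consumption
   reproducible). A resting T cell scans for the nearest virus within
   `virus_radius` (ties uniform), consumes it and activates. An active Teff
   attacks its patch's myelin and, if the patch had myelin, attempts
   duplication with the saturating law
   `p_e = eff_dup · (myelin/init_mye)² · mean_Tregs/(Treg_here + mean_Tregs)`
   evaluated on the post-attack myelin (the probability is computed for the
   duplication event, i.e. after the attack that licenses it) and on the
   count of *active* Tregs within `treg_radius` — resting Tregs do not
   secrete the inhibitory signals. An active Treg removes the nearest active
   Teff within `treg_radius` (ties uniform), moves onto its patch, and on
   success attempts duplication with constant probability `p_t`. Each agent
   ends its own turn with one random Von Neumann move.
3. **Recovery** of all damaged non-lesioned patches.
4. **Death**: every life counter decrements; agents at zero are removed.

Duplication itself is Bernoulli-first: the coin is tossed, then the density
gate requires fewer than `patch_density` = 3 agents (all species) on the
parent's patch. If the gate fails the parent relocates to a random neighbour
and exactly one retry is made with a freshly recomputed probability — a
bounded rendering of the model's "move and recompute" loop, which as stated
has no termination guarantee. The newborn is active, placed on a random
neighbour (exempt from the gate at placement), and gets a fresh life draw;
the parent's life is halved (floored, minimum 1, since a surviving agent
cannot have life 0).

## Randomness and reproducibility

All stochastic decisions — pulse trials, placements, life draws, turn
shuffling, movement, tie-breaks, duplication coins — consume a single random
stream seeded once per run. A seed therefore *is* a virtual patient:
replaying a seed reproduces every observable bit-for-bit, and a cohort is
just a set of consecutive seeds. The stepping engine is implemented in C++
for speed (a 5-year patient takes well under a second) but draws from R's
generator, so `set.seed()` governs everything and the granular rule
functions and the full-run driver share one stream.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `grid_size` | 51 | lattice side (patches) |
| `dt_hours` | 2.4 | hours per step |
| `init_mye` | 100 | initial myelin per patch (units) |
| `eat_mye` | 5 | myelin destroyed per attack |
| `rec_mye` | 1 | regrowth per damaged patch per step |
| `eff_dup` | 0.1 | max Teff duplication probability |
| `p_t` | 0.1 / 0.025 | max Treg duplication probability (healthy / hill) |
| `treg_radius` | 3 | Treg visibility radius (patches) |
| `virus_radius` | 3 | virus contact radius |
| `mean_Tregs` | 10 | half-saturation of Treg inhibition (cells) |
| `patch_density` | 3 | max agents per patch for duplication |
| `hlife` | 60 | mean half-life (steps) |
| `pulse_prob` | 100/365 | per-trial pulse probability |
| `pulse_mode` | per_step | when the pulse trials run |
| `agents_per_pulse` | 1 | agents per successful pulse |

Four constants are calibration choices, not published values, and are
exposed in the configuration: `rec_mye` (1 unit/step — slow remyelination,
an order of magnitude below the attack rate), `virus_radius` (3, mirroring
`treg_radius` — both describe short-range cell contact), `mean_Tregs` (10 —
a local active-Treg crowd of about a third of the radius-3 disc's density
cap halves Teff proliferation) and `agents_per_pulse` (1 — the minimal
pulse amplitude). They were fixed once, before any cohort experiment, and
not revisited.

### The pulse-mode choice

The introduction rule admits two readings: per-step Bernoulli trials with
p = 100/365, or a nominal calibration of 100 impulses per species per year —
mutually inconsistent at 10 steps per day, since per-step trials yield about
1000 successes per species per year. Both readings are implemented. `per_step` is the default because it is the literal
transition rule and because it is the regime in which the model's defining
behaviour appears: under per-step pulses the standing virus and T-cell
populations are large enough for Tregs to establish control in healthy
patients, and the two arms separate cleanly (median final damage ~144000 vs
~84000 at 20 seeds/arm). Under `per_day` pulses (the reading that calibrates
to the nominal 100/year), agent densities are so sparse that Treg control
never establishes and the two arms become indistinguishable — the
cross-regulation phenotype vanishes. `per_day` remains selectable and is the
mode in which the 100-impulses-per-year calibration property is tested.

## What the simulations show — and don't

At the default calibration the hill arm reproduces the qualitative disease
course: early activation flares, stepwise accrual of permanent lesions
(relapses), relapse counts concentrated in the first half of the 5-year
horizon, and a final-damage distribution far above the healthy arm's
(two-sample KS D = 1.0 at 20 seeds per arm). The healthy arm reproduces
control of Teff flares — activated Tregs suppress outbreaks and recoverable
damage heals — but *not* full end-of-course recovery: after the agent-free
cold start (the model begins with an empty lattice, so the first outbreak
faces no Tregs) and under the slow default regrowth rate, healthy patients
retain a permanent-damage floor in the ~10⁴-unit range rather than ending
near zero as the balanced scenario is meant to. Sensitivity runs indicate
this floor is governed by the exposed calibration constants — chiefly
`rec_mye` relative to `eat_mye`, and `virus_radius` via the standing
active-Treg density — not by the transition rules; the defaults were
nevertheless kept as fixed study conditions rather than fitted to the
behaviour they were expected to produce. Conclusions about *relative* arm behaviour (separation,
relapse timing, monotone lesion growth) are robust across seeds; absolute
damage magnitudes should be read as calibration-dependent.

The synthetic cohorts emulate between-patient variability purely as
stochastic realisation differences under identical parameters. Real cohorts
add parameter heterogeneity (genetics, exposure), ongoing treatment, and
spatially structured anatomy, none of which the model represents — passing
cohort tests shows internal consistency of the mechanism, not clinical
calibration.

## Numerical and degenerate-input choices

Probabilities are validated into [0, 1]; `eat_mye ≤ init_mye`; a lattice
smaller than 3×3 is rejected (the Von Neumann neighbourhood would
degenerate). Myelin is clamped to [0, `init_mye`] at every update, and the
lesion state (`myelin = 0`) is absorbing by construction, so unrecoverable
damage is monotone non-decreasing — both properties are asserted as tests
across seeds. Tie-breaks (equidistant suppression or activation targets) are
uniform random; the empty world steps to an empty world; `steps = 0` yields
a single-record time series. The KS statistic is computed as the exact
ECDF supremum over pooled sample points (robust to the heavily tied
zero-damage values a well-controlled arm produces) and is checked against a
brute-force oracle on all small samples; its p-value uses the standard
asymptotic null distribution.

Problem sizes used by the test suite and the reproduction script — 20
patients per arm at the full 18250 steps, smaller lattices (11–21 patches)
for rule-level checks, 10⁴–10⁵ draws for distributional checks — were chosen
so the full suite runs in a few minutes on a single core while keeping
binomial standard errors well inside the asserted tolerances.

## A short tour

```{r, eval = FALSE}
library(rrmsim)

# one hill patient, 5 years
run <- run_simulation(scenario_params("hill"), seed = 42, steps = 18250)
autoplot(run)                       # populations + damage vs time
autoplot(snapshot(run$world))       # spatial lesion map
detect_relapses(run)                # episodes of new permanent damage

# the two-arm cohort experiment
hill    <- run_cohort(scenario = "hill",    n = 20, base_seed = 1)
healthy <- run_cohort(scenario = "healthy", n = 20, base_seed = 1)
cmp <- compare_cohorts(hill, healthy)
glance(cmp)
autoplot(cmp)                       # ECDFs of final damage, both arms
```
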