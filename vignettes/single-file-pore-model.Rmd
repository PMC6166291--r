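---
title: "Occupancy states and kinetics of single-file water pores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Occupancy states and kinetics of single-file water pores}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
library(porestates)
```

## The problem

A single-file water pore — an aquaporin, a narrow carbon nanotube — admits
one molecule per cross-section, so molecules move strictly sequentially.
Two permeabilities characterise such a pore: the osmotic permeability
$P_f$, the coefficient of net water flow down a water-activity gradient,
and the diffusion permeability $P_d$, the coefficient of isotopic tracer
exchange at equilibrium. Their ratio is experimentally accessible and, for
single-file pores, informative about the number $N_p$ of water molecules in
the pore. This package implements a combinatorial model of pore occupancy
states under which $P_f/P_d = N_p$ exactly, evaluates the competing
expressions found in the channel literature, and provides a stochastic
kinetic model of the underlying mechanisms with an exact master-equation
oracle.

## The combinatorial model

**Assumptions.** (1) The pore has $i \ge 1$ slots, each one water-molecule
diameter $d_w$ wide, so the pore length is $i\,d_w$ and $i = N_p$ when the
pore is full. (2) A slot holds one of three objects: an indistinguishable
water molecule, the single tracer (physically identical to water but
countable), or a vacancy. (3) At most one tracer and at most one vacancy
are in the pore at any time.

Slot 1 is the entrance (left), slot $i$ the exit (right); configurations
are written entrance→exit with the glyphs `O`, `*O*`, `[]`. "Exit state"
always refers to the right end; tracers moving the other way are handled by
mirror symmetry in the kinetic model rather than by a mirrored class.

Enumerating the four mutually exclusive cases (no tracer or vacancy; tracer
only, $i$ placements; vacancy only, $i$ placements; tracer and vacancy,
$i(i-1)$ ordered placements, water filling the rest in one way) gives
$(N_S)_i = i^2 + i + 1$ states. `enumerate_configurations()` constructs
exactly these, in a fixed lexicographic order (water < tracer < vacancy) so
that output files are reproducible; the test suite checks the enumeration
against an independent generate-and-filter oracle over all $3^i$ slot
assignments.

`census()` never uses the closed forms: it classifies every enumerated
configuration and tallies the classes, and `closed_form_census()` provides
the algebraic counterpart ($n_d = i^2$, $n_{dex} = i$, $n_f = i$,
$n_{fex} = 1$); the suite requires the two to agree field by field for
$i = 1..12$.

```{r}
census(3)
```

## Ratio models

Following the reciprocal-state-count construction, each permeability is
inversely proportional to the number of states its flow must sample, so

$$\frac{P_f}{P_d} = \frac{1/(N_S)_f}{1/(N_S)_d} = \frac{i^2}{i} = i,
\qquad
\frac{P_f}{P_d} = \frac{1/(N_S)_{fex}}{1/(N_S)_{dex}} = \frac{i}{1} = i,$$

and both routes are computed in `pfpd_ratio()` from the census counts, not
from hard-coded formulas, so a counting bug breaks the ratio. The
tracer-exit-state route has a notable corollary: $(N_S)_{fex} = 1$ for
every $i$, so under this model $P_f$ itself is length-independent and the
entire length dependence of the ratio sits in $(N_S)_{dex} = i$.

The competing expressions are exposed as models `NP_MINUS_1` ($i-1$),
`NP_PLUS_1` ($i+1$; this is the full-pore count of $i$ tracer states plus
one null state, a count that mixes a non-tracer state into a tracer
census — we expose it as a ratio model but deliberately not as a census
field), `NP2P1_OVER_NPP1` ($(i^2+1)/(i+1)$) and `MEAN_OCC_PLUS_1`
($\langle n\rangle + 1$ with the single-vacancy mean occupancy
$\langle n\rangle = i-1$ derived from the enumeration). For display the
package rounds half-up to two decimals and trims trailing zeros (`1.67`,
`2.5`, `6.25`); full precision is kept internally and in machine-readable
outputs. One display convention is worth noting: $(10^2+1)/11 = 9.1818...$
prints as `9.18` under this rule, while coarser one-decimal rounding would
print `9.2`; we keep the uniform two-decimal rule.

At $i=1$ the expressions separate sharply: the state-count model gives 1,
$i-1$ gives 0 and $i+1$ gives 2; for large $i$ they converge (the gap
$i - (i^2+1)/(i+1) = (i-1)/(i+1)$ rises from 0 toward 1), which is why long
biological pores cannot discriminate the models experimentally.

## Kinetic model

The kinetic layer makes the two verbal mechanisms concrete as a
continuous-time Markov chain over the enumerated configurations
(tracer-bearing states additionally tagged by the tracer's reservoir of
origin, which is what defines a translocation).

* **Knock-on collision**, rate $k_{coll} \cdot a$ per side: on a full pore,
  a collision at the entrance ejects the exit-slot molecule — the striker
  does not enter, so the vacancy appears at the far end; with a vacancy at
  slot $v \ge 2$, the same collision advances the single molecule adjacent
  to the vacancy on its entrance side (the vacancy steps toward the
  entrance). One molecule moves per event; the package represents concerted
  multi-molecule shifts only as sequences of such single steps, since no
  rate is available for a compound move.
* **Brownian hop**, rate $k_{hop}$ per direction: a molecule adjacent to
  the vacancy hops into it.
* **Brownian escape**, rate $k_{exit}$, enabled only on a full pore — the
  minimal rule that preserves the single-vacancy constraint dynamically.
* **Entry**, rate $k_{enter} \cdot a$, fills a vacant end slot from the
  adjacent reservoir; the entrant is the tracer with probability equal to
  that side's tracer fraction, provided no tracer is already inside.

Collision and entry rates scale linearly with the adjacent reservoir's
water activity, so an osmotic gradient is simply $a_L > a_R$; whether a
gradient should scale entry as well as collision is not settled by the
mechanism description, and we scale both (linearly), which keeps boundary
conditions thermodynamically consistent at equilibrium.

**Defaults.** No canonical rate constants exist for this abstracted model,
so the package fixes order-one defaults once: $k_{coll} = k_{hop} =
k_{enter} = 1$, $k_{exit} = 0.1$, $a_R = 1$, tracer fraction 0.1 on the
left and 0 on the right. The single structural requirement is
$k_{exit} < k_{hop}$ — escaping the full pore into solution crosses a
higher barrier than moving into an in-pore vacancy — and the constructor
enforces it. Time is dimensionless; the rates set the scale. Tracers enter
from the left only by default (the classic tracer experiment); a tracer
that returns to the left reservoir rejoins its pool, identity untracked. A
right-side tracer fraction exists solely so mirror-symmetry can be tested.

**Estimators.** From an equilibrium run,
$P_d = (\text{tracer translocations L→R}/t)\,/\,f_L$; from a gradient run,
$P_f = (\text{net water crossings}/t)\,/\,(a_L - a_R)$, with water
crossings tallied at the exit-side boundary (at stationarity the net rate
is the same at either boundary). Both are molecules per unit time, so the
ratio is dimensionless and directly comparable to $N_p$. Standard errors
come from non-overlapping batch means (20 batches by default, more when a
test needs better normality); a run with fewer than 100 tracer
translocations carries a `low_precision` flag rather than raising an
error. Vacancy lifetimes are measured from vacancy creation (ejection or
escape) to restoration of the full pore, counting only lifetimes that lie
entirely inside the observation window.

**Oracle.** `build_generator()` assembles the exact generator matrix from
the same transition rules (it refuses $i > 6$; the exact solve is meant
for small instances) and `solve_stationary()` solves $\pi Q = 0$,
$\sum\pi = 1$ by a least-squares linear solve after verifying strong
connectivity (a reducible chain — e.g. $k_{enter} = 0$, which makes the
full pore unrecoverable — is reported with the offending states). The
stationary distribution yields exact net water flux, tracer translocation
rates and full-pore occupancy, which the test suite requires the Gillespie
estimates to match within three batch-means standard errors.

## What the simulations show — and do not show

At the default rates the exact equilibrium tracer translocation rate
decreases strictly with pore length (the vacancy forces the tracer to
sample more states, slowing $P_d$), vacancy lifetimes under an osmotic
gradient ($a_L/a_R = 2$) are shorter than at equilibrium (repeated
entrance collisions sweep the vacancy to the entrance, where it refills),
and the simulated $P_f/P_d$ grows with $i$. The simulated ratio does not
equal $N_p$ at arbitrary rates — at the defaults it overshoots — and the
package asserts no such equality: the identity $P_f/P_d = N_p$ is a
statement about state counts, and the mapping from the counting argument
to a specific kinetic regime is left as a question the oracle can explore
(`ratio_scan()` tables simulated ratios against the prediction).

## Numerical choices and problem sizes

Gillespie sampling uses exponential waiting times and rate-proportional
event choice over a pre-resolved transition table, seeded explicitly;
identical parameters and seed give byte-identical outputs. Entry events are
split into water and tracer branches with fraction-weighted rates, so the
chain is simulated exactly. The test suite uses horizons of a few thousand
time units (tens of thousands of events) for oracle comparisons, and
24 000 time units for the ratio-versus-length scan, chosen so the
batch-means standard errors are small against the effects being tested; the
oracle comparisons run at $i \in \{2, 3\}$ over three fixed seeds. The
acceptance script's quantities are purely combinatorial and run in well
under a second.

## Limitations

The model abstracts away everything molecular: no water geometry, hydrogen
bonding, pore-wall energetics, charged species, or pressure-driven flow
distinct from activity scaling; single-vacancy occupancy is an assumption,
not a derivation, so pores that admit multiple vacancies (very long or
loosely packed channels) fall outside it. The synthetic trajectories are
realisations of exactly this abstract chain — agreement between simulator
and oracle validates the implementation, not the biological fidelity of
the mechanism. Limiting cases with no pore to count (a bare membrane,
where $P_f/P_d = 1$, or a wide hole) are documented constants, not model
outputs. No fitting to experimental aquaporin data is provided, and the
exponential length dependence reported for some nanochannels is outside
the model's scope.
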