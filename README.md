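# porestates

Water crosses aquaporin-like channels in single file: the pore is so narrow
that molecules cannot pass each other. For such pores the osmotic
permeability P<sub>f</sub> (net flow down a water-activity gradient) exceeds
the diffusion permeability P<sub>d</sub> (tracer exchange at equilibrium),
and the ratio P<sub>f</sub>/P<sub>d</sub> carries structural information
about the channel. `porestates` implements a combinatorial occupancy-state
model of this ratio and a stochastic kinetic simulator of the mechanisms
behind it, for anyone studying water (or tracer) transport through
single-file channels: membrane biophysicists, channel modellers, and anyone
teaching exclusion-process kinetics.

## The model

A pore of `i` slots (each one water-molecule diameter wide) holds
indistinguishable water molecules `O`, at most one tracer `*O*` and at most
one vacancy `[]`. Counting the four mutually exclusive cases — empty of
both, tracer only, vacancy only, tracer plus vacancy — gives

    (N_S)_i = i(i−1) + i + i + 1 = i² + i + 1

distinct occupancy states (13 for `i = 3`). Four classes of these states
drive the permeability analysis:

| class | meaning | count |
| --- | --- | --- |
| (N_S)_d  | diffusion tracer states: tracer anywhere            | i²  |
| (N_S)_dex | tracer in the exit slot                             | i   |
| (N_S)_f  | osmotic tracer states: tracer present, pore full     | i   |
| (N_S)_fex | full pore with tracer in the exit slot              | 1   |

Writing each permeability as the reciprocal of the number of states its flow
must sample gives the central identity, by either route:

    Pf/Pd = (1/(N_S)_f)   / (1/(N_S)_d)   = (1/i)/(1/i²) = i = N_p
    Pf/Pd = (1/(N_S)_fex) / (1/(N_S)_dex) = (1/1)/(1/i)  = i = N_p

where `N_p` is the number of water molecules filling the pore. The package
also evaluates the competing literature expressions `i − 1`, `i + 1`,
`(i² + 1)/(i + 1)` and `⟨n⟩ + 1` for comparison.

The kinetic layer turns the verbal mechanisms into an exact continuous-time
Markov model: knock-on collisions (a solution molecule strikes the entrance
molecule of a full pore and the exit molecule is ejected; with a vacancy
present the collision advances the column by one slot), Brownian hops into
an adjacent vacancy, Brownian escape from a full pore, and entry from
solution into a vacant end slot, all with collision/entry rates scaling
linearly in reservoir water activity. A Gillespie simulator estimates
P<sub>d</sub> (unidirectional tracer flux over tracer fraction) and
P<sub>f</sub> (net water flux per unit activity difference); a
master-equation stationary solver provides exact fluxes for small pores as
an oracle.

## Worked example

```r
library(porestates)

census(3)
#> Pore state census (i = 3 slots)
#>   total states:           13
#>   null / tracer-only / vacancy-only / tracer+vacancy:  1 / 3 / 3 / 6
#>   diffusion tracer states (n_d):       9
#>   diffusion tracer exit states (n_dex): 3
#>   osmotic tracer states (n_f):         3
#>   osmotic tracer exit states (n_fex):  1

pfpd_ratio(3, "TRACER_EXIT_STATES")
#> Pf/Pd prediction [TRACER_EXIT_STATES] at i = 3: 3

format_model_table(model_table(c(1, 2, 3, 4, 7, 10)))
#>    i state_count_model np_minus_1 np2p1_over_npp1 np_plus_1
#> 1  1                 1          0               1         2
#> 2  2                 2          1            1.67         3
#> 3  3                 3          2             2.5         4
#> 4  4                 4          3             3.4         5
#> 5  7                 7          6            6.25         8
#> 6 10                10          9            9.18        11
```

The 13 states of the 3-slot pore split into 9 diffusion tracer states and 3
osmotic (full-pore) tracer states, so both counting routes give
Pf/Pd = 3 = N_p. The comparison table shows how the competing expressions
disagree most at short pores (`i − 1` is 0 at `i = 1`) and converge for the
long pores of real aquaporins.

A simulated ratio at default rates (equilibrium run for P_d, activity
gradient run for P_f):

```r
simulate_pfpd(3, seed = 7, t_max = 20000)
#> Permeability estimates
#>   p_d:   0.03105 (se 0.004)
#>   p_f:   0.2539 (se 0.00728)
#>   ratio: 8.176 (se 1.08)
#>   note: fewer than 100 tracer translocations; low precision
```

The simulated ratio is regime-dependent — it exceeds the combinatorial
prediction at these default rates and is reported, not asserted, to equal
`N_p`; it does grow with pore length, as the state-count argument requires.

## Command line

```sh
porestates census --i 1 --max-i 10 --out census.csv
porestates table2 --i-list 1,2,3,4,7,10 --out table2.md --format markdown
porestates simulate --i 3 --a-l 1.5 --seed 42 --oracle --out run.csv
porestates ratio-scan --i-list 2,3,4,5 --reps 3 --seed 1 --out scan.csv
```

Every output file gets a `.meta.json` sidecar with the resolved
configuration and package version; a YAML `--config` file may supply any
flag, with flags taking precedence.

## Scope

The package models neutral water/tracer transport only: no ions, no
molecular-dynamics forces or pore-wall energetics, no pressure-driven term
distinct from activity scaling, and no fitting to experimental aquaporin
data. See the methods vignette (`vignettes/single-file-pore-model.Rmd`) for
the model assumptions, parameter rationale and limitations.
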