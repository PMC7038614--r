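---
title: "In silico evolution of organic-acid production: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{In silico evolution of organic-acid production: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acidevolve)
```

`acidevolve` predicts flux-bound interventions that redirect a fungal
organic-acid fermentation towards a chosen product. It couples a
constraint-based metabolic model to a two-phase dynamic batch model, scores
candidate strains with a closed-form productivity estimate, and searches the
space of continuous flux-bound changes with a genetic algorithm. This
vignette documents the underlying models, the numerical choices, and the
limits of what the package's own tests demonstrate.

## The two-phase batch fermentation model

Citric-acid fermentations at low pH run in two physiological phases. While
external phosphate is available the organism grows and stores phosphate as
polyphosphate (*phosphate storage*, phase 1). Once external phosphate is
depleted — at time $t_c$ — growth becomes limited by the slow release of the
stored phosphate, and metabolism shifts to exporting protons, which at pH 2
means exporting partially dissociated organic acids (*proton production*,
phase 2). The fermentation ends when the substrate is exhausted at time
$t_f$.

The dynamic simulator (`simulate_batch()`) is a standard dFBA scheme:
explicit Euler stepping with default $\Delta t = 0.01$ h, where each step
solves the phase FBA and updates biomass $A$, substrate $S$, external
phosphate $P$, acids and protons by $\text{rate} \times A \times \Delta t$.
Uptake bounds are capped by pool availability within the step, so finite
pools can never go negative. The phase switch and the substrate-depletion
endpoint are located by linear interpolation inside the step in which the
pool crosses zero; for a first-order scheme with piecewise-constant rates
this interpolation is exact, and halving $\Delta t$ moves $t_c$ and $t_f$ by
well under 0.5% (this is tested).

Phase 1 maximises growth subject to a fixed specific polyphosphate-storage
flux and a capped external-phosphate uptake. Phase 2 closes external
phosphate and solves a lexicographic program: growth is maximised first,
limited by a *cap* on the specific release of stored phosphate, then proton
export is maximised at that growth rate, and finally the flux vector is made
unique by parsimonious minimisation of total absolute flux. Two points in
this design were genuinely open:

* **Release cap rather than a forced release flux.** Modelling the
  stored-phosphate release as a hard equality would pin the phase-2 growth
  rate for every genome. Mutations that constrain biomass synthesis would
  then make the program infeasible instead of slowing growth, and
  complementation could never report a growth change. With a cap plus
  growth-first lexicographic objective, the wild type grows at the
  release-permitted rate while constrained mutants settle below it — exactly
  the growth/productivity trade-off the evolutionary experiments exploit.
  The mechanistic kinetics of polyphosphate mobilisation are *not*
  reproduced; the cap is a single specific flux parameter.
* **pH is held at its initial value (2) for all flux calculations.** The
  trajectory additionally reports the pH implied by cumulative proton
  export, but that value does not feed back into the FBA. No feedback rule
  is part of the parameterisation, and at these proton yields the
  dissociation fractions would change only marginally over a batch.

## The fitness function

Evaluating a full dynamic simulation for every individual would be orders of
magnitude too slow for evolution, so fitness is a closed form over a single
phase-2 FBA snapshot. With wild-type bounds in phase 1 (mutations are
modelled as induced at $t_c$), the phase-1 outcome is the same for every
individual, and three constants follow from one wild-type dFBA run: $t_c$,
and the biomass and substrate at the switch, $A_c$ and $S_c$
(`extract_constants()`).

From the mutant's phase-2 FBA we read the growth rate $\mu_2$, the substrate
uptake $f_2$, the target-acid output $p_2$ and the proton output $h$. Yields
at substrate depletion follow from flux ratios,

$$c(t_f) = \frac{p_2\, S_c}{f_2}, \qquad h(t_f) = \frac{h\, S_c}{f_2},$$

and the depletion time from integrating exponential phase-2 growth,

$$t_f = t_c + \frac{1}{\mu_2}\ln\!\Big(1 + \frac{S_c\,\mu_2}{f_2\,A_c}\Big),$$

with the continuous limit $t_f = t_c + S_c/(f_2 A_c)$ when $\mu_2 = 0$
(numerically: $\mu_2 < 10^{-10}$, and the logarithm's argument is clamped at
1). The simple fitness is the volumetric productivity $F = c(t_f)/t_f$. For
target acids the wild type does not produce this evaluates to zero for every
early individual and evolution cannot start; the adapted fitness

$$F = \frac{h(t_f) + w\, c(t_f)}{t_f}, \qquad w = 10,$$

keeps proton production as a baseline gradient while weighting the target
acid ten-fold (on the same mmol/L yield units as the proton term). The test
suite verifies the closed forms against numerical integration of
$S' = -f_2 A$, $A' = \mu_2 A$ to 0.1%, and the complete estimator against a
full dynamic simulation of the wild type to 5%.

## The flux-balance core

FBA problems here are small (tens of reactions for the toy network), but the
genetic algorithm solves on the order of $10^5$ of them per run, so the
package carries its own dense bounded-variable revised simplex
(`src/simplex.cpp`): two-phase with explicit artificial variables, an
explicitly maintained basis inverse with product-form updates and periodic
refactorisation, Dantzig pricing with a Bland fallback after degenerate
stalls, and feasibility/optimality tolerances of $10^{-9}$. Degenerate
optima are resolved by a parsimonious secondary criterion — total absolute
flux is minimised at the fixed objective value — because the
mutation-recording rule compares fluxes against bounds for equality and
therefore needs a unique, reproducible flux vector. In the tests the solver
is fuzzed against an independent brute-force vertex-enumeration oracle.

Infeasibility is an expected outcome, not an error: flux-forcing mutations
can empty the polytope, and such individuals simply score fitness 0.

## The genetic algorithm

Each reaction contributes two genes: its lower bound (chromosome 1) and its
upper bound (chromosome 2). The wild-type genome is the original bounds, and
no mutation may leave the original range, so irreversible reactions can
never become reversible. Biomass, maintenance-ATP, transport, exchange and
acid-dissociation reactions are protected from mutation; evolution acts on
internal metabolism only.

Per generation, with population $N = 500$:

| step | rule | default |
|---|---|---|
| elimination | $\lceil 0.05N \rceil$ drawn uniformly from the fitness-ranked bottom half | 25 |
| selection | $2\times$ the eliminated count: uniform across the population / fresh wild types / uniform from the bottom half | 5 / 10 / 35 |
| recombination | per-gene inheritance from the non-dominant parent | rate 0.04 |
| mutation | per-gene Laplace step, visited in random order | rate 0.02 |

Selected parents are shuffled and paired consecutively (no pairing rule is
otherwise implied by the design); eliminated or already-selected individuals
are never drawn. The fresh wild-type parents matter: without them wild-type
genes are eventually lost from the pool and deleterious mutations can no
longer be complemented away by recombination.

A mutation adds a Laplace(0, $b$) draw to the current bound; an unmutated
gene starts from the wild-type *flux* of its reaction rather than from the
(typically huge) default bound, which is what makes single mutations act as
realistic knock-downs. The scale $b$ is 0.1 times the wild-type flux, or 0.1
times the maximum attainable flux when the wild-type flux is zero, or a
fixed 0.01 when both are zero — in which case the draw's sign is forced
away from zero crossing (negative on chromosome 1, positive on chromosome
2) so it cannot force flux. Mutations whose resulting bound forces flux
($lb > 0$ or $ub < 0$) pass a secondary 30% acceptance gate, and accepted
ones are capped at 1% of the reaction's maximum flux computed under the
individual's current other bounds (a wild-type-bound cache is available as a
speed option, `max_flux_cache = "wildtype"`). When mutation or recombination
would cross the chromosomes ($lb > ub$), the moving bound is clipped to the
other one, i.e. the mutation becomes a full constraint at that value.

Only new individuals are evaluated, existing ones are immutable, and the top
half is safe from elimination, so the best population fitness is
non-decreasing — an invariant the tests assert on every run. Offspring that
are bit-identical clones of a parent reuse the parent's cached fitness.
Individuals are recorded when they first produce a target acid the wild
type lacks, or (for the wild-type acid) when they beat the running maximum
or 110% of the wild-type fitness; recorded genome diffs keep only
*phenotypic* mutations, those whose reaction flux sits on the mutated bound
(tolerance $10^{-6}$).

## Solution analysis

Recorded individuals within 95% (strict) of the best recorded fitness are
solution candidates; identical mutation sets collapse to one candidate.
Pruning then complements mutations one at a time — restoring the wild-type
bound while keeping the rest — in ascending reaction-index order, discarding
any mutation whose complementation costs at most 5% of the current solution
fitness, with the pruned solution as the new baseline after each discard.
The pass repeats until a fixed point, which makes pruning idempotent. Each
retained mutation gets a complementation record: % fitness decrease, %
target-acid flux decrease, and % growth increase relative to the intact
solution (an infeasible complemented genome counts as fitness 0).

Mutation frequencies count the solutions containing a reaction (once per
solution, so a lower- and upper-bound mutation of the same reaction do not
double-count) divided by the number of solutions; the plot export applies a
0.2 frequency cut-off while the raw table keeps everything. The
*representative* solution is chosen from the near-maximal set (> 95% of the
best) as the one maximising the summed frequency of its mutations — ties
broken by fewer mutations, then higher fitness. "Best represents the
average" admits many formalisations; frequency-weighted overlap is the one
used here, stated so results are reproducible.

## The toy network

`build_toy_model()` generates a deterministic ~38-reaction core-carbon
network so that every stage of the pipeline is testable without a
genome-scale model: glucose uptake, lumped glycolysis, the pyruvate node
(lactate dehydrogenase, a decarboxylase route to acetate, pyruvate
carboxylase), TCA cycle with glyoxylate shunt and an NADH-dependent fumarate
reductase, a lumped electron-transport chain (NADH and ubiquinol oxidation
against oxygen with P/O ratios of 2 and 1), maintenance ATP hydrolysis, a
biomass reaction drawing on a dedicated precursor-synthesis step plus
phosphate, and per-acid dissociation/export reactions releasing
$\sum_i 1/(1+10^{pK_{a,i}-pH})$ protons per molecule at pH 2 (real
p$K_a$ values). Every internal reaction is balanced for carbon, which the
tests audit.

The defaults are chosen once so the toy reproduces the phenomenology of a
citric-acid fungus, and they are part of the study conditions rather than
tuning knobs: batch conditions $A_0 = 0.05$ g/L, $S_0 = 100$ mmol/L,
$P_0 = 0.09$ mmol/L; maintenance 0.4 mmol gDW⁻¹ h⁻¹; phase-1 glucose cap
0.5 and phosphate cap 0.02 with storage flux 0.015; phase-2 glucose cap 0.5
and release cap 0.0025 (growth cap 0.05 h⁻¹ at 0.05 mmol P per gDW).
Under these conditions the wild type secretes citrate and nothing else (the
proton-richest acid per glucose), the phase-1 growth rate is ATP-limited at
$\mu_1 \approx 0.089$ h⁻¹, and the productivity optimum lies below the
phase-2 growth cap, so evolution towards citrate finds growth-constraining
mutations — while switching to lactate requires jointly knocking down NADH
oxidase and fumarate reductase, giving the analysis pipeline a genuine
essential "NADH-recycling block" to find.

What the toy does *not* emulate: compartments and transporter energetics,
redox cofactor diversity (one NAD pool, no NADPH), biomass composition
detail, oxygen transfer limits, and pH feedback. Passing tests on the toy
therefore demonstrate the correctness of the algorithms and the
plausibility of the evolutionary dynamics — not quantitative predictions
for any real organism; those require a curated genome-scale model supplied
as SBML.

## Problem sizes used by the tests

The shipped test-and-demonstration workloads are deliberately desk-scale:
operator statistics use $10^4$ samples; the end-to-end evolution property
runs 5 seeds × 2,000 generations at population 500 on the toy network
(roughly a minute per run), which is sufficient for a complete acid switch
on the toy; analysis examples run from a 600-generation log. Genome-scale
work at the published scale (tens of thousands of generations on ~1,800
reactions) uses exactly the same code paths but is a compute-cluster
exercise, not part of the test suite.

## Known limitations

* The simplex is dense; models beyond a few thousand reactions would want a
  sparse LP backend behind `solve_fba()`.
* The phase-1 parameterisation assumes constant specific rates, which is
  what makes $t_c, A_c, S_c$ closed-form; substrate-dependent uptake
  kinetics would require replacing the constants by per-individual phase-1
  simulations.
* Gene-protein-reaction strings are carried and counted but not evaluated
  as Boolean constraints; evolution acts on reaction bounds, not genes.
* `read_sbml()` supports the fbc-v2 and legacy COBRA dialects; exotic SBML
  (groups, comp) is ignored rather than rejected.
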