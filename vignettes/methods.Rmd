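---
title: "Quantifying karyotype megaevolution: models and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying karyotype megaevolution: models and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyorate)
```

## The analysis in one paragraph

Cross-species chromosome painting (zoo-FISH) maps each chromosome of a
study species as an ordered string of syntenic blocks named after the
outgroup chromosomes they derive from.  `karyorate` turns such homology
maps into quantitative statements about karyotype evolution in four
steps: (1) adjacencies of blocks ("syntenic associations", e.g.
`"17+18"`) become binary characters and are polarized on a phylogeny by
Fitch parsimony against an outgroup, yielding ancestral association
sets, synapomorphies and homoplasy flags; (2) fusion and fission events
between an ancestral and a derived karyotype are counted from a maximal-
run fragment decomposition of the homology map; (3) event counts divided
by dated internode times give per-branch fixation rates, with bounds
obtained by re-evaluating the quotient at one standard error of the
divergence time; (4) converting a branch rate to fixations per
generation and inverting the diffusion rate equation for underdominant
rearrangements yields the long-term effective population size that would
be required to fix that many rearrangements.  A forward Wright--Fisher
simulator provides a stochastic cross-check of the diffusion formula,
and a synthetic karyotype-evolution generator provides histories with
known event logs for validating the counting machinery.

## Data model

A `karyotype` holds one representative chromosome per homologous pair.
Each `chromosome_model` is an ordered vector of block labels
(`"16"`, `"2q"`, `"16a"`: outgroup chromosome, optional ancestral arm,
optional fission-segment tag), an optional centromere position and a
gross morphology (`A`, `SM`, `ST`, `M`, `B`).  Positions are 0-based;
the centromere is a junction index between blocks because painting
rarely localizes breakpoints more finely, with a "within block" fallback
flag.  Sex chromosomes are parsed and carried but excluded from
association characters and event counts: Y paints are generally not
produced and the X is conserved, so including them would mix evidence
of very different quality.

Associations are unordered, orientation-blind pairs of adjacent blocks.
Painting carries no reliable orientation signal, so a chromosome
`[12, 2q]` and its reversal encode the same association `"12+2q"`;
inversion annotations are chromosome-level notes, not characters.

## Ancestral reconstruction

Characters are unordered binary presence/absence states, gains and
losses weighted equally.  The per-character minimum change count is the
Fitch score (computed with the state-count generalization, so soft
polytomies are handled); a score above 1 flags homoplasy.  Where the
final pass leaves a node ambiguous, the state observed in the outgroup
is chosen, in preference to ACCTRAN/DELTRAN conventions: every polarity
decision in this kind of analysis is rooted in the outgroup karyotype,
and resolving ambiguity the same way keeps node assignments reproducible
and interpretable.  Because of this rule the assignment can imply more
changes than the Fitch score on characters whose most-parsimonious
reconstructions disagree near the root; the reported score is always the
minimum.  Node ages play no role in parsimony; they are consumed by the
rate step.

The package reports association sets per node and does not attempt to
assemble whole ancestral chromosomes from overlapping associations; how
conflicts between characters sharing a block should be reconciled is not
specified by the underlying method, so chromosome-level assembly is left
to the user.

## Counting fusions and fissions

`decompose()` cuts each derived chromosome into maximal runs of blocks
that are contiguous on a single ancestral chromosome, in either order
(orientation-blind, consistent with the association definition).  A
derived segment label (`"16a"`) matches the untagged ancestral block
(`"16"`) and occupies its left half, `b`/`y` the right half, so a block
split across two derived chromosomes scores as one fission and
re-adjacent `a|b` segments score as nothing.  Fusions are junctions
between fragments on derived chromosomes; fissions are the extra
fragments each ancestral chromosome was split into.  The balance
identity `n_derived = n_ancestral + fissions - fusions` holds whenever
every ancestral chromosome is represented, and the counts are minimal:
on histories without breakpoint reuse they equal the true event counts,
with reuse they are a lower bound.  Inversions and centromeric shifts
are deliberately not counted; orientation-blind adjacency undercounts
inversions by construction, which is the appropriate behaviour when they
are excluded from rates.

Fusion junctions are classified from centromere annotations:
centromere-to-centromere joins of two ancestral termini on a biarmed
derived chromosome are Robertsonian, telomere-to-telomere joins are
tandem (telomeric) fusions, and anything unresolvable - interior
breakpoint ends, missing centromere or morphology annotation, a
centromere only localized "within" a block - degrades to `unspecified`
rather than guessing.

## Rates with divergence-time error bounds

`branch_rate(n, t, se)` returns `n/t` with bounds `n/(t-se)` and
`n/(t+se)`.  When `se >= t` the lower-time bound is nonphysical
(negative or infinite); it is flagged but reported as computed, because
published tables print such values and faithful reproduction beats
silent clamping.  Display rounding is half-even to 4 decimals;
comparisons against published tables should use a +/-0.001 tolerance for
4-decimal values since such tables mix rounding and truncation (e.g.
1/12.6332 = 0.07916 printed as 0.0791).  The "Stasis"/"Evolution"
comments in `rates_table()` are narrative annotations with documented,
configurable thresholds (at most 1 change; central rate above 2
changes/myr), not analysis.

Generation length enters only through
`per_generation_rate(R, g) = R * 1e-6 * g`.  The species-specific value
used in the source analyses is not printed in them, so the package
treats generation length as a sensitivity grid of 2--10 years by
default.

## Effective population size from underdominant fixation

For a rearrangement with genotype fitnesses `1 : 1-s : 1` the diffusion
fixation probability from frequency `p0` is

$$P(N_e, s, p_0) = \frac{\int_0^{p_0} e^{4 N_e s\, x(1-x)}\,dx}
                        {\int_0^{1} e^{4 N_e s\, x(1-x)}\,dx},$$

and the per-generation fixation rate with census size equal to `Ne`
(exposed as a `census_ratio` parameter defaulting to 1, since no
`Ne/N` ratio is published for these data) and `p0 = 1/(2 Ne)` (a single
new mutant) is `R = 2 Ne u P`.  The exponent is exactly quadratic, so
the denominator reduces algebraically to a Gaussian integral,
`sqrt(pi/a) * erf(sqrt(a)/2) * exp(a/4)` with `a = 4 Ne s`; this is an
exact identity, not an approximation.  The numerator is evaluated by
adaptive quadrature (relative tolerance `1e-10`) after rescaling so the
integrand lies in `(0, 1]`, and the whole computation is carried in log
space.  This keeps `lande_rate()` well-behaved deep into the
strong-selection regime, where `P` itself underflows a double (around
`Ne * s > 700`; use `log = TRUE` there).

`solve_ne()` inverts the strictly decreasing map `Ne -> R` by bisection
on `log(Ne)` over `[2, 1e7]` (200-iteration cap, relative residual
`1e-6`).  A target at or above the rate attainable at the lower bracket
is diagnosed `supra_neutral_no_solution` - underdominance only ever
drags the fixation rate below the neutral rate `u`, so such targets
require mutation rates, not population sizes.  Targets below the rate at
the ceiling return `below_minimum`.  The quadrature route is the primary
computation because the analysis grids include small `Ne * s` cells near
the neutral bound where the Laplace closed form
`2u sqrt(Ne s/pi) e^{-Ne s} / erf(sqrt(Ne s))` fails; the closed form is
retained (`lande_rate_closed()`) as a cross-check.  Its relative error
is `(e^{2s}-1)/(2s) - 1`, approximately `s`, independent of `Ne * s`:
about 10% at `s = 0.1` and 72% at `s = 0.5`.  It is therefore a valid
oracle only for weak selection, which is how the test suite uses it.

## The Wright--Fisher oracle and its limits

`simulate_fixation()` implements the discrete model the diffusion
approximates: deterministic selection on genotype frequencies followed
by binomial resampling of `2N` allele copies, all replicates advancing
in lock-step from one seeded generator (bit-reproducible).  The test
suite validates the simulator against the exact Markov-chain absorption
probability obtained by solving the linear system of the `2N+1`-state
chain - an oracle independent of both the simulator and the quadrature.

A known limitation worth stating precisely: the diffusion formula
carries a deterministic `O(s)` bias relative to the exact discrete
chain.  At `N = 20` it overestimates fixation by about 0.7% at
`s = 0.02` but 12% at `s = 0.1`, and at `N = 50, s = 0.1` by about 32%
(of a very small probability).  Monte-Carlo comparisons at a few hundred
thousand replicates resolve this bias for the stronger-selection cells,
so simulator-vs-diffusion agreement within Monte-Carlo noise should only
be expected where `s` is small.  This is a property of the diffusion
limit itself, not of either implementation.

`deme_fixation_experiment()` is explicitly exploratory: monogamous
pairs, Poisson offspring, viability selection against heterozygotes and
a hard cap, with demography followed after allele loss so that deme
extinction is recorded.  It reproduces directions - near-certain
extinction of tiny demes at one offspring per pair, neutral fixation at
the initial frequency - and is not a reconstruction of any published
small-deme model.

## The synthetic generator

`evolve_karyotypes()` defines the regimes under which the counting
machinery is validated.  Defaults mirror the two regimes seen in real
painting data and ship as presets: `"stasis"` (0.02 events/myr per
type - branches of up to ~12 myr with at most one change) and `"burst"`
(3 fusions + 3 fissions per myr, the tempo at which tens of events
accumulate on a single short internode).  Event counts per branch are
Poisson in rate times branch duration; fusions join uniformly chosen
chromosome ends, fissions cut uniform junctions with a within-block
fallback that creates `a`/`b` segment labels.  Events are applied
sequentially in log order, so simultaneous-event ambiguity cannot
arise, and the log replays from the root to the exact simulated states
(`replay_history()`), which is the generator's defining invariant.

With `allow_breakpoint_reuse = FALSE` the generator restricts fissions
to junctions present in the root karyotype and forbids fusions from
recreating any adjacency previously seen on the lineage (including the
fresh breakpoint between `a|b` segments).  Under these conditions the
parsimony counts are provably exact per branch, which the suite checks;
with reuse allowed only the lower-bound property is guaranteed.

What the generator does not emulate: unequal rates across lineages
within one simulation, inversions (excluded from counting anyway),
whole-chromosome duplications or losses, and real paint-resolution
artifacts beyond the simple censoring model of `emulate_painting()`
(which absorbs undersized same-origin runs into their flanking segment,
never re-merging split `a|b` segments).  Passing recovery tests on
synthetic histories therefore demonstrates correctness of the counting
algebra, not robustness to every artifact of wet-lab painting data.

## Problem sizes used in validation

The test suite runs the Wright--Fisher oracle at `2e5` replicates per
grid cell, the exhaustive parsimony oracle on 500 random trees of up to
6 leaves (enumerating all internal labelings), the event-balance
identity on 1000 simulated ancestor/descendant pairs, and recovery
checks on 80 simulated histories; the full suite completes in about a
minute on one core.  These sizes give 3-sigma Monte-Carlo resolution of
roughly 1% relative on fixation probabilities near 0.02 while keeping
the suite fast enough to run on every change.

## Reproducing the headline numbers

`scripts/acceptance.R` recomputes the effective-population-size ceilings
from scratch: branch-rate triples from the published internode inputs
(39 changes over 6.2324 +/- 2.7562 myr; 14 over 4.6205 +/- 3.2150 myr),
a 2--10-year generation-length grid, mutation rates `1e-4` and `1e-3`,
and selection coefficients 0.1, 0.3, 0.5.  The solved maxima - about 59
and 68 individuals, dropping to about 20 and 23 when selection is at
least 0.3 at the highest mutation rate - are written as JSON; see the
README for the exact invocation.
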