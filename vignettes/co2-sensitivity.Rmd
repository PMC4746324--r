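---
title: "CO2 sensitivity analysis of compartmentalized metabolic networks"
author: "co2flux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CO2 sensitivity analysis of compartmentalized metabolic networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(co2flux)
```

## The modelling problem

Photoautotrophic microalgae fix CO~2~ through RubisCO and divert the fixed
carbon into biomass. How the intracellular flux distribution responds when
the gas-phase CO~2~ concentration moves between air level (0.04 %) and
strong enrichment (10 %) is a question about the whole network: carbon
concentrating machinery, photorespiratory traffic between chloroplast and
mitochondrion, and central carbon metabolism all reroute. Flux balance
analysis (FBA) addresses this at genome scale with three ingredients: a
compartmentalized stoichiometric matrix $S$ (metabolites $\times$
reactions), the steady-state assumption $Sv = 0$, and a biomass
pseudo-reaction whose flux is maximized:

$$\max\ c^\top v \quad \text{s.t.}\quad S v = 0,\ LB \le v \le UB,$$

where $c$ is all zeros except a single 1 at the biomass column. Growth
conditions enter through exchange-reaction bounds: the photon uptake is
pinned to the light regime (57.54 mE gDW^-1^ h^-1^, a cool-white source)
and the CO~2~ exchange upper bound is moved across conditions. All other
material fluxes are in mmol gDW^-1^ h^-1^; the biomass flux is h^-1^.

This package implements that analysis end to end — building and extending
the network, assigning directionality, solving the LP, classifying
CO~2~-sensitive reactions, and reconciling the predictions with qPCR and
metabolomics observations — together with seeded generators that produce
every input with known ground truth.

## Network representation and complementation

Networks are S4 objects (`MetabolicNetwork`) holding a metabolite table, a
reaction table with stoichiometries as named numeric vectors, and the
objective id. Metabolite ids carry their compartment in brackets
(`"co2[h]"`); the compartment vocabulary is open, with
`defaultCompartments()` documenting the ten-compartment convention of
fully compartmentalized algal models. Reversibility is encoded purely
through a negative lower bound: the equation arrow written on disk is
derived from the bounds, never stored independently, so the two cannot
disagree. Coefficients are numeric doubles; fraction syntax (`"3/2"`) is
accepted on input, and the steady-state residual of every reported
solution is checked against the 10^-6^ tolerance, which doubles meet
comfortably at the problem sizes involved.

Complementation extends a base reconstruction from two tables: homology
hits (protein to EC number, with e-values) and an EC-indexed reaction
catalog with generic (compartment-free) equations. The stages run in a
fixed order and each candidate carries an ordered verdict trail:

1. **associate** — every catalog reaction under the EC of an accepted hit
   (e-value at most 10^-10^ by default; the upstream search's own cutoff
   is not part of the table, so acceptance is re-checked here);
2. **dedupe** — candidates whose compartment-stripped stoichiometry equals
   a base reaction are removed, comparing both orientations when either
   side is reversible;
3. **reactant filter** — only candidates all of whose species the base
   model already contains survive; a configurable blacklist of generic
   species names ("an alcohol") fails candidates that cannot be wired into
   a network;
4. **compartmentalize** — a candidate is instantiated in *every*
   compartment hosting all of its species (id suffixed `_c`, `_h`, ...);
   candidates with no such compartment are dropped with a recorded
   verdict;
5. **gap fill** — dead-end metabolites introduced by the additions are
   connected by the shortest catalog path (breadth-first over the
   bipartite metabolite–reaction structure, depth at most 3, ties broken
   lexicographically by catalog id); when no path exists a boundary
   sink/source reaction is inserted, mirroring the insertion of exchange
   reactions that guarantee origin and consumption of new species.

Counts are non-increasing through stages 2–3 and the whole procedure is
deterministic, so identical inputs give byte-identical networks. A
pathway-label blacklist (empty by default) stands in for the manual
rejection of routes implausible for a green alga.

## Thermodynamic directionality

Directionality of added reactions comes from group-contribution Gibbs
energies at 27 °C and pH 7: a compound's formation energy is an origin
term plus group-count-weighted contributions, and the reaction energy is
the stoichiometric sum. Decompositions are input data — no structure
parsing is attempted. The classification threshold $\tau$ defaults to
30 kJ/mol, a common constraint-based-modelling heuristic: $|\Delta G_r|
\le \tau$ is reversible, strongly negative is forward irreversible, and
strongly positive reactions are flipped before being constrained forward.
An override table allows literature-based calls to replace computed ones.
No concentration or ionic-strength corrections are applied, since only
temperature and pH are fixed by the protocol the parameters describe.

## Solving the LP, and what to do about alternate optima

The solver is a dense bounded-variable two-phase primal simplex written
for this package: Dantzig pricing with smallest-index tie-breaks,
switching permanently to Bland's rule after a run of degenerate
iterations, so it cannot cycle and identical inputs give identical
vertices. Feasibility and pivot tolerances are 10^-9^; reported solutions
must satisfy $\|Sv\|_\infty \le 10^{-6}$ and the bounds within 10^-9^.
The test suite checks the solver against exhaustive enumeration of basic
feasible solutions on a hundred seeded random networks and against an
independent LP implementation.

FBA optima are rarely unique, and any statistic computed from
non-objective fluxes is meaningless without a degeneracy policy. The
package's policy is parsimony: with the biomass flux pinned at its
optimum, minimize $\sum_j |v_j|$ (splitting reversible columns into
non-negative forward and backward parts). The parsimonious vector is what
the sensitivity scan consumes. This second stage is a deliberate design
choice documented here rather than part of the original experimental
protocol, which did not discuss alternate optima; objective values are
unaffected, but per-reaction fluxes (and therefore every downstream
number that depends on them) are policy-dependent in any FBA study.

## The CO2 scan and the sensitivity coefficient

`defaultConditions()` encodes five CO~2~ levels: 0.04 % (air, the low
reference), 2.5, 5, 8 and 10 % (the high reference). The air-level figure
is used rather than a literal zero: a zero-carbon condition supports no
growth at all and the low reference of the matching growth experiments is
ambient air. The CO~2~ exchange bound attached to each level scales
linearly with the percentage (1 mmol gDW^-1^ h^-1^ per percent by
default); the mapping is a configurable stand-in for bounds calibrated
against measured biomass, which belong to the experiment, not the method.

For each reaction the flux variation coefficient across conditions is

$$\rho = \frac{\mathrm{sd}(v)}{\max(|\overline{v}|,\ \varepsilon)},
\qquad \varepsilon = 10^{-9},$$

with the sample standard deviation; $\rho \ge 0.01$ (inclusive) flags a
reaction as CO~2~-sensitive. The named coefficient is defined here as the
coefficient of variation with an $\varepsilon$-guard — the guard makes
all-zero flux profiles yield $\rho = 0$ rather than 0/0, and the
inclusive comparison honours the stated significance bracket. $\rho$ is
dimensionless and invariant under scaling all of a reaction's condition
fluxes by a nonzero constant.

Scan results live in a `SummarizedExperiment` (reactions × conditions,
assay `"flux"`, with $\rho$, the sensitive flag, pathway and compartment
annotations in `rowData`), so the usual Bioconductor tooling applies.
Aggregation counts sensitive reactions per pathway and per compartment
(reactions spanning compartments count as `"transport"`). For
reconciliation with metabolomics, a metabolite's net flux is the signed
dot product of its stoichiometric row with the flux vector restricted to
sensitive reactions — production added, consumption subtracted — and the
low/high ratio divides the net flux at 0.04 % by the one at 10 %,
flagged undefined when the denominator is within $\varepsilon$ of zero.

## qPCR and metabolomics reconciliation

Relative expression uses the efficiency-corrected ratio
$E_t^{\Delta Ct_t} / E_{ref}^{\Delta Ct_{ref}}$ with $\Delta Ct =
Ct(\text{high}) - Ct(\text{low})$, so values above 1 mean higher
expression at low CO~2~; the orientation is a convention fixed and
documented here. The default reference is actin alone, matching how such
panels are usually normalized; a geometric mean over several reference
genes is available. Records flagged by the melt-curve check are excluded
before averaging. With all efficiencies equal to 2 the ratio reduces
algebraically to the classical $2^{-\Delta\Delta Ct}$, which the tests
verify numerically.

Amplification efficiency is fitted per curve: after subtracting a
baseline (median of the earliest cycles), log10 fluorescence is regressed
on cycle over sliding windows of 4–6 cycles and the best window (highest
R^2^ at the widest acceptable width, R^2^ at least 0.99) gives
$E = 10^{\text{slope}}$, capped at 2.2. Two numerical guards matter: the
exponential-phase gate excludes readings below the baseline level (where
additive baseline noise dominates the log signal) and above 5 % of the
curve maximum; and when a curve demonstrably plateaus, the saturation is
inverted ($F \to F/(1 - F/F_{max})$) before fitting, because the smooth
approach to the plateau depresses window slopes while leaving R^2^ high.
Curves with no acceptable window — flat wells — are flagged, never
forced.

Metabolite intensities are normalized per sample by cell count and then
by total ion content, making every sample's analyte values sum to 1 and
the result invariant to per-sample rescaling. Fold changes are log2
ratios of condition means with Welch tests on log-scale replicates and
Benjamini–Hochberg adjustment ($\alpha = 0.05$); the replicate design of
the emulated experiment is 3 biological replicates at low and 2 at high
CO~2~. Concordance compares, per metabolite, the sign of
$\log_2(\text{net flux}_{high}/\text{net flux}_{low})$ with the sign of
the measured high-vs-low fold change; metabolites whose net-flux ratio is
undefined or changes sign between conditions are reported unevaluable
rather than forced into either class.

## What the synthetic data emulate — and what they do not

`generateNetwork()` builds a small compartmentalized autotroph with a
designed optimum: CO~2~ enters through an exchange and transport step,
a fixation core consumes it together with two photons per carbon, a
linear chain (the planted sensitive set) carries the fixed carbon to the
biomass drain, and a quench reaction absorbs unused photons. Because the
CO~2~ bound is the designed bottleneck below the light cap, the optimal
biomass equals the bound and every reaction on the carbon path scales
with it, while a pinned chain fed by a fixed uptake and disconnected
decoy cycles stay constant or at zero under the parsimonious policy.
Planted dead-end metabolites exercise gap filling. Default sizes are a
few dozen metabolites and reactions in three intracellular compartments
(cytosol, chloroplast, mitochondrion) — large enough to exercise
compartment transport and placement, small enough that the enumeration
oracle can check subproblems exhaustively.

The truth manifest distinguishes the *planted* interior chain from the
full *expected sensitive set*: the CO~2~ exchange itself, the fixation
core, the biomass drain and the photon quench necessarily vary with the
bound in any correct solution, so exact-recovery assertions compare
against the full set.

The qPCR generator produces logistic amplification curves
($F = b + F_0E^c/(1 + F_0E^c/P)$) with Ct taken from the actual
threshold crossing; Ct scatter is Gaussian (sd 0.15 cycles) and read
noise multiplicative — plausible defaults chosen here, not measured
values. The metabolite generator plants fold changes (by default
including a more-than-five-fold accumulating sugar) on low-abundance
analytes so that total-ion-content normalization leaves the planted
effects nearly intact; with planted analytes at high abundance, TIC
normalization would deform them, which is a real limitation of
composition-based normalization, not of the generator.

Passing on these conditions shows that the pipeline's logic — filtering,
placement, LP optimality, classification, bookkeeping, statistics — is
correct, and that effect sizes of the planted magnitude survive the
stated noise. It does not show that a genome-scale reconstruction of a
real alga is accurate, that real growth saturates (a linear program
cannot produce the saturation real cultures show at high CO~2~ —
biomass increases linearly in the bound until light limits), or that
real qPCR chemistry matches the logistic curve family.

## Numerical choices, degenerate inputs, limitations

* Feasibility/pivot tolerance 10^-9^; steady-state report threshold
  10^-6^; all bounds finite (default magnitude 1000).
* Ties everywhere break lexicographically (catalog ids, smallest column
  index in the solver), making every stage deterministic; re-running any
  stage on identical inputs is byte-identical.
* $\rho$ on fewer than two conditions is an error; duplicate condition
  names are rejected; an infeasible condition aborts the scan naming the
  condition.
* Zero cell counts or zero total ion content are errors; analytes absent
  from one condition are flagged, not dropped silently.
* Problem sizes used by the test-suite and acceptance computations: LPs
  up to 8 reactions for enumeration cross-checks (100 instances), 20
  blueprint networks of roughly 30–45 reactions for recovery, 50-seed
  efficiency and 100/200-seed fold-change simulations — sizes chosen so
  the whole suite re-runs in well under half an hour on one core.
* Headline counts of the original genome-scale study (enzymes found by
  homology, reactions added, 155/87 sensitive reactions) depend on the
  specific base reconstruction, database snapshots and calibrated
  condition fluxes, none of which are shipped here; they are treated as
  descriptive context, not as targets the synthetic conditions could or
  should reproduce.
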