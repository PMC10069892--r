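---
title: "Respiratory CO2 traits in constraint-based plant models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Respiratory CO2 traits: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(respitraits)
```

## The problem

Plant respiration releases CO2 through a dispersed set of enzymatic steps —
glycine decarboxylase closing the photorespiratory cycle, the pyruvate
dehydrogenase and 2-oxoglutarate dehydrogenase complexes, isocitrate
dehydrogenase, 6-phosphogluconate dehydrogenase of the oxidative pentose
phosphate pathway, and malic enzyme, among others — spread over
mitochondria, plastids, peroxisomes and the cytosol. Genome-scale metabolic
models make these fluxes computable: under the steady-state assumption
$S\,v = 0$ with flux bounds $l \le v \le u$, flux balance analysis (FBA)
predicts a flux distribution maximizing a biomass objective, and
parsimonious FBA (pFBA) selects, among the optima, the distribution with
minimal total absolute flux.

This package computes, from any such model, a panel of respiratory CO2
traits; screens all single and double reaction knockouts for their effect
on CO2 release per unit of biomass carbon; minimizes that ratio directly as
a linear-fractional program; compares the complements of CO2-producing
enzymes (as EC-number sets) across models; and implements the classical
whole-plant respiration models that these flux-level quantities connect to.

## The trait panel

All traits derive from a single pFBA distribution computed under a
physiological constraint on RuBisCO: the oxygenation:carboxylation ratio
$V_o/V_c$ is confined to $[0.31, 0.55]$, the range implied by intracellular
O2:CO2 partial pressures divided by the average CO2/O2 specificity of
RuBisCO. The panel is:

* **Net CO2 assimilation** $A_{net}$: the difference between the summed
  fluxes of CO2-consuming and CO2-producing reactions, direction-aware (a
  reversible carboxylase running backward counts as production). Magnitudes
  below $10^{-9}$ mmol gDW$^{-1}$ h$^{-1}$ — the solver feasibility
  tolerance — are reported as zero.
* **Day respiration** $R_d = V_c - 0.5\,V_o - A_{net}$, the
  Farquhar–von Caemmerer–Berry decomposition: each oxygenation ultimately
  releases half a CO2 in the photorespiratory cycle, and whatever CO2
  evolution remains after accounting for photorespiration is
  non-photorespiratory (day) respiration.
* **Carbon use efficiency** $\mathrm{CUE} = 1 - (0.5\,V_o + R_d)/V_c$,
  which is algebraically identical to $A_{net}/V_c$; the test suite asserts
  this identity to $10^{-9}$ on every computed trait set rather than
  assuming it.
* **Growth respiration** $R_g$: the sum of fluxes through all CO2-releasing
  reactions at the same distribution. This is the operational, flux-level
  quantity; it is distinct from the growth-respiration coefficient
  $g_R$ of the classical growth-and-maintenance model (see below), and the
  output labels keep the two apart.
* **Release and fixation capacity**: $R_{netmax}$ maximizes CO2 export, and
  $A_{netmax}$ maximizes CO2 import minus export, both at FBA-optimal
  growth. Note that on a *closed* photoautotroph — CO2 the sole carbon
  source, as in the day model of the toy world — carbon conservation pins
  the CO2 exchange at optimal growth to exactly $-$ (biomass carbon flux),
  so $R_{netmax}$ is negative there; the meaningful dominance property,
  asserted in the tests, is that it bounds the CO2 export of any optimal
  distribution from above. With a reduced-carbon source open (the night
  model's starch pool), $R_{netmax}$ turns positive.
* **Scaled growth respiration** $R_g / (\mu \cdot c_B)$, with $\mu$ the
  growth rate and $c_B$ the molar carbon fraction of the biomass reaction
  (mol C incorporated per unit biomass flux, computed from precursor
  elemental formulas): mol CO2 released per mol carbon fixed in biomass,
  the unit in which day/night conditions and knockouts are compared.

CO2 production and consumption are defined by a per-model **inventory**:
every metabolite recognized as CO2 (by CHEBI-style annotation, chemical
formula `CO2`, or id/name matching, across all compartments) contributes
its stoichiometric coefficient to a reaction's net CO2 per unit forward
flux. Transport reactions (CO2 translocation between compartments) and
exchange reactions are excluded from production accounting — translocation
moves CO2 without making it, and boundary transport is reported separately.
Reactions that merely interconvert CO2 and bicarbonate count as
producers/consumers by default (they do change CO2 moles); an
`ignore_bicarbonate` switch reroutes them to the excluded set. RuBisCO
carboxylation and photorespiratory decarboxylation are deliberately *not*
excluded at inventory level: the trait layer needs the full sets, and an
explicit exclusion list is available for the stricter biochemical
definition of respiration that leaves out photosynthesis and
photorespiration.

## Day/night comparison and the knockout screen

`compare_conditions()` solves the day model first and bounds the night
model's growth from above by the day optimum, so scaled traits are
comparable across the two conditions. `run_screen()` re-solves pFBA for
every knockout set (bounds closed to zero), records growth, $R_g$, scaled
$R_g$ and fold-changes against the wild type from the same constraint
regime, and prunes pairs whose members both carry zero wild-type flux —
their joint knockout provably leaves the wild-type optimum feasible, and
under a deterministic solver the pruned records would be identical to the
wild type. A knockout is viable when its growth exceeds $10^{-6}$ times the
wild-type growth, separating numerically-zero growth from slow growth.

`minimize_scaled_respiration()` minimizes
$\sum_{\text{producing}} (\text{CO2 flux}) \,/\, (c_B \cdot \mu)$ exactly,
via the Charnes–Cooper substitution $y = t\,v$, $t \ge 0$, denominator
$\equiv 1$, which converts the linear-fractional program over the flux
polytope into a single LP. The direction-aware numerator is linearized on
the split (forward/backward) flux system; because the numerator is
minimized, the two halves of a reversible reaction are never
simultaneously inflated. A degenerate solution with $t^* = 0$ (an
unbounded growth direction) is refused with an error.

## The LP backend

No linear-programming package is available in the target environment, so
the package ships its own dense two-phase primal simplex (C++ via
RcppArmadillo) behind a narrow interface (`solve_lp()`): canonicalization
shifts finite lower bounds, splits free variables, and adds slack rows;
the solver uses Dantzig's entering rule with a stability-biased ratio test
(largest pivot among near-minimal ratios), switches to Bland's rule if an
iteration budget is exceeded (guaranteeing termination), and
refactorizes — rebuilds the tableau from the current basis with a fresh
linear solve — every 250 pivots and at every claimed optimum, which bounds
the roundoff drift that plain tableau updates accumulate. Feasibility and
reporting tolerances are $10^{-9}$; optimality comparisons in the tests
use $10^{-6}$. The solver is deterministic: identical inputs give
identical pivots, so screens are byte-reproducible. Its correctness is
cross-checked in the test suite against an independent vertex-enumeration
oracle on every fixture with at most 8 reactions, and the fractional
minimizer against a bisection oracle, to $10^{-6}$ and $10^{-5}$
respectively.

pFBA splits only reactions whose bounds straddle zero. Because total-flux
minimality does not pin individual fluxes, a `lexicographic` option (the
default for reported traits) additionally minimizes each reaction's
absolute flux in reaction-id order with the total pinned; reported fluxes
below $10^{-8}$ (the pinning slack) are rounded to zero.

## The synthetic world

`generate_toyplant()` builds "toyplant-v1", a four-compartment C3
photoautotroph with ~60 reactions: RuBisCO carboxylation and oxygenation, a
lumped Calvin–Benson cycle, thylakoid light reactions (8 photons
$\rightarrow$ 2 NADPH + 2 ATP) with cyclic electron flow (2 photons
$\rightarrow$ 1 ATP), the full two-arm photorespiratory salvage
(phosphoglycolate phosphatase, glycolate oxidase, two aminotransferases,
glycine decarboxylase returning serine, CO2, NH3 and NADH, hydroxypyruvate
reductase fed by a malate/oxaloacetate shuttle, glycerate kinase), plastid
oxidative pentose phosphate decarboxylation (EC 1.1.1.49 + EC 1.1.1.44) and
NADP-malic enzyme (EC 1.1.1.40), starch mobilization for the night model,
mitochondrial PDH/citrate synthase/IDH (EC 1.1.1.42)/OGDH (EC
1.2.4.2)/lumped lower TCA, transhydrogenase, oxidative phosphorylation,
alternative oxidase and an external NADH dehydrogenase, cytosolic lower
glycolysis, and a biomass reaction (triose phosphate + serine + ATP +
NADPH) with full elemental formulas.

Every internal reaction is balanced for C, H, O, N and P; the generator
closes H and O automatically with water and protons and refuses to emit a
model with a C/N/P imbalance. Three simplifications keep the network
tractable while preserving the science: water, protons, phosphate and O2
are single pooled species rather than per-compartment pools (they carry no
carbon and no redox information); cofactor formulas are neutral bookkeeping
forms chosen so each couple differs by a consistent moiety; and several
multi-step pathways are lumped. ATP, NAD(P)H and all carbon metabolites
*are* compartmentalized, because the biology under test depends on it: in
the dark the chloroplast can regenerate NADPH only through the oxidative
pentose phosphate pathway, which is what makes 6-phosphogluconate
dehydrogenase the dominant dark CO2 producer, while the forced oxygenation
flux makes glycine decarboxylase dominate in the light.

Two stoichiometric choices pin the day optimum to a closed form. With the
light reactions delivering ATP:NADPH at 1:1 and cyclic electron flow at 2
photons per ATP, one unit of biomass (6 mol C: 1 triose + 1 serine) costs
$V_c = 6$ carboxylations, 12 NADPH and 19 ATP, hence $6 \times 8$ photons
through the light reactions plus $7 \times 2$ through cyclic flow: **62
photons per unit biomass**, so the FBA optimum is `photon_bound`/62
exactly. For this to be the unique optimum, (i) oxidative phosphorylation
runs at P/O 2.0, which makes a burn-and-refix loop (respiring fixed carbon
for ATP, then re-fixing the CO2) strictly less photon-efficient than
cyclic electron flow, and (ii) the external NADH dehydrogenase runs at P/O
1.0, which makes the triose-phosphate shuttle exactly cost-neutral as an
NADPH-to-ATP converter — a tie that pFBA resolves to zero shuttle flux.
Both values sit at the low end of the physiological range; they are
accuracy-of-the-toy choices, not biological claims.

Defaults: `photon_bound = 100` mmol gDW$^{-1}$ h$^{-1}$ (growth rate
$\approx 1.6$ h$^{-1}$ unconstrained, dimensionless toy units at a
leaf-like scale), `starch_bound = 1.2` for the night model (chosen so
night growth, capped by the day optimum, is starch-limited but positive).
The night model differs from the day model only in its exchange bounds
(photons closed, starch open) — same reaction roster, as in paired
day/night models of real plant metabolism.

The generator records its ground truth — the closed-form optimum, the
producer/consumer/excluded label of every CO2-touching reaction, the
biomass carbon content (6), and the expected dominant day and night
producers — and `generate_random_variant()` adds seeded, carbon-balanced
decarboxylating bypass reactions with labels derived from their sampled
stoichiometry, so the inventory classifier is property-tested on inputs it
was not written against.

What a green test on this world does establish: the LP machinery agrees
with enumeration; the trait algebra is exact; the classifier matches
designed labels; the day/night ordering of scaled respiration and the
identity of the dominant producers follow from the designed physiology.
What it does not establish: anything about the numerical trait values of
real genome-scale models, which depend on curation choices, biomass
compositions and alternate optima that the toy does not emulate.

## Classical growth models

`respiration_eq1()` implements the growth-and-maintenance decomposition
$R = g_R\,\mathrm{d}W/\mathrm{d}t + m_R W$ ($g_R$ in mol CO2 per mol C,
$m_R$ per unit time), `respiration_general()` the cost-weighted general
paradigm $R = \sum_r \alpha_r v_r$ (negative unit costs are allowed, with a
warning, for CO2-consuming processes); the two coincide when the process
roster encodes exactly growth and maintenance, and the package treats them
as one operation with different rosters. The nitrogen–carbon
balanced-growth extension partitions nitrogen as $N = N_p + \gamma C$ with
$W = kC$, giving the linear ODE
$\mathrm{d}W/\mathrm{d}t = (\phi_{CN} N_p k - \phi_{CN}\gamma W - m_R W)/(1+g_R)$;
note the inflow term is *multiplied* by $k$, as the substitution
$W = kC$ with $\mathrm{d}C/\mathrm{d}t = \phi_{CN} N_p$ requires.
`simulate_nc_growth()` integrates it with fixed-step RK4, halving the step
until self-convergence at $10^{-10}$ relative — the system is linear and
stiffness-free, so nothing more sophisticated is warranted — and the test
suite validates the trajectory against the closed form
$W(t) = a/b + (W_0 - a/b)e^{-bt}$ to $10^{-8}$ across a 20-point
parameter grid.

## Design decisions on points the analysis leaves open

* **Formula-less biomass precursors** (how carbon molar fractions treat
  metabolites without formulas): skipped and *reported* in
  `skipped_metabolites`, so the choice is auditable per model.
* **CO2 exchange in growth respiration**: exchange fluxes are excluded
  from $R_g$ and $A_{net}$ (they are boundary transport, not production)
  and used explicitly only in $R_{netmax}$/$A_{netmax}$; the inventory
  report makes the exclusion explicit.
* **EC harvesting** follows a fixed precedence — CV-term annotations, then
  a regex over reaction notes, then an optional user mapping table — with
  all hits at the first successful level kept; partial EC numbers compare
  as opaque strings (set identity, no hierarchical matching).
* **Alternate optima**: trait computations default to lexicographic pFBA
  so printed values are backend-stable; the screen relies on the solver's
  determinism instead (lexicographic screening is available but ~50x more
  LP solves).
* **Scaled-respiration reference**: the ratio reported as "before" is the
  scaled $R_g$ of the lexicographic pFBA solution under the same
  constraint regime as the minimization — both candidate readings (pFBA
  value vs. independently evaluated optimum) are computable, and the
  functions return the ingredients of each.

## Known limitations

* The simplex is dense and suited to models up to a few hundred reactions;
  genome-scale models (thousands of reactions) would need a sparse
  factorized backend behind the same `solve_lp()` interface.
* The toy world has a single biomass composition and no thermodynamic
  constraints; loops are excluded by pFBA parsimony, not by
  loop-law constraints.
* Gene–protein–reaction rules are out of scope: knockouts are
  reaction-level.
* The day model is carbon-closed, so release-capacity traits behave
  differently than in published models with rich exchange menus (see the
  trait panel section); this is a property of the fixture, not of the
  trait code.
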