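---
title: "Elementary flux patterns, pathway discovery and pathway energetics"
author: "fluxpattern"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Elementary flux patterns, pathway discovery and pathway energetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxpattern)
```

## The model

A metabolic network is a stoichiometric matrix $N$ with one row per
internal metabolite and one column per reaction; external metabolites
(CO₂ in all shipped fixtures, plus whatever an externalization policy
adds) impose no constraint. After `split_reversible()` every column is
irreversible, so the admissible steady states form the pointed polyhedral
cone

$$C = \{v \;:\; N v = 0,\; v \ge 0\}.$$

Its extreme rays are the **elementary flux modes** (EFMs): fluxes whose
support (set of active reactions) is minimal. A whole-cell network has
astronomically many EFMs, which motivates the subsystem view: given a
subsystem $S$ of reactions of interest, a **flux pattern** is a subset
$P \subseteq S$ such that some $v \in C$ is positive exactly on $P$
within $S$, and a flux pattern is **elementary** (an EFP) when it is not
a union of other flux patterns. Every EFP is the $S$-projection of at
least one whole-network EFM, its *witness*; witnesses certify that a
pattern seen in the subsystem corresponds to a complete steady-state
pathway through the entire network.

Splitting a reversible reaction creates a forward/backward column pair
whose simultaneous use is a spurious two-cycle. The engines therefore
never report two-cycle modes, reject candidate patterns containing both
directions of one parent, and force the opposite direction to zero when
one direction of a pair is a required subsystem member. Patterns and
routes are reported over split ids (`PGI_f`/`PGI_b`), which keeps the
direction information the figures of the field usually annotate.

## Engines and their guarantees

Three independent computational routes cross-validate each other:

* **The oracle** (`enumerate_efms()`): double description run on a
  rational nullspace basis of $N$, processing one nonnegativity
  constraint at a time with the combinatorial adjacency test. All
  arithmetic is exact (numerator/denominator pairs of doubles, reduced
  with a vectorized gcd), so the enumeration is provably complete for
  networks up to the configured cap (32 columns by default). Modes are
  normalized so their smallest nonzero flux is 1.
* **The LP layer**: a dense two-phase primal simplex with Bland's rule.
  The problems are small (tens of rows/columns) and rationally valued, so
  determinism mattered more than speed: identical inputs give identical
  optimal bases, hence identical witness fluxes and byte-identical
  reports. Structural conclusions are never drawn from floating point —
  elementarity of any candidate support is certified by an exact rank
  test, which also recovers the exact rational flux.
* **The pattern/mode engines** (`enumerate_efps()`, `k_shortest()`,
  `witness_mode()`): pattern-hood is one LP feasibility query per
  candidate member set ($v_i \ge 1$ on members, $v_j = 0$ on the
  subsystem complement), scanned in cardinality order with lexicographic
  tie-breaks; union-reducible patterns are filtered afterwards.
  `k_shortest()` enumerates all target-containing EFMs by recursive
  reaction exclusion — find one mode by LP, then branch on excluding each
  non-required support reaction; because elementary supports form an
  antichain, every other mode survives in some branch — and sorts by
  support cardinality, so the result for $K$ is a prefix of the result
  for $K+1$. Support reduction (used by witnesses and the exclusion
  search) forces support reactions to zero one at a time until the exact
  rank test accepts the support as a single elementary mode.

The test suite asserts exact agreement between the engines and the oracle
on every fixture and on twenty seeded random networks, which is the
calibration for all LP tolerances (a single absolute threshold of 1e-9 on
simplex pivots and 1e-9 support cutoffs; fixture coefficients are small
rationals, so basic solutions are well separated from these thresholds).

## Pathway discovery

`discover(net, source, target)` reproduces the iterative
subsystem-expansion procedure: the seed subsystem is
$\{source, target\}$; each round enumerates EFPs, takes witnesses of the
target-containing patterns, and adds their reactions to the subsystem —
except *essential* reactions, which every route must use anyway. A
reaction is essential when the LP $\{Nv=0, v\ge 0, v_{target}\ge 1,
v_r=0\}$ is infeasible. This LP criterion is the definition consistent
with "required for production at steady state"; the suite cross-validates
it by checking that every essential reaction occurs in every oracle
route. Two design choices are worth stating:

* a reversible parent joins the subsystem as **both** split directions
  (the subsystem is a set of reactions, not of directions);
* two witnesses count as the same route when their supports coincide
  outside a declared cofactor-reaction set, mirroring the
  externalization idea of the K-shortest setup.

On the glycolysis/PPP fixture the procedure terminates in three
iterations with 2, 3 and 8 patterns and exactly two ribose-5-phosphate
routes (oxidative and non-oxidative); on the ketogenesis fixture it finds
the two acetol branches discussed below.

## The fixtures

`build_glycolysis_ppp()` is hepatic upper glycolysis plus the PPP:
glucose exchange in both directions, hexokinase, reversible PGI, the
PFK/FBPase substrate cycle, reversible aldolase to a lumped triose
phosphate with a drain, a lumped oxidative branch (G6P → Ru5P + CO₂) and
the five reversible non-oxidative interconversions. The glucose efflux
and the FBPase make the fixture's pattern lattice rich enough to exhibit
the full three-iteration discovery walkthrough; both are standard liver
enzymes rather than modelling artifacts.

`build_tca(glyoxylate)` contrasts the TCA cycle with and without the
isocitrate lyase / malate synthase bypass: without it no flux pattern
contains the oxaloacetate outflow (the two acetyl carbons leave as CO₂);
with it a pattern exists whose witness consumes exactly two acetyl-CoA
per oxaloacetate.

`build_ketone_acetone()` is the centrepiece. The carbon skeleton runs
acetyl-CoA → (thiolase, HMG-CoA synthase/lyase) → acetoacetate →
acetone + CO₂ → acetol → methylglyoxal → pyruvate → oxaloacetate → PEP →
G6P. Acetoacetate decarboxylation is one irreversible step regardless of
its enzymatic or spontaneous mechanism — stoichiometry, not kinetics, is
in scope. Two alternative acetol → methylglyoxal steps exist: an
NAD⁺-coupled dehydrogenation (`ACDH`) and a direct NADPH-consuming
monooxygenase-type conversion (`AKRED`); methylglyoxal oxidation to
pyruvate reduces NADP⁺. An optional D-lactaldehyde branch (off by
default) adds the further acetone routes via that intermediate. Every
acetyl-CoA → G6P mode obeys 4 AcCoA → 1 G6P + 2 CO₂ + 4 CoA.

With `include_cofactors = TRUE` the network carries charged cofactor
species only (`atp`, `gtp`, `nadh_c`, `nadh_m`, `nadph_c`, `fadh2_m`;
the discharged partners are implicit, which halves the bookkeeping
without changing any balance), the pyruvate–malate NADPH cycle as a
lumped reaction (1 ATP + 1 mitochondrial NADH per cytosolic NADPH), a
nucleoside diphosphate kinase, and the surrounding liver energy
metabolism (glycolysis lumps, PDH, a lumped TCA turn yielding 3 NADH +
1 FADH₂ + 1 GTP, glycerol kinase/G3P dehydrogenase, citrate-shuttle
export of acetyl-CoA at 1 ATP, a lipogenesis lump of 8 AcCoA + 7 ATP +
14 NADPH per palmitate, and the β-oxidation lump returning 8 AcCoA +
7 NADH + 7 FADH₂ for 2 ATP per palmitate). The gluconeogenic segment
from PEP charges 1 ATP (phosphoglycerate kinase) and 1 cytosolic NADH
(GAPDH running reductively) per PEP.

`build_random(seed, n_modes, n_mets)` superposes seeded random
source-to-sink chains; chains share reactions, so the elementary mode
structure is richer than the generating routes. It exists purely to give
the equivalence properties a large, unbiased test bed.

What the fixtures deliberately do **not** emulate: genome-scale route
multiplicity (full human metabolic reconstructions support dozens of
distinct ketogenesis and acetone-degradation routes that the lumps here
collapse), kinetics and regulation, proton/water bookkeeping, and membrane
transport energetics beyond the lumps listed above. Passing tests
therefore demonstrate correctness of the algorithms and of the lumped
liver stoichiometry, not quantitative agreement with any genome-scale
model.

## Energetics

`atp_cost(net, route, policy)` answers: carrying this route at one mole
of product, with every internal metabolite balanced, what is the minimal
net ATP consumption? The LP restricts support to the route plus the
policy's balancing reactions, fixes the output flux at 1, and settles
each priced cofactor pool through an exchange column weighted by its
ATP-equivalent: 2.5 per mitochondrial NADH, 1.5 per cytosolic NADH
(glycerol-phosphate-shuttle entry) and 1.5 per FADH₂. These exchanges
*are* the lumped respiratory chain with configurable yield — drawing a
cofactor costs what respiration would have earned from it, returning one
earns the same credit, so no arbitrage is possible. NADPH deliberately
has no exchange: it must be balanced in-network through the
pyruvate–malate cycle, which is what makes the NADPH-consuming acetol
branch expensive (6 vs 16 ATP per glucose; the 10-ATP premium is
2 × 3.5 for replenishment plus 2 × 1.5 for the unregenerated cytosolic
NADH). GTP counts as ATP through the kinase. The P/O ratios are policy
parameters, not constants; the shipped defaults are the textbook values,
and together with the lump stoichiometries they reproduce the pair
6/16 exactly — that calibration is asserted in a test rather than
hard-coded anywhere.

The efficiency metrics are ratios of such LP results.
*Gluconeogenic energy efficiency* of a substrate:
$(Y_{glc} - C_{gng}) / (m \, Y_{sub})$, where $Y$ are maximal catabolic
ATP yields, $C_{gng}$ the minimal net cost of forming one glucose, and
$m$ the substrate moles required. *Glucose storage efficiency*: glucose
regained over glucose invested for the round trip glucose → compound →
glucose, with each leg's net ATP converted to glucose equivalents at the
glucose yield $Y_{glc}$ (30 under the default policy). Both computations
are two-stage LPs — optimize carbon first, then cost at fixed carbon —
because a one-stage cost minimization could profitably burn extra
substrate. On the lumped network these come out at 93.9% for glycerol
and 51.4% for palmitate via the efficient route — close to, but not
exactly, the round figures a genome-scale reconstruction yields, because
the lumps collapse minor side routes.

`gibbs_change()` implements the transformed-formation-energy sum with
$RT$ concentration terms (pH 7.2, 37 °C, 1 mM default concentration
where unmeasured). The shipped table
(`inst/extdata/thermo_ketone_synthetic.tsv`) is synthetic: real-compound
values are literature-flavoured, CoA-ester values are internally
consistent inventions, and charged-cofactor "formation energies" encode
hydrolysis/oxidation free energies under the charged-species convention.
It supports the qualitative claim the tests assert — every discovered
gluconeogenic route is thermodynamically feasible (ΔG < 0) — and nothing
more.

## Numerical choices and degenerate inputs

* Simplex: Bland's rule (no cycling), pivot tolerance 1e-9, two-phase
  with explicit artificial-variable drive-out; redundant constraint rows
  are dropped during phase 1.
* Support membership: flux > 1e-9 after an exact-rational recovery of
  the candidate support; the recovery fails loudly rather than rounding.
* Tie-breaks everywhere are lexicographic on reaction ids; enumeration
  output is canonically sorted, so identical runs produce byte-identical
  JSON.
* Zero columns (reactions whose every metabolite is externalized) are
  legal; they can never enter a support-minimal mode containing a
  target.
* Degenerate requests error with diagnoses: unreachable targets, member
  sets containing both directions of a split pair, unbalanceable species
  in `atp_cost()` (named in the message), zero vectors in
  `is_elementary()`.
* Problem sizes: the shipped analyses run on 15–38 column networks; the
  exhaustive oracle is capped at 32 columns by default, and the whole
  test suite (including the twenty-network equivalence sweep) completes
  in well under a minute on one core.

## Known limitations

Exhaustive enumeration is exponential and meant only as ground truth at
fixture scale. The subset scan in `enumerate_efps()` is exponential in
the subsystem size (fine up to ~16 members as used here). The discovery
procedure inherits the field's assumption that witnesses of elementary
patterns exist as single elementary modes; pathological networks where a
pattern is realizable only as a superposition are reported as errors
rather than silently approximated. The energetics layer prices cofactors
linearly and ignores thermodynamic driving-force constraints on
individual reactions; ΔG is evaluated for overall conversions only.
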