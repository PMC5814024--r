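---
title: "Predicting element-transferring reactant/product pairs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting element-transferring reactant/product pairs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(primarypairs)
```

## The model

A metabolic reaction moves chemical elements from reactants to products
through specific compound pairs — its *primary pairs*. `primarypairs`
predicts them from the two pieces of information present in essentially
every metabolic reconstruction: the stoichiometric equation and the
compound formulas. No chemical structures, atom mappings or curated
annotations are required.

The prediction alternates two steps until a fixed point:

**Per-reaction greedy assignment.** Compounds are expanded into instances
by their (integer) stoichiometric coefficients; this makes, say, the two
identical halves of a dimerization reaction individually assignable. Every
reactant-instance/product-instance pair is scored by the weighted Jaccard
similarity of the current (residual) formulas,

$$J(l,r) \;=\; \frac{\sum_e \min(l_e, r_e)\,W_e}{\sum_e \max(l_e, r_e)\,W_e},$$

multiplied by $\hat\theta_{X,Y}$, the current point estimate of the
probability that compound types $X = c(l)$, $Y = c(r)$ form a primary pair
in any reaction. The top-scoring pair is selected, the element-wise
minimum of the two residuals is recorded as the transferred formula, and
both residuals shrink by that transfer; exhausted instances drop out and
the loop repeats until no candidate pair scores above zero.

**Global re-estimation.** $\theta_{X,Y}$ is given a
$\mathrm{Beta}(\alpha,\beta)$ prior and updated with binary incidences: of
the $n_{X,Y}$ reactions in which $X$ and $Y$ occur on opposite sides,
$y_{X,Y}$ had the pair assigned at least once (assignment through several
instance pairs of one reaction still counts once). The estimate is the
posterior mode (MAP),

$$\hat\theta_{X,Y} = \frac{\alpha + y_{X,Y} - 1}{\alpha + \beta + n_{X,Y} - 2},$$

so with the default $\alpha = 1$ a pair that co-occurs often but is never
assigned is driven to exactly zero, while recurrent assignments (an
ATP/ADP-type currency couple) are reinforced. Iteration starts from
$\hat\theta \equiv 1$ and stops when no estimate moves by $\varepsilon$ or
more between successive rounds. The reported pair lists are those of the
final iteration, and the whole procedure is deterministic.

The key assumption is that *formula similarity tracks mechanism*: the
product receiving a reactant's atoms usually resembles it. The
transaldolase reaction (TALA) is the canonical counter-example — both
substrates are phosphorylated carbohydrates, and formula similarity pairs
s7p with f6p and g3p with e4p although the dihydroxyacetone moiety
actually moves the other way. `test-acceptance.R` pins this failure mode
down deliberately: it is a property of the method, not a bug. Only element
counts are tracked, never which individual atoms move.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `W_C` | 1 | weight of carbon (dimensionless, in [0,1]) |
| `W_H` | 0 | weight of hydrogen |
| `W_other` | 0.82 | weight of every other element |
| `alpha` | 1 | beta-prior pseudo-successes |
| `beta` | 43 | beta-prior pseudo-failures |
| `epsilon` | 1e-5 | convergence tolerance on $\hat\theta$ |
| `maxIterations` | 100 | iteration cap |

Carbon is the structural backbone of organic molecules, so equal carbon
counts are the strongest similarity signal; hydrogen bookkeeping in models
is too inconsistent (protons, hydration states) to carry information,
hence weight zero. The intermediate `W_other` and the prior `(1, 43)` are
the optimum of a grid search of all three parameters against a curated
pair reference; `gridSearch()` reproduces that protocol on any
model/reference pair, and `gridPoints()` enumerates the full 51 × 50 × 50
search grid. The sharp prior (mean 1/44) encodes that most co-occurring
compound pairs are *not* primary pairs. `priorParams()` accepts any
$\alpha,\beta \ge 1$; below $\alpha + \beta = 2$ (outside the supported
grid) the posterior mode is undefined and the uninformative value 0.5 is
substituted.

## Numerical and procedural choices

* **Tie-breaking.** Two candidate pairs tie when their corrected scores
  agree within a relative tolerance of 1e-9 (exact floating-point equality
  is meaningless). Ties are broken by sorting on (reactant compound name,
  product compound name, reactant instance index, product instance index)
  and taking the first, which makes repeated runs byte-identical.
  `detectAmbiguousReactions()` reports reactions where a selection step
  tied between *distinct* compound pairs; ties between instance pairs of
  the same compound pair cannot change the prediction and are ignored.
  The count is an upper bound on real ambiguity.
* **Zero-score fallbacks.** With $\alpha = 1$, never-assigned pairs have
  $\hat\theta = 0$ exactly, so late in a reaction all corrected scores can
  vanish while elements remain; selection then falls back to the raw
  weighted similarity. A second fallback covers zero *weights*: at
  `W_other = 0` (a legitimate grid point) residuals sharing only, say,
  phosphate score zero under both criteria, and selection falls back to a
  hydrogen-blind unweighted similarity. Together with the balance
  precondition this guarantees that every non-hydrogen atom is accounted
  for at every parameter setting — `verifyElementConservation()` checks
  exactly this invariant.
* **Hydrogen-residue rule.** After the scored loop, a wholly
  hydrogen-only compound instance (a proton) that was never selected is
  paired with the opposite-side instance holding the largest hydrogen
  residual (glucose donates its twelfth hydrogen to the proton in the
  glucose kinase example), while residual hydrogen on multi-element
  compounds is dropped without creating a pair (the one-hydrogen
  difference left between 2-oxoglutarate and NADH in AKGDH). This is the
  only rule consistent with both bundled worked examples yielding exactly
  four pairs; it is isolated in a single helper should evidence favor a
  different convention.
* **Compartments.** By default $\hat\theta$ statistics strip the
  compartment tag, so a transporter moving X between cytosol and periplasm
  reinforces the {X, X} pair; `strictCompartments = TRUE` keys on the full
  id. Graph vertices always keep compartments distinct.
* **Reversibility.** Pairs are computed once, on the equation as written:
  element transfer is direction-symmetric.
* **Degenerate inputs.** Reactions with unparseable or
  indeterminate-composition formulas (repeat variables like `(C2H4O)n`,
  dot composites), non-hydrogen imbalance, synthetic (biomass/exchange)
  flags, or non-integer coefficients are excluded up front by
  `filterReactions()` with a per-reaction reason log, mirroring the
  standard data-cleaning protocol for reaction databases. Non-integer
  coefficients are excluded rather than rounded because instance expansion
  requires countable atoms — the chief offenders are biomass-type
  reactions that are excluded anyway. A compound appearing on both sides
  may pair with itself (an identity transfer), which conserves elements
  for catalytic participants. Fractional counts inside a formula string
  mark the formula indeterminate rather than erroring.
* **Evaluation universe.** `buildConfusionMatrix()` counts, per reaction,
  every (reactant, product) compound pair; carbon mode restricts the
  universe to pairs of carbon-containing compounds and predictions to
  carbon-moving transfers, so that true negatives are countable on the
  same universe as carbon-only references. MCC returns 0 when a marginal
  is zero. Grid-search ties go to the lexicographically smallest
  parameters.

## The synthetic generator

`generateSynthetic()` builds reaction sets that are balanced by
construction: each reaction draws a few *moieties* (indivisible
sub-formulas) from a pool, places one compound per moiety on the reactant
side, and re-partitions the same moieties into product compounds (single
or pairwise-merged conjugates); both sides being exact sums of the same
moieties, every element balances, and the moiety movements define a known
ground-truth pairing. Moiety carbon counts are spaced geometrically and
screened so that any two moieties (and the fixed ATP-like currency triple)
have pairwise similarity below 0.5, which makes the ground truth
recoverable from formulas. An optional currency triple (`cur_A =>
cur_B + cur_P`) recurs across a configurable fraction of reactions to
exercise the $\hat\theta$ reinforcement mechanism.

What the generator deliberately does **not** emulate: chemically realistic
formulas, near-similar substrate pairs (the TALA failure mode),
thermodynamics, reversibility effects, or the noisy, partially annotated
formulas of real databases. Passing the recovery property therefore shows
that the machinery is implemented correctly under its own assumptions, not
that real-database accuracy is reproduced — that comparison requires the
external curated references, which are read through
`readReferencePairs()` but are not bundled.

Test and acceptance problem sizes were chosen to keep the suite quick on a
laptop while still exercising every mechanism: the 5-reaction bundled
model for the worked examples, 1000 synthetic reactions for the
conservation property, 20 seeds × 30 reactions for recovery, all
$(y, n)$ with $n \le 50$ for the MAP-vs-numeric-oracle check, and 2×2×2
executed grids (the full grid is shape-checked only).

## Known limitations

* Predictions are wrong whenever the most similar formulas are not the
  mechanistic pair (TALA-type reactions); such cases need manual curation.
* Tie reporting flags potential, not realized, ambiguity.
* Formulas with indeterminate composition exclude their reactions
  entirely; partial information (e.g. polymer repeat units) is not used.
* Charges and isotopes are ignored; balance is judged on non-hydrogen
  element counts only.
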