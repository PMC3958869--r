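---
title: "Predicting PDMS-water partition coefficients from molecular structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting PDMS-water partition coefficients from molecular structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spmekfw)
```

## The problem

Solid-phase microextraction (SPME) samples organic analytes from water with
a fiber coated in polydimethylsiloxane (PDMS). At equilibrium the analyte
partitions between coating and water with a coefficient
$K_{fw} = C_f / C_s$, and the mass captured by a coating of volume $V_f$ in
a sample of volume $V_s$ follows from the two-phase mass balance

$$M_f \;=\; \frac{K_{fw}\,C_0\,V_s\,V_f}{K_{fw} V_f + V_s},$$

so the sensitivity of an SPME method for a given analyte is governed by
$K_{fw}$. Measured coefficients exist for a few hundred compounds;
everything else needs an estimate. This package implements a quantitative
structure-property relationship (QSPR): three descriptors computed directly
from the molecular graph predict $\log_{10} K_{fw}$ by ordinary least
squares.

## The descriptors

**Additive polarizability** $\Phi$ is a group-contribution surrogate for
molecular polarizability, the property that controls the London-dispersion
attraction between a nonpolar analyte and the nonpolar PDMS phase. It is a
dot product of feature counts (atoms by element, hydrogens, rings, double
and triple bonds) with fixed contribution factors; `pdms_scheme()` holds
the factor table (carbon 0.577, hydrogen −0.120, oxygen −0.825, ...,
double bond −0.859).

**First-order valence molecular connectivity index** $^1\chi$ encodes
molecular size and branching. Each heavy atom gets a delta value
$\delta = Z_v - h$ (valence electrons minus attached hydrogens); the index
sums $(\delta_i \delta_j)^{-1/2}$ over all bonds. More branching at fixed
size lowers the index. For chlorine, bromine and iodine the second-row
definition does not reproduce the published indices and the Kier–Hall
higher-row form $\delta = (Z_v - h)/(Z - Z_v - 1)$ is used (verified
against the printed chlorobenzene 2.477 and bromobenzene 2.891 values).

**Indicator variable** $I$ marks hydrogen-bonding ability: 1 for any
compound with N/O/halogen bound to a hydrogen-bearing carbon, any
acetylenic compound, and any aromatic with ring hydrogens; 0 otherwise.
Hydrogen-bond donors/acceptors prefer the aqueous phase, so $I$ enters
with a negative coefficient.

`parse_smiles()` supplies the molecular graphs from a deliberately narrow
SMILES dialect (C/N/O/F/Cl/Br/I, branches, rings, `- = #` bonds, aromatic
`c n o`); anything outside the dialect is rejected loudly rather than
mis-parsed. Hydrogens are never graph nodes — both descriptors operate on
the hydrogen-suppressed skeleton with per-atom hydrogen counts.

## Conventions fixed by back-calculation

The source tables print descriptor values without stating all counting
conventions; the following were fixed by back-calculating printed values,
and each is exposed as a `pdms_scheme()` option:

* **Aromatic rings in $\Phi$** contribute three double-bond terms each and
  no cycle term (benzene $6(0.577)+6(-0.120)+3(-0.859)=0.165$ as printed;
  a cycle term would give $-0.787$). Fused systems contribute three per
  ring — naphthalene's printed $-0.344$ requires six double-bond terms,
  one more than a Kekulé perfect matching provides. Non-aromatic rings
  contribute the cycle term.
* **Hydrogen counting** includes O–H and N–H hydrogens, although the
  factor table's footnote says carbon-attached only: the printed m-cresol
  ($-0.323$), 3-chlorophenol ($-0.727$) and 4-chloroaniline ($-0.022$)
  values are consistent only with all-hydrogen counting.
  `count_heteroatom_hydrogens = FALSE` restores the literal footnote.
* **Nitrogen** has no factor row; benzonitrile (0.753) and 4-chloroaniline
  back-calculate with a nitrogen contribution of exactly 0, which the
  default scheme encodes explicitly.
* **Hydroxyl oxygens**: the factor table lists a hydroxyl factor of
  −3.701, yet every printed hydroxyl compound — including the aliphatic
  alcohols benzyl alcohol ($-0.323$) and phenethyl alcohol ($0.014$) —
  back-calculates with the plain oxygen factor ($-0.825$). The default
  scheme therefore applies the oxygen factor to all oxygens;
  `hydroxyl_factor = "aliphatic"` opts into the literal table behaviour
  for sp³ C–OH groups. No printed compound is consistent with the hydroxyl
  factor, so the literal mode exists for completeness, not reproduction.
* **Kekulé assignment** is deterministic (depth-first matching from the
  lowest atom index); for benzenoid systems every valid assignment yields
  identical descriptors because neither $^1\chi$ (bond-order blind) nor
  $\Phi$ (per-ring counting) depends on which alternation is chosen. This
  is property-tested.

## Known discrepancies in the printed tables

Recomputing all 87 compounds from structure reproduces the printed
$^1\chi$ and $\Phi$ to ±0.005 except for eleven entries, returned by
`kfw_anomalies()` and flagged by `check_consistency()`. Four look like
plain misprints (e.g. 2,2,3-trimethylbutane's index printed 3.944 where
the computed value is 2.943; a molecular weight of 122 for C₈H₁₆). The
rest are internal inconsistencies: phenol's polarizability disagrees with
every other hydroxyl compound; the biphenyl value duplicates the adjacent
1-methylnaphthalene row; three chlorinated benzenes imply chlorine deltas
inconsistent with chlorobenzene itself; iodobenzene's printed index
differs by 0.018 from the higher-row iodine delta. Printed values are
never "corrected" — the packaged tables carry them verbatim, and all
regression reproduction uses them as printed.

## The regression models

The response is $\log_{10} K_{fw}$ throughout; the tables print $K_{fw}$
and the loaders add the transform. `kfw_fit()` is ordinary least squares
via QR (delegated to `lm()`), returning the multiple correlation
coefficient $r = \sqrt{1 - SSE/SST}$. Refitting the printed training
table reproduces the published fits:

```{r refits}
train <- kfw_training()
kfw_fit(log_kfw ~ phi, train)                      # r = 0.977
kfw_fit(log_kfw ~ phi + chi1 + indicator, train)   # r = 0.989
```

`kfw_published()` returns the published equations verbatim for
prediction without refitting. Two quirks are kept deliberately: the
four-descriptor equation's water-solubility coefficient is printed as
+0.001 although the refit value is −0.00015 (and the single-parameter WS
slope is negative), so that equation extrapolates poorly to very soluble
compounds; and the single-parameter correlation table reports $r$
unsigned, so `kfw_model` objects carry both `r` and `r_signed`.

Stepwise selection is approximated by forward selection with an entry
threshold of $p \le 0.05$ (`forward_selection()`); on the training table
it admits all four of $\Phi$, $^1\chi$, $I$, $WS$ in that order, matching
the published stepwise outcome.

## Test-set agreement and the validation statistic

Applying the published three-descriptor equation to the 26 test compounds
and correlating predicted with observed $\log_{10} K_{fw}$ gives an
ordinary Pearson $r$ of only 0.54 — yet the published agreement value is
0.819. No conventional choice (linear scale, refit coefficients, rank
correlation) reproduces that number. What does is the **through-origin
(uncentered) correlation** on the log scale,
$r_0 = \sum xy / \sqrt{\sum x^2 \sum y^2}$, the $r$ associated with a
regression line forced through the origin in the observed-vs-predicted
plane — the natural statistic for a calibration-style comparison plot:

```{r validate}
kfw_validate(kfw_published("eq5"), kfw_test(), scale = "log")
```

`kfw_validate()` therefore reports both: `r` (centered) for conventional
use and `r_origin`, which reproduces the published three-descriptor value
to within 0.003. The centered value is much lower because the test set
spans only ~3.7 log units with most compounds bunched at the low end, and
because the test measurements come from a different laboratory than the
training data — the observed-vs-predicted slope of ~1.3 reflects that
systematic offset. The two-descriptor equation's published 0.771 is not
reproduced by any variant tried (the through-origin value is 0.808); it
is documented here rather than chased.

## The synthetic generators

Property tests draw on two generators. `generate_alkane(k)` samples a
labelled tree uniformly over Prüfer sequences, rejecting degrees above
four, and emits SMILES — exercising the parser and descriptors on
arbitrary branched alkanes, where closed forms exist (unbranched
$^1\chi = 0.5(k-3) + \sqrt{2}$; acyclic-alkane $\Phi = 0.337k - 0.240$).
`generate_linear_dataset()` produces standard-normal designs with known
coefficients for parameter-recovery tests (exact at $\sigma = 0$, within
three standard errors at $\sigma > 0$, $n = 200$). These emulate the
structure of the real inputs, not their chemistry: generated alkanes have
no heteroatoms or rings, and the synthetic regressions have orthogonal,
homoscedastic designs, unlike the strongly collinear descriptor columns
($r_{\chi\Phi} = 0.676$). Passing them shows the machinery is correct,
not that the model generalises beyond the compound families of the
training data.

## Numerical choices and limitations

* Problem sizes are tiny (87 compounds, ≤ 6 predictors); QR-based least
  squares is exact to machine precision and no tolerance tuning arises.
  Rank-deficient designs are an error naming the aliased columns, never a
  silent coefficient drop.
* The mass-balance calculator is closed-form; conservation holds to
  relative 1e−12 over randomized systems spanning ten orders of magnitude.
* The SMILES dialect excludes charges, isotopes, stereochemistry and
  bracket atoms by design; stereoisomer pairs in the tables (cis/trans
  dimethylcyclopentanes) necessarily share descriptors — consistent with
  the printed values, which differ only in $K_{fw}$.
* Applicability domain: training compounds are alkanes and alkylbenzenes
  ($K_{fw}$ 58–93292), the test set adds monofunctional benzenes and
  phenols. Predictions for polyfunctional, ionizable or very polar
  compounds extrapolate beyond both.
* All logarithms are base 10, the field's convention for partition
  coefficients.
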