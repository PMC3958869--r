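# spmekfw

Structure-based prediction of partition coefficients between SPME/PDMS
fiber coatings and water.

## What it is for

Solid-phase microextraction (SPME) with a polydimethylsiloxane (PDMS)
coated fiber is a standard solvent-free way to sample organic compounds
from water. Whether it works for a given analyte is governed by the
equilibrium partition coefficient K<sub>fw</sub> = C<sub>f</sub>/C<sub>s</sub>
between coating and water: the extracted mass is

    Mf = Kfw · C0 · Vs · Vf / (Kfw · Vf + Vs)

for a coating of volume V<sub>f</sub> in a sample of volume V<sub>s</sub>
at initial concentration C<sub>0</sub>. Measured K<sub>fw</sub> values
exist only for a limited compound list, so this package estimates
log<sub>10</sub> K<sub>fw</sub> from molecular structure with a QSPR
model built on three descriptors computed directly from a SMILES string:

* **Φ** — additive group-contribution polarizability (dot product of
  atom/bond counts with fixed contribution factors), capturing the
  London-dispersion affinity for the nonpolar PDMS phase;
* **¹χ** — first-order valence molecular connectivity index,
  Σ<sub>bonds</sub> (δ<sub>i</sub>δ<sub>j</sub>)<sup>−1/2</sup> with
  δ = valence electrons − attached hydrogens, capturing size and
  branching;
* **I** — a 0/1 hydrogen-bonding indicator.

The central model, refit from the packaged 61-compound training table, is

    log10 Kfw = 1.447 + 0.728 Φ + 0.316 ¹χ − 0.224 I    (r = 0.989)

and is validated against an independent 26-compound test set. The package
is aimed at analytical chemists planning SPME methods and at QSPR
practitioners who want the descriptor engine (SMILES parser included, no
external chemistry toolkit required).

## Worked example

Predict K<sub>fw</sub> for ethylbenzene and size up an extraction with a
0.66 µL PDMS coating in 1 mL of water:

```r
library(spmekfw)

d <- compute_descriptors(parse_smiles("CCc1ccccc1", "ethylbenzene"))
d
#>           name     smiles     chi1   phi indicator      mw ws log_kow
#> 1 ethylbenzene CCc1ccccc1 2.971344 0.839         1 106.168 NA      NA

m <- kfw_published("eq5")
predict(m, d, type = "kfw")
#> [1] 592.5659

spme_system(kfs = predict(m, d, type = "kfw"), c0 = 1, vf = 6.6e-4, vs = 1)
#> <spme_system> Kfs = 592.566, C0 = 1, Vf = 0.00066, Vs = 1
#>   equilibrium: Mf = 0.281141 (28.11% of total analyte)
```

The computed descriptors (¹χ = 2.971, Φ = 0.839, I = 1) equal the printed
training-table entries for ethylbenzene; the predicted K<sub>fw</sub> of
593 compares with the measured 566, and at equilibrium the fiber holds
28% of the analyte mass.

Refit the models or check the data yourself:

```r
train <- kfw_training()                         # 61 compounds, printed values
kfw_fit(log_kfw ~ phi + chi1 + indicator, train)  # r = 0.989
kfw_validate(kfw_published("eq5"), kfw_test())    # test-set agreement
check_consistency(train)                          # printed vs recomputed
```

`check_consistency()` recomputes every descriptor from structure and
flags the eleven documented discrepancies in the printed tables (see
`kfw_anomalies()` and the methods vignette); anything else it reports
indicates a real problem.

A command-line interface covering batch descriptor computation, fitting,
prediction, validation and the uptake calculator is installed at
`inst/cli/spmekfw` (see `kfw_cli("--help")`).

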