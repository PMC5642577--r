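# tlpca — two-level principal component analysis for fragment-based QSAR

`tlpca` fits a bilinear, two-level model of molecular bioactivity for
quantitative structure–activity work on fragmented molecules —
prototypically, fixed-length peptides in which each residue side chain
is one fragment. It is aimed at drug-design and immunoinformatics users
who want a small, interpretable model that says *which physicochemical
properties* and *which fragment positions* drive activity, rather than a
black-box predictor.

## The model

With `x[i,l,k]` the value of physicochemical property *k* for fragment
*l* of sample *i*, the activity (e.g. pIC50) is modeled as

    w_i = Σ_l b_l · Σ_k a_k · x[i,l,k]

— one coefficient per property (`a_k`, shared across fragments) and one
per fragment position (`b_l`, shared across properties), no intercept.
The coefficients are estimated by alternating least squares from
`B⁰ = 1`: each half-step collapses the N×L×K descriptor tensor against
one coefficient level (`F = X·B`, `H = X·A`) and solves the resulting
normal system `(FᵀF)A = FᵀW` or `(HᵀH)B = HᵀW` through a truncated
eigendecomposition pseudo-inverse, until the RMS residue
`Q = √(mean (w_expt − w_fit)²)` stabilizes. At convergence,
eigen-decomposition of `FᵀF` and `HᵀH` yields normalized eigen spectra,
per-property contributions `γ_j = Σ_{k≤K'} β̃_k φ²_{j,k}`, per-fragment
contributions `λ_j`, and per-sample cosine projections and
contributions.

The package bundles its benchmark: binding affinities (pIC50) of 9-mer
epitope peptides to the human MHC class I molecule HLA-A\*0201 (90
training, 40 independent test peptides) together with an 8-scale
amino-acid side-chain property table and the reference coefficient and
eigenvalue/contribution tables.

## Worked example

```r
library(tlpca)

bench <- hla_benchmark()
x     <- encode_peptides(bench$train, bench$property_table)
fit   <- tlpca(x)
fit
#> Two-level bilinear activity model (8 properties x 9 fragments)
#> Alternating fit: 43 iterations, converged
#>
#> Property coefficients {a_k}:
#>      Lip      Hyd      S_L      S_H  P_alpha   P_beta      P_c      Vol
#> -0.02491  0.19377 -0.00223  0.00339  0.14761  0.07499  0.19099  0.00381
#>
#> Fragment coefficients {b_l}:
#> Residue-1 Residue-2 Residue-3 Residue-4 Residue-5 Residue-6 Residue-7 Residue-8
#>   2.45957   8.17749   2.98614  -4.69885   3.04584   2.43651   1.22789  -3.40222
#> Residue-9
#>  -3.59121
#>
#> Training R = 0.8859, Q (RMS residue) = 0.3688
```

The training correlation climbs from 0.41 after the first property step
to 0.886 at convergence (`plot(fit)` draws the R and Q traces). The 40
held-out peptides are predicted at r = 0.867:

```r
xte <- encode_peptides(bench$test, bench$property_table)
pearson_r(predict(fit, xte), bench$test$activity)
#> [1] 0.8671348

predict(fit, c(novel = "ILWQVPFSV"))
#>  novel
#> 8.5088   # a strong predicted binder (high pIC50)
```

The contribution analysis shows the activity signal concentrated on one
principal component per side, carried almost entirely by side-chain
volume and lipophilic surface area, with all nine positions of nearly
equal weight:

```r
contribution_analysis(fit, x)
#> Two-level PCA contribution analysis (energy threshold 0.95)
#>
#> Property side: 1 principal component(s), leading share 0.99165
#>     Vol     S_L     S_H  P_beta P_alpha     Lip     P_c     Hyd
#> 0.78853 0.20203 0.00096 0.00005 0.00003 0.00003 0.00001 0.00000
#>
#> Fragment side: 1 principal component(s), leading share 0.98801
#> Residue-1 Residue-2 Residue-3 Residue-4 Residue-5 Residue-6 Residue-7 Residue-8
#>   0.11906   0.12015   0.11092   0.09749   0.10284   0.10684   0.11790   0.10037
#> Residue-9
#>   0.11244
```

`simulate_tensor()` generates synthetic tensors with planted
coefficients for solver validation, and `read_fragment_tensor()` accepts
long-format descriptor tables for non-peptide molecules fragmented by
any external scheme.

## Command line

A thin CLI wraps the same functions (installed at `exec/tlpca` inside
the package library):

```sh
tlpca train    --dataset train.csv --property-table props.csv --out run/
tlpca predict  --model run/model.json --dataset query.fasta \
               --property-table props.csv --out pred/
tlpca analyze  --model run/model.json --dataset train.csv \
               --property-table props.csv --out analysis/
tlpca simulate --n-samples 200 --noise-sd 0 --seed 1 --out sim/
tlpca export-fixtures --out fixtures/
```

Exit codes: 0 success, 2 input/validation error, 3 numerical failure.

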