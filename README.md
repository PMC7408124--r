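# coumlox

QSAR modelling of coumarin lipoxygenase inhibitors in R.

Lipoxygenases (LOX) peroxidize polyunsaturated fatty acids; inhibiting them
is of interest both pharmacologically (inflammation) and in food chemistry
(rancidity). A series of 37 substituted coumarins (2H-chromen-2-ones,
decorated at positions 3, 6, 7 and 8) was assayed against soybean LOX-3, and
a three-descriptor multiple linear regression was published linking
log(% inhibition at 100 µM) to computed molecular structure. This package
rebuilds that entire analysis as tested, reusable code for QSAR
practitioners: the compound set, the descriptors, the model selection, the
validation battery, and the applicability domain.

## What is inside

**The compound library.** `coumarin_table()` reconstructs the 39-row data
set (37 modelled compounds plus two with no measurable LOX value) from its
substituent specifications, builds SMILES for each, and carries the
measured activities, the published train/test split (test =
{16, 19, 22, 24, 25, 28, 35, 37}) and the training-set outlier flag
(compound 14). `embed_3d()` turns any SMILES into a single
force-field-minimized 3D conformer (OpenBabel via ChemmineOB).

**The descriptors.** Three families, computed natively:

- `count_c026()` — the Ghose–Crippen atom-centered fragment *C-026*: the
  number of aromatic R–CX–R carbons, i.e. carbons flanked by two aromatic
  carbons and bearing a heteroatom substituent.
- `rdf_value()` — radial distribution function descriptors,
  RDF(r) = Σ_{i<j} w_i w_j exp(−β (r − r_ij)²), over all atom pairs with
  carbon-scaled atomic weights; *RDF035p* is r = 3.5 Å with polarizability
  weights (β = 100 Å⁻²).
- `hats_value()` — GETAWAY leverage autocorrelations,
  HATS_k(w) = Σ_{d_ij = k} (h_i w_i)(h_j w_j), with leverages from the
  molecular influence matrix H = M(MᵀM)⁻¹Mᵀ of the centered coordinates;
  *HATS8p* is lag 8 with polarizability weights.

`descriptor_matrix()` computes the full grid (fragment counts, 30 RDF radii
× 5 weighting schemes, HATS lags 0–8 × 5 schemes) for a compound table.

**Model building.** `filter_descriptors()` applies the missing-value, zero
and pairwise-correlation (R² > 0.7) elimination tests;
`select_test_set()` re-derives a test set by single-linkage clustering;
`ga_select()` runs a genetic algorithm over descriptor triples with
leave-one-out Q² as fitness; `mlr_fit()` is the underlying OLS engine with
standardized coefficients. The published equation

    log(% inhibition) = 0.67 + 0.42·C-026 + 0.07·RDF035p − 1.85·HATS8p

is frozen in `published_model()` / `predict_published()`.

**Validation.** `validate_model()` assembles the complete report: R², R²adj,
s, F, Kxx, ΔK, RMSE/MAE/CCC (training, cross-validated, external), Q²_LOO,
Y-scrambling means, Q²F1/Q²F2/Q²F3, r²m average and difference, and the
Williams plot data with warning leverage h* = 3p′/n (`plot()` draws it).

**Synthetic ground truth.** `synthetic_spec()`, `gen_descriptors()`,
`gen_response()` and `ga_recovery_experiment()` generate block-correlated
descriptor matrices and sparse linear responses so the selection and
validation machinery is testable without a single molecule.

## Worked example

```r
library(coumlox)
tbl <- coumarin_table()
m7  <- embed_3d(tbl$smiles[tbl$no == 7])   # the strongest inhibitor (96.6 %)
m7
#> molecule3d 'O=C1C(C(=O)c3ccccc3)=Cc2ccc(OCc3ccccc3)cc2O1'
#>   atoms: 43 ( 27 heavy ), 46 bonds, 18 aromatic atoms

count_c026(m7)                             # two R-CX-R carbons
#> [1] 2
round(rdf_value(m7, 3.5), 2)               # RDF035p (published: 7.003)
#> [1] 6.44
predict_published(count_c026(m7), rdf_value(m7, 3.5), hats_value(m7, 8))
#> [1] 1.76
```

The predicted 1.76 is the frozen published equation evaluated on this
package's own recomputed descriptors; the measured value is
log10(96.6) = 1.98. Differences against the published calculated column
come from conformer provenance: the original work used semiempirically
optimized geometries and a commercial descriptor engine, this package uses
a force-field conformer and open descriptor implementations.

`run_pipeline(pipeline_config(seed = 1))` executes the whole analysis
(descriptors → filtering → split → GA → validation → predictions) and
writes every table to the configured output directory.

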