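# ftirhdx

Protein secondary-structure quantification from FTIR spectra recorded
along a hydrogen/deuterium-exchange (HDX) time course.

## What it does, and for whom

The amide I band (~1700–1620 cm⁻¹) of a protein infrared spectrum reports
secondary structure, but α-helix and irregular ("Others") structure both
absorb near 1655 cm⁻¹ in H₂O. Because exposed irregular structure
exchanges its amide protons for deuterons much faster than hydrogen-bonded
helix or sheet, a short ²H₂O exposure shifts the irregular band downward
and transiently separates it from the helix band — improving helix and
Others prediction while the displaced coil band invades the sheet region
and degrades sheet prediction. `ftirhdx` is for spectroscopists and
chemometricians who want to build and validate such structure-prediction
models, and to study the timepoint trade-off quantitatively.

The package provides:

* **Preprocessing** — straight-line baseline correction between 1720 and
  1480 cm⁻¹, vector normalization over 1720–1590 cm⁻¹, sub-gridpoint peak
  localization by bias-cancelled local cubic fits, concatenation of the
  four HDX timepoint blocks (t0, t15, t105, t24h), difference spectra, and
  a CSV spectra-matrix dialect that round-trips at 12 significant digits.
* **Reference structure fractions** — a classic-format DSSP parser;
  H / E / Others percentages with Others = 100 − H − E; ordered/disordered
  helix split by amputating two residues at each helix end; parallel/
  antiparallel sheet split from DSSP bridge-ladder case; amino-acid
  compositions.
* **Side-chain correction** — a configurable band library (Gln anchored at
  1672 cm⁻¹ protonated / 1635 cm⁻¹ deuterated), composition-weighted
  synthesis and exact stoichiometric subtraction.
* **Calibration engines** — NIPALS PLS with interval scanning (`ipls_scan`),
  least-squares SVM regression (RBF dual solve with closed-form LOO grid
  search), and ascending stepwise linear regression (greedy wavenumber
  selection by exact leave-one-out RMSECV).
* **Validation** — leave-one-out RMSECV, the reference standard deviation
  STDDEV_REF, the efficiency ratio ζ = STDDEV_REF / RMSE, and deterministic
  Kennard–Stone max–min test-set selection (default 25 test / 60 training).
* **A synthetic library generator** — spectra whose amide I/II composition
  follows the structure fractions, with class-dependent exchange kinetics
  (Others ≫ helix > sheet), amide I downshift on deuteration, amide II
  decay / amide II′ growth, side-chain bands, baseline drift and noise —
  plus matched reference profiles, so the whole pipeline runs and is
  tested without any measured spectra.

## The statistic at the core

For each structure class s with reference contents *y* (% of residues)
and model predictions *ŷ₋ᵢ* from leave-one-out refits,

```
RMSECV = sqrt( mean_i ( y_i − ŷ_{−i} )² )
ζ      = STDDEV_REF / RMSECV ,   STDDEV_REF = sd(y)
```

ζ = 1 means the spectra add nothing over guessing the set mean; the
reference workflow reaches ζ ≈ 3 for helix after a 15-minute deuteration
pulse. Model comparison across timepoints (t0, t15, t105, t24h, and the
concatenated global model) is the package's central experiment.

## Worked example

```r
library(ftirhdx)

## a synthetic 85-protein library at four HDX timepoints
lib <- generate_library(generator_config(n = 85, seed = 1))

## preprocessing and peak readout for one protein
pre <- lapply(lib$series[["P001"]]$spectra,
              function(s) vector_normalize(baseline_correct(s)))
round(find_peak_position(pre$t0,  1655), 1)   # 1649.6 cm-1
round(find_peak_position(pre$t15, 1655), 1)   # 1641.2 cm-1  (downshift on HDX)

## the full experiment: PLS at t0 vs t15 for three structures
res <- run_experiment(experiment_config(
  generator  = generator_config(n = 85, seed = 1),
  structures = c("H", "Others", "E"),
  models     = "PLS",
  conditions = c("t0", "t15"),
  outdir     = "ftirhdx_run"
))
res$loo
```

which prints (rounded):

```
 model condition structure rmse n_var stddev_ref zeta
   PLS        t0         H 3.30    10       8.85 2.68
   PLS       t15         H 2.03     7       8.85 4.35
   PLS        t0    Others 4.11    10      11.45 2.79
   PLS       t15    Others 1.96    10      11.45 5.86
   PLS        t0         E 0.95    10       8.52 9.00
   PLS       t15         E 1.50    10       8.52 5.66
```

Read the table row-pairs per structure: helix RMSECV improves from 3.30%
to 2.03% and Others from 4.11% to 1.96% after the 15-minute pulse, while
sheet degrades from 0.95% to 1.50% — the deuteration trade-off the
pipeline is built to expose. (`n_var` is the latent-variable count chosen
by leave-one-out scan; absolute errors on synthetic libraries are not
comparable to measured-spectra values.) `run_experiment()` also writes the
generated spectra, reference fractions, a Kennard–Stone test-set table and
the ASLR wavenumber rankings to `outdir`.

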