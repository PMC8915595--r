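# iamdist

Biomimetic chromatography measures how strongly a drug molecule binds the two
materials that dominate its distribution in the body: phospholipid membranes
(via immobilized artificial membrane, IAM, HPLC columns carrying a bonded
phosphatidylcholine monolayer) and human serum albumin (via chemically bonded
HSA columns). `iamdist` implements the desk side of that workflow for
physicochemists and DMPK scientists:

* **Calibration.** Gradient retention times are mapped to the chromatographic
  hydrophobicity index, CHI(IAM) — the acetonitrile volume-% at which the
  isocratic retention factor `k = (tR − t0)/t0` equals 1 — through an ordinary
  least-squares line `CHI = a + b·tR` fitted to a standard mixture
  (`chi_calibration()`, `isocratic_chi()`, `retention_factor()`).
* **Conversion.** CHI(IAM) is converted to the octanol/water-comparable
  lipophilicity scale, log K(IAM), by a strictly monotone exponential-offset
  fit `log K = a·e^{b·CHI} + c` to the standards' paired values
  (`chi_logk_conversion()`).
* **Distribution models.** Linear models in log K(IAM) and log K(HSA)
  estimate human in vivo distribution properties, chiefly the steady-state
  volume of distribution

      log Vdss = c0 + c1·log K(IAM) − c2·log K(HSA)

  (binding to tissue phospholipid raises Vdss, binding to plasma albumin
  lowers it), plus bounded logistic-link models for % brain tissue binding,
  tissue unbound fraction and drug efficiency, and
  `log Vdu = log Vdss − log10(fu)` (`estimate_log_vdss()`,
  `fit_vdss_model()`, `recover_vdss_model()`, `estimate_percent_btb()`,
  `estimate_fu_tissue()`, `estimate_drug_efficiency()`, `estimate_log_vdu()`).
* **Column QC.** System-suitability testing against reference CHI values
  (5-unit pass rule) and paired-column comparison with a 2×SEE outlier rule
  (`run_system_suitability()`, `compare_columns()`,
  `batch_reproducibility()`).
* **Synthetic data.** Seeded generators that reproduce the statistical
  structure the analysis assumes, for end-to-end validation
  (`simulation_config()`, `generate_compound_set()`).

The printed study tables (calibration standards, 72 marketed drugs with
clinical log Vdss, suitability references, per-batch CHI and log K(HSA)
measurements, tabulated model estimates) ship as CSV fixtures
(`load_fixture()`, `study_data()`). One fixture column is demonstrably
misaligned in print; `realign_hsa()` documents and repairs it (see the
methods vignette).

## Worked example

```r
library(iamdist)

# 1. calibrate a run from the shipped standards and convert a retention time
cal <- chi_calibration(load_fixture("table1"))
print(cal)
#> Gradient retention time -> CHI(IAM) calibration
#>   CHI = -21.803 + 16.246 * tR   (n = 9)
#>   r^2 = 0.9988, SEE = 0.608 CHI units, max |resid| = 0.99
predict(cal, 1.58)          # paracetamol, 1.58 min
#> [1] 3.866

# 2. convert CHI to the log K(IAM) lipophilicity scale
conv <- default_conversion()
print(conv)
#> CHI(IAM) -> log K(IAM) conversion
#>   form: log K = 0.4484 * exp(0.04566 * CHI) + 0.6886
#>   calibration range: [2.9, 49.4] CHI; max fit error 0.0085 log units

# 3. estimate log Vdss for a compound measured on a new-era column
profile <- data.frame(chi_iam = 0.99, logk_hsa = 1.44)  # acetazolamide
est <- estimate_distribution(cbind(profile, acid_base_class = "neutral"))
est$log_vdss
#> [1] -0.4671  (clinical value: -0.46 log L/kg)

# 4. column QC: compare old-column reference CHI with a new batch
tab <- load_fixture("table4")
cmp <- compare_columns(tab$name, tab$chi_iam_ref, tab$chi_iam_r20511,
                       exclude = c("Felbamate", "Sulphadimidine"))
print(cmp)
#> Paired-column CHI comparison (n = 70)
#>   chi_b = 3.799 + 0.821 * chi_a;  r = 0.968 (r^2 = 0.938)
#>   SEE = 3.52 CHI units (2xSEE outlier threshold 7.04); max |diff| = 16.31
#>   outliers: Fenoprofen, Indomethacin, Pindolol, Procainamide, Sulpiride
```

The flagged outliers are small polar bases that retain less on the
better-endcapped new-generation IAM phase; the comparison slope (0.82) and
threshold reproduce the study-level QC statistics.

A shell front end with pipeline exit codes (0 pass / 1 QC fail / 2 error)
lives at `inst/exec/iamdist`:

```sh
Rscript inst/exec/iamdist suitability --input measured.csv
```

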