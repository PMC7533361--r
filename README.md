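# glutenPRM

Desk-side toolkit for targeted parallel-reaction-monitoring (PRM) mass
spectrometry of immunogenic gluten peptides released during simulated
(INFOGEST-style) gastrointestinal digestion of food. It is written for
proteomics and food-science labs that run (or plan) the six-peptide
α-gliadin marker panel — P1–P6, including the canonical 33mer — and want
every non-instrument step to be scripted, validated and reproducible.

## What it computes

* **In-silico MS/MS** — monoisotopic/average peptide masses, precursor m/z
  `(M + zH⁺)/z`, and b/y/a fragment ions (b = prefix + H⁺, y = suffix +
  H₂O + H⁺, a = b − CO), including a single stable-isotope label
  (the ¹³C₉,¹⁵N-Phe internal standard P1H); percent proline and overlapping
  DQ2.5 epitope-core motif counts.
* **PRM inclusion lists** — scheduled transitions (precursor, fragments,
  RT ± 0.5 min windows), fragment selection from observed spectra (top 4–5
  direct-sequence ions by intensity), CSV round trips, and a validator that
  cross-checks every configured m/z against recomputation and *reports*
  discrepancies rather than fixing them.
* **Digestion planning** — simulated fluid recipes, the 1:1 v/w phase
  volume schedule with gastric sampling-loss carry-over, enzyme dosing by
  activity, and TFA quench volumes.
* **Synthetic chromatograms** — Gaussian (optionally exponentially
  modified) extracted-ion traces with areas on the shipped calibration
  scale, seeded noise and full ground-truth manifests.
* **Quantification** — trapezoidal XIC integration (fragments summed),
  unweighted OLS calibration, ICH residual-based limits
  (`S = √(RSS/(n−2))`, `LOQ = 10·S/|slope|`, `LOD = 3.3·S/|slope|`, plus a
  blank rule `mean + k·sd`), back-calculation with SPE dilution-factor
  (default 2.1) and internal-standard recovery correction, matrix-effect
  percentages and day-to-day CV reports.

## Worked example

```r
library(glutenPRM)

p1 <- default_peptides()$P1
precursor_mz(p1, 2)          # 784.927
fragment_mz(p1, "y", 2)      # 279.134
fragment_mz(p1, "b", 4)      # 483.293

# simulate a calibration series on the shipped response scale, quantify
models <- default_peak_models(noise_sd = 2e4)["P1"]
cal  <- calibration_series(models, replicates = 3, seed = 42)
ab   <- integrate_samples(cal$chromatograms)
m    <- merge(cal$manifest, ab, by = "sample_id")
cu   <- fit_calibration(m$level, m$abundance)
cu
#> <calibration> y = 3.40544e+06 x +404141   r = 1.0000  RSS = 4.656e+07  n = 15  (0.5-10 ug/mL)

unk <- simulate_trace(models$P1, 4, seed = 7)   # a 4 ug/mL "digesta" sample
back_calculate(integrate_xic(unk), cu, dilution_factor = 2.1, recovery = 0.9)
#>   abundance      raw    final clipped
#> 1  14029150 4.000948 9.335546   FALSE
```

The fitted slope/intercept land on the generator's true response
(3,405,436 and ~404,809), the raw concentration recovers the simulated
4 µg/mL, and `final = raw × 2.1 / 0.9` applies the SPE dilution and
internal-standard recovery corrections.

```r
volume_schedule(2.5)
#> INFOGEST digestion plan (bolus mode) for 2.5 g dry sample
#>   rehydration water :    8.000 mL
#>   oral fluid        :    2.500 mL
#>   gastric fluid     :    5.000 mL
#>   intestinal fluid  :   10.000 mL
#>   TFA quench        :     8.40 uL of 12% stock per 1 mL aliquot (-> 0.1%)
```

A command-line front end mirrors these operations
(`inst/cli/glutenprm validate | transitions | digestion | simulate |
quantify | lodloq | matrix-effect | replicability`).

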