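---
title: "Methods: targeted PRM quantification of immunogenic gluten peptides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: targeted PRM quantification of immunogenic gluten peptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glutenPRM)
```

## The problem

Celiac disease is triggered by proline/glutamine-rich gluten peptides that
survive gastrointestinal digestion and present HLA-DQ2.5-restricted T-cell
epitopes. Six alpha-gliadin marker peptides (P1--P6, including the canonical
33-residue "33mer") cover the immunodominant DQ2.5 glia-alpha epitopes.
glutenPRM packages the desk side of a targeted parallel-reaction-monitoring
(PRM) workflow for these peptides: everything that is arithmetic, statistics
or simulation rather than wet lab — in-silico MS/MS, inclusion lists,
digestion-experiment planning, chromatogram simulation with known ground
truth, and calibration-curve quantification with ICH detection limits.

## Mass and m/z arithmetic

Peptide masses are sums of monoisotopic residue masses plus one water;
precursors are `(M + z·H⁺)/z` with the proton (1.007276 Da) as the only
charge carrier — standard positive-mode ESI peptide work, no adducts.
Fragments follow the b/y/a backbone series: b = N-terminal prefix + H⁺,
y = C-terminal suffix + H₂O + H⁺, a = b − CO. A single stable-isotope label
(the ¹³C₉,¹⁵N-phenylalanine of the internal standard P1H, residue 6)
contributes its mass delta to exactly the fragments containing the labeled
residue. All computation is full double precision; m/z is conventionally
*reported* at three decimals.

Two deliberate choices:

* **Monoisotopic everywhere, average only for reconciliation.** The
  transition list's printed precursors are monoisotopic (they recompute to
  within ±0.005 Th), while the "molecular weight (kDa)" column of the same
  table matches the *average* mass at 3-decimal kDa rounding for the longer
  peptides. Both masses are exposed; only monoisotopic feeds m/z.
* **The P1H label-delta override.** The label footnote (¹³C₉,¹⁵N) implies
  +10.027 Da, but the printed P1H precursor implies +6.000 Da and the
  printed labeled b11 implies +6.011 Da. The shipped config overrides the
  composition delta with **+6.006 Da**, the single value consistent with
  *both* printed P1H m/z within the validator tolerances; the
  composition-derived delta is used whenever no override is present, and the
  validator flags the disagreement rather than hiding it.

## Epitope motif counting

Epitope multiplicities (e.g. three copies of DQ2.5-glia-α2 in the 33mer)
require **overlapping** exact matching: the repeats shift by less than a
full motif length. Cores are editable config, not hard-coded; the shipped
file carries the native (non-deamidated) 9-mers PFPQPQLPY, PYPQPQLPY and
PQPQLPYPQ, which reproduce the full peptide-by-epitope multiplicity table.
The canonical glia-α3 register begins with a phenylalanine that P6 does not
contain, so the shipped α3 core is the native 9-mer actually present in P6
(RPQQPYPQP); this is a documented stand-in, flagged in the config file.
Deamidation (Q→E) is not modelled: the method quantifies native peptides.

## The transition list and its validator

The shipped transition list stores the *printed* method values verbatim —
including five entries that do not recompute from the sequences.
`validate_config()` recomputes every precursor (tolerance 0.005 Th) and
every parseable fragment label (tolerance 0.01 Th, matching the default
spectrum-match tolerance) and reports discrepancies instead of correcting
them. On the shipped config it finds, deterministically:

* the P3/P4 precursor swap (each printed value matches the *other*
  peptide's sequence almost exactly);
* the P1H label override vs. its composition footnote;
* P1 "b6" (and its P1H twin), which match no b/y/a ion at all;
* P6 "b9", which is exactly b8; and P2 "b9", P3 "b7" and P5 "b21", which
  are 0.013--0.037 Th off any assignable ion.

Fragment labels are stored as free text precisely so these
printed-but-unassignable entries survive export/import round trips.

## Digestion planning

The INFOGEST-derived schedule is linear in the dry mass *m*: rehydration
water `4m/1.25` mL, oral fluid `m` mL (1:1 v/w with the dry mass), gastric
fluid 1:1 with the bread + oral bolus, intestinal fluid 1:1 with the total
after the gastric addition, minus any gastric-phase sampling losses. The
phrase "1:1 v/w with the total solution" is ambiguous; a literal reading
(rehydration water included) gives 6.5 mL of gastric fluid for 1.25 g of
bread, contradicting the protocol's own worked example of 2.5 mL. The
default `"bolus"` mode therefore follows the worked examples; the literal
reading stays available as `mode = "literal"`. Densities are 1 g/mL, as in
the protocol's own arithmetic. TFA quenching solves the exact mixing
balance `v = V·t/(s−t)` (8.40 µL of 12% stock per 1 mL aliquot for 0.1%
final). Working fluids allocate `V/1.25` of the 1.25× electrolyte stock,
CaCl₂ from a 300 mmol/L stock, enzyme solution dosed by activity
(α-amylase 75, pepsin 2000, chymotrypsin 25 + trypsin 100 U/mL working
strength) and water to volume; components sum exactly to the requested
volume. Enzyme dosing is in activity units only — unit↔mg conversion
depends on the activity assay and is left to the user.

## The simulator: a stated world

`simulate_trace()` draws a Gaussian elution peak (EMG optional, for
integration-robustness tests) whose *area* follows the linear response
`area = slope·c + intercept`, plus a constant baseline and seeded white
intensity noise. Defaults are the conditions of the real method, chosen
once:

| parameter | default | why |
|---|---|---|
| slope/intercept | the shipped per-peptide calibration values (e.g. P1: 3,405,436 and 404,809 counts·min per µg/mL) | simulated abundances live on the method's scale |
| retention times | the scheduled RTs (3.48--7.29 min) | matches the inclusion list |
| peak σ | 0.05 min | a ~0.2 min-wide UPLC peptide peak |
| sampling interval | 0.01 min | σ ≥ 4·dt keeps trapezoidal area error < 0.5% (in practice ≪ 0.1%) |
| noise sd | 5 × 10⁴ counts | ≈ 0.2% of a mid-curve peak apex; visible but not dominant |
| calibration levels | 0.5, 1, 2, 5, 10 µg/mL | the external standard curve |
| limit-study levels | 10 … 0.01 µg/mL, ≥ 5 injections | the LOD/LOQ dilution design |
| matrix fractions | 1.0, 0.75, 0.5, 0.2; spike 3 µg/mL | the matrix-effect workflow |
| day-to-day CV | 5% between days, 2% within | mid-range of the reported 3.8--8.6% |

All randomness flows from one explicit seed; the global RNG stream is left
untouched. What the simulator does **not** emulate: peak-shape drift,
co-eluting interferences, isotope envelopes, detector saturation, or
retention-time shifts — a green round-trip test establishes that the
*arithmetic* chain is correct, not that the method works on a real
instrument.

One emergent property worth knowing: two shipped intercepts (P4, P6) are
negative, so below ~0.6 µg/mL their simulated response line predicts
negative area. Areas are physically non-negative, and integration floors at
zero, so the lowest standards of those peptides are zero-censored; exact
round-trip recovery holds for peptides with positive intercepts (P1, P2,
P3, P5) and, for the others, above the censoring point.

## Quantification and the ICH limits

Abundance is the trapezoidal integral of the extracted ion current over the
scheduled window, **summed** (not averaged) across a peptide's fragment
traces, floored at zero; baseline handling defaults to none (the simulator
is baseline-true) with an optional linear chord subtraction. Calibration is
unweighted ordinary least squares (1/x and 1/x² available but off by
default, matching the plain least-sum-of-squares curves shipped).

The residual-based limits use the regression residual standard deviation
`S = sqrt(RSS/(n−2))` — the printed formula's "γ − ŷ" wording is ambiguous,
but "standard deviation of the residuals" in the cited ICH method denotes
exactly this quantity — with `LOQ = 10·S/|slope|`, `LOD = 3.3·S/|slope|`
(ratio 10/3.3 by construction). The blank-based alternative is
`mean + k·sd` with `k = 10` as shipped (3.3 selectable). The published
LOD/LOQ table is *not* a computational target: it derives from instrument
data that is not printed, so the package's acceptance is property-based
(oracle agreement, the exact ratio, linear scaling of LOQ with injected
noise, and simulated round-trip recovery).

Back-calculation is `raw = (A − intercept)/slope`, then
`final = raw × DF / recovery`: DF defaults to 2.1 (200 µL loaded onto the
SPE cartridge, 2 × 210 µL eluted) and recovery is the internal-standard
abundance ratio observed/expected. Division by recovery (rather than
subtracting a suppression percentage) is the standard internal-standard
ratio correction and is the documented interpretation. Negative raw
concentrations are reported as 0 with a flag so downstream summaries stay
physical. The sample (n−1) standard deviation is used for CV and blank
statistics — day-to-day designs are small-n. Replicability passes at
CV < 10% across day means.

## Pipeline and reproducibility

`run_pipeline()` integrates everything over the scheduled windows, fits one
pooled calibration per peptide per batch (per-bracket drift correction is a
deliberate non-feature of the default), derives LOD/LOQ, and quantifies
unknowns; the report bundle carries the seed and an FNV-1a config hash and
contains no timestamps, so identical runs write identical bytes. Interleaved
standards are pooled — the shipped design injects the standard curve every
10--15 samples into one batch.

## Known limitations

* No vendor raw-file or mzML ingestion: chromatograms enter as the
  delimited long format (`sample_id, transition_id, time_min, intensity`).
* No peak deconvolution; co-eluting interference lands in the area.
* Single-label support only; no PTMs, neutral losses, or isotope envelopes.
* The epitope α3 core is a documented stand-in (see above).
* Collision-energy and instrument-method generation are out of scope; the
  gradient and instrument tables ship as acquisition metadata only.
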