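# oisi — analysis of sensory-evoked optical intrinsic signals

Optical intrinsic signal (OIS) imaging records slow changes in the light
reflected from (or transmitted through) cortical tissue during sensory
stimulation. The signal mixes two processes: the **hemodynamic response**
(oxy-/deoxy-hemoglobin changes, HbO/HbR) and **tissue light scattering**
(LS, activity-dependent cellular swelling). In developing cortex these are
temporally separated — an early scattering phase during the stimulation
train, a hemodynamic phase delayed by tens of seconds — while in mature
cortex they overlap. `oisi` is for experimenters who need to turn raw
multispectral frame stacks into that decomposition, and to validate every
step against a forward simulator with known ground truth.

The core model is the modified Beer-Lambert law with a scattering
pseudo-chromophore: for each illumination band λ,

    OIS_λ(t) ≈ (Δ[HbO]·ε̄_HbO,λ + Δ[HbR]·ε̄_HbR,λ + μs′·ΔS) · 2·d_IV

with extinction coefficients ε̄ band-averaged over each diode's emission
spectrum, reduced scattering coefficient μs′, and optical pathlength equal
to twice the cortical layer-4 depth d_IV (0.35 mm neonatal, 0.75 mm adult
rat). With ≥ 3 bands the system is inverted per timepoint.

The package covers:

- **Simulation** — gamma-variate chromophore dynamics (`simulate_chromophores`,
  neonatal/adult presets), Beer-Lambert forward projection
  (`forward_project`), trial rendering with illumination drift and pixel
  noise (`render_trials`), LFP traces (`simulate_lfp`).
- **Preprocessing** — Gaussian spatial filtering (`spatial_filter`),
  reference-region illumination correction (`illumination_correct`),
  trial averaging (`average_trials`).
- **Mapping** — OIS activation maps (`compute_ois_map`), deterministic
  active-region detection (`detect_active_region`), ROI time-course
  extraction with reflectance/transmission polarity handling
  (`extract_timecourse`).
- **Decomposition** — band-averaged coefficients
  (`band_average_extinction`), system assembly (`mbll_model`), per-timepoint
  inversion (`mbll_decompose`).
- **Metrics & statistics** — 95-percentile peak amplitude, first-crossing
  peak position, half-recovery time, average LFP, optimal-rate ranking,
  exact one-tailed Mann-Whitney U and sign tests.
- **Orchestration** — `run_config()` / `validate_config()` /
  `run_pipeline()` with a reproducible manifest, plus a thin CLI at
  `inst/scripts/ois.R`.

## Worked example

```r
library(oisi)
run <- run_pipeline(neonatal_config(seed = 5), quiet = TRUE)
print(run)
```

```
ois_run
  detection band: GREEN, active mask 462 px
  band metrics:
  band amplitude_percent peak_position_s
 GREEN         0.7736249            25.4
   RED         0.2460119             8.0
    IR         0.1788237             7.0
  chromophore metrics (kernel fit):
 component   amplitude peak_time_s half_recovery_s
         S 0.002991296    10.11195        24.85546
       HbT 1.489767657    30.06628        21.74540
```

Reading this: the pipeline simulated 12 noisy trials per band of a neonatal
scene, preprocessed them, detected the active barrel region (462 px), and
extracted per-band time courses. The GREEN band (blood-volume sensitive)
peaks 25.4 s after stimulus onset — the delayed hyperemia — while RED and IR
(oximetry/scattering sensitive) peak at 7–8 s, inside the 10 s train: the
early scattering phase. Decomposition recovers the injected dynamics: the
scattering component peaks 10.1 s after onset and falls to half its peak
24.9 s later; total hemoglobin (true amplitude 1.5 uM) peaks at 30.1 s.
The adult preset (`adult_config()`) collapses both peaks inside the train.

The same run from a shell, writing maps, masks, CSVs and a manifest:

```sh
Rscript inst/scripts/ois.R demo-neonatal --out out_dir --seed 5
```

## Notes

The spectral fixtures under `inst/extdata/` (LED emission, hemoglobin
extinction, reduced scattering) are synthetic curves at literature
magnitudes, flagged as such in their filenames and headers; quantitative
use requires measured diode spectra and blood extinction tables in the same
two-column CSV format. See the vignette
(`vignettes/ois-decomposition.Rmd`) for the model, conventions, estimator
choices and limitations.
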