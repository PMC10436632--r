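# diaflow

Quantitative tracking of diaphragm deformation in B-mode ultrasound
cine loops.

The diaphragm appears in ultrasound as a bright curved band over a
darker speckled background, and its motion over 3–5 breathing cycles
carries clinically useful information (excursion, contraction
pattern). `diaflow` turns such a loop — a multi-frame DICOM file or a
directory of grayscale images — into motion curves: inter-frame and
cumulative horizontal/vertical displacement of the band, its global
strain, the respiratory period, and per-cycle peak-to-peak values. It
is aimed at researchers in respiratory imaging who need an open,
scriptable alternative to closed speckle-tracking software.

## Method in brief

* **Segmentation (frame 1):** 3×3 mean filter, Otsu threshold
  (`f ≥ T → 255, else 0`, manual override possible), largest
  8-connected bright component = the diaphragm band.
* **Seeding:** 300 random points in the band, cleaned by DBSCAN
  (largest density cluster kept).
* **Tracking:** pyramidal Lucas-Kanade optical flow per point,

  ```
  [u v]' = [ ΣIx²  ΣIxIy ; ΣIxIy  ΣIy² ]⁻¹ [ −ΣIxIt ; −ΣIyIt ]
  ```

  over an m×m window (default m = 15), sub-pixel positions, points
  invalidated on degeneracy or frame exit.
* **Curves:** per-frame displacement = mean point displacement;
  cumulative = running sum; the points are reduced to 15 groups along
  the band and the centroid chord-sum gives the band length `L(t)` and
  global strain `GS(t) = (L(t) − L(0))/L(0) × 100%`.
* **Cycles and drift:** size-5 moving-average smoothing, peak/trough
  detection, period `T = 2·|adjacent peak − trough|·Δt` (median over
  pairs), and drift correction
  `S_corr(t) = S(t) − (S(T)/T)·t` anchored at the end of the first
  cycle, so curves return to zero at cycle boundaries.

A synthetic speckle phantom with exact ground-truth motion and strain
(`phantom_spec()` / `render_phantom()`) ships with the package, so the
whole chain is testable without patient data. See the vignette in
`vignettes/diaphragm-tracking.Rmd` for the full model description,
parameter meanings, and validation design.

## Worked example

```r
library(diaflow)

# a 4-cycle breathing phantom (2.5 s period, 12.5 fps) with a slow
# vertical drift of 0.05 px/frame
ph  <- render_phantom(phantom_spec(drift_rate = 0.05, seed = 42))
res <- run_pipeline(ph$seq, config = list(seed = 42), output_dir = "out")
```

which logs

```
loaded 126 frames (0.08 s/frame) from phantom(seed=42)
segmented diaphragm: threshold 125.0, component of 1315 px
seeded 300 points, kept 300 after DBSCAN
tracked 126 frames; 300 points survive to the last frame
respiratory period 2.480 s (4 peaks, 3 troughs)
```

and `res$report` summarizes the recovered kinematics:

```
period_s: 2.480                      # programmed: 2.5 s
cum_h pkpk: 5.76 +/- 0.01 px         # programmed horizontal excursion: 6 px
cum_v pkpk: 2.78 +/- 0.01 px         # programmed vertical excursion: 3 px
gs pkpk: 9.87 +/- 0.02 %             # programmed strain amplitude: 10 %
```

The period is recovered to within one frame interval, the excursions
to a few percent (the size-5 smoothing slightly attenuates sharp
cycle extremes), and the strain peak-to-peak to ~0.1 strain points.
`out/curves.csv` holds the drift-corrected curves per frame
(`time_s, interframe_h_px, interframe_v_px, cumulative_h_px,
cumulative_v_px, gs_percent`) and `out/report.json` the full run
report (all parameters, per-stage point counts, period, peak-to-peak
summaries).

Clinical loops run the same way:

```r
res <- run_pipeline("patient_loop.dcm", config = list(seed = 1),
                    output_dir = "out")
```

or from the shell via the thin CLI wrapper:

```sh
Rscript inst/cli/diaflow.R run --input patient_loop.dcm --out out/ --seed 1
Rscript inst/cli/diaflow.R phantom --out phantom_dir/ --seed 7
```

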