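# dcefit

Pharmacokinetic analysis of T1-weighted dynamic contrast-enhanced MRI
(DCE-MRI) in R, aimed at preclinical (small-animal) studies. After a bolus
of a gadolinium contrast agent, tissue signal enhancement encodes the
first-order exchange of tracer between blood plasma and the
extravascular-extracellular space (EES):

    dCe/dt = (Ktrans/ve) (Cp − Ce),      Ct = vp·Cp + ve·Ce

with transfer constant `Ktrans` (min⁻¹), EES fraction `ve`, plasma fraction
`vp`, and washout rate `kep = Ktrans/ve`. `dcefit` fits this system
pixel-wise over a region of interest, in five standard formulations:

| model       | fitted parameters       | needs                         |
|-------------|-------------------------|-------------------------------|
| `tofts`     | Ktrans, ve              | AIF + T1 calibration          |
| `ext_tofts` | Ktrans, ve, vp          | AIF + T1 calibration          |
| `hoffmann`  | A_H, kep, kel           | signal only                   |
| `larsson`   | kep, initial slope      | AIF shape                     |
| `rr`        | Ktrans, ve              | reference-region curve        |

plus model-free parameters (RCE, IAUC, TTM). Around the fitting core it
provides: spin-echo and spoiled-gradient-echo signal equations with their
exact inversions to concentration, variable-TR T10 mapping, coarse pixel
binning (2×2 … 10×10), bounded Levenberg–Marquardt estimation with
standard errors and convergence flags, parametric-map export in three text
layouts, raw-binary and minimal DICOM I/O, a YAML-configured batch CLI, and
a self-contained digital phantom generator with known ground truth for
validating the whole pipeline.

## Worked example

Generate the standard single-compartment validation phantom (a 50×60-pixel
tissue region of 10×10 patches sweeping Ktrans × ve, SPGR 30°/TR 5 ms,
0.5 s frames, injection at 60 s) with 20% baseline Gaussian noise, and fit
the Tofts model at the 10×10 patch resolution:

```r
library(dcefit)

ph  <- generate_phantom(default_tofts_spec(noise_sigma_fraction = 0.2, seed = 42))
roi <- ph$tissue_roi
roi$bin_factor <- 10L
map <- fit_roi(ph$series, roi, "tofts", relax = ph$relax, aif = ph$spec$aif)
summary(map)
#> tofts map on 5 x 6 grid (10x10 binning): 30 fitted, 30 converged, 0 clamped
#>  parameter      mean        sd  n
#>     Ktrans 0.1229318 0.1292432 30
#>         ve 0.1716063 0.1774957 30
```

The per-parameter means/sds run over all 30 patches (true grid means are
0.1217 and 0.172, so the noisy maps sit on top of the truth). A single
curve — here the patch mean of the `Ktrans = 0.1`, `ve = 0.2` patch —
goes through the same calibration and fit explicitly:

```r
acq   <- ph$series$acq
tmod  <- ph$series$frame_times - 60          # seconds since injection
curve <- apply(ph$series$data[31:40, 31:40, 1, , drop = FALSE], 4, mean)
ct    <- concentration_from_spgr(curve, mean(curve[1:120]), acq, ph$relax)
dce_fit(tmod, as.numeric(ct), "tofts", aif = ph$spec$aif)
#> tofts model fit (1200 frames)
#>   Ktrans  0.10015 +/- 0.00024
#>   ve      0.19997 +/- 0.00018
#>   kep     0.50085 (derived)
#>   residual norm 0.162229 | converged after 3 iterations
```

`0.10015 ± 0.00024 min⁻¹` against a true 0.1: averaging the 10×10 patch
reduces the 20% pixel noise to 2%, and the fit recovers the generating
parameters within a fraction of a percent. The ± values are 1-sigma
standard errors from the scaled `(JᵀJ)⁻¹` at the solution.

The same analyses run from a shell via the bundled CLI
(`inst/cli/dcetool`): `phantom`, `analyze`, `t10` and `export`
subcommands; see `?cli_main`.

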