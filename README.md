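# gaitIMU

Running gait analysis from a **single foot-mounted IMU** (tri-axial
accelerometer + gyroscope). For biomechanists and wearable-sensor engineers
who need per-stride spatiotemporal and kinetic parameters — stride velocity,
stride length, stride frequency, stride/contact/swing/flight times and peak
vertical ground reaction force — without an optical motion-capture lab or
force plates.

## What it computes

The pipeline is the classic strapdown chain with a fused event detector at
its core:

1. **Orientation** — Mahony proportional–integral complementary filter:
   the error `e = â_s × ĝ_s` between measured and expected gravity
   directions corrects the gyro rates via `ω + K_p e + K_i ∫e dt`; gravity
   is then removed in the navigation frame, `a_n = C_ns' a_s − (0,0,g)'`.
2. **Events** — strides are segmented at mid-swing (MSW) peaks of the
   sagittal angular velocity ω_x above an adaptive threshold
   `mean + k_σ·SD`. Initial and terminal contact (IC, TC) are localized
   either by the conventional angular-velocity rules (AVGS: negative peak /
   toe-off dip) or by the fused scheme (MFD-GED) that takes a weighted mean
   (0.7/0.3) of the anterior–posterior acceleration transient and the
   angular-velocity kinematic marker inside stride-adaptive windows.
   Mid-stance (MS) blends a minimum angular-velocity-energy window with a
   minimum acceleration-variance window,
   `t_MS = w·t_ω + (1−w)·t_v`, `w = σ²_a/(σ²_a + |σ²_a − σ²_prev|)`.
3. **ZUPT stride reconstruction** — `a_n` is double-integrated between
   mid-stance anchors with zero-velocity resets; the endpoint velocity
   error is redistributed linearly (`v_j − (j/n)·v_n`), and
   `SL = √(d_x² + d_y²)`.
4. **Parameters** — `ST = IC_{i+1} − IC_i`, `CT = TC_i − IC_i`,
   `SWT = ST − CT`, `FT = (SWT − CT)/2`, `SF = 120/ST`, `SV = SL/ST`, and
   the spring-mass (SLIP) peak force `F_max = (π/2)(FT/CT + 1)` body
   weights from `F(t) = (π/2) m g (FT/CT + 1) sin(πt/CT)`.

`agreement_report()` adds the validation statistics used for wearable
systems (Bland–Altman bias/LoA, Pearson r, ICC(3,1)/(3,k), MAE, paired t,
Cohen's d), and `simulate_run()` generates synthetic foot-IMU recordings
with exact ground truth for every event and parameter.

## Worked example

```r
library(gaitIMU)

sim <- simulate_run(gait_profile(n_strides = 10, seed = 42))
fit <- gait_analysis(sim$recording, method = "mfdged", mass_kg = 75)
fit
#> <gait_analysis> method=mfdged: 10 strides from 11.8 s of data
#>   SV 2.54 m/s  SL 1.90 m  ST 0.748 s  CT 0.312 s  peak vGRF 1.89 BW

summary(fit)
#> Gait analysis (mfdged), 10 strides (0 flagged)
#>     parameter      mean      sd
#>            sv   2.54200 0.05260
#>            sl   1.90100 0.02820
#>            sf 160.50000 2.75000
#>            st   0.74800 0.01290
#>            ct   0.31170 0.00845
#>           swt   0.43630 0.01580
#>            ft   0.06232 0.01090
#>  peak_vgrf_bw   1.88600 0.06250
```

The simulated runner covers 1.90 m per 0.748 s stride (2.54 m/s) with
312 ms of ground contact and a modelled peak force of 1.89 body weights —
ordinary numbers for comfortable-speed overground running. Comparing both
detectors against the simulator's ground truth:

```r
compare_methods(sim$recording, sim$truth, mass_kg = 75)
#> <gait_comparison> bias (ref - est) by parameter:
#>   parameter         MFD-GED         AVGS p (paired)
#>   sv           0.0349+/-0.0175 0.0340+/-0.0118      0.789
#>   sl           0.0264+/-0.0117 0.0255+/-0.0118     0.0394
#>   st           0.0000+/-0.0012 0.0000+/-0.0022      0.975
#>   ct           -0.0074+/-0.0008 -0.0138+/-0.0018   1.35e-06
#>   swt          0.0075+/-0.0012 0.0138+/-0.0017   1.78e-06
#>   ft           0.0074+/-0.0008 0.0138+/-0.0014   3.01e-08
#>   peak_vgrf_bw 0.0460+/-0.0035 0.0835+/-0.0079   4.16e-08
```

Spatial parameters (SV, SL, ST) agree closely for both methods; the fused
detector roughly halves the contact-time bias (−7.4 vs −13.8 ms) and the
derived swing/flight/peak-force biases, with the paired test confirming the
difference — the pattern is starkest on forefoot-strike data
(`gait_profile(strike_pattern = "forefoot")`), where angular-velocity-only
detection triggers tens of milliseconds early.

A thin CLI wraps the same functions
(`Rscript inst/cli/gait-imu.R simulate|analyze|compare|validate ...`),
writing CSV/JSON outputs; see the script header for flags.

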