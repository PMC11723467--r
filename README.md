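# lamigrind

Cutter-tip state estimation for robotic laminar bone grinding, from a
pre-operative CT volume and an intra-operative milling force/torque
signal.

In laminectomy-style surgery a ball-end cutter thins the vertebral lamina
layer by layer near the spinal cord. Navigation systems track the tool
holder, not the cutting tip, so the tip position is uncertain exactly
where sub-millimetre margins matter. `lamigrind` implements a
template-matching estimator for surgical-robotics and bone-machining
researchers: it converts the planned milling paths over a CT volume into
a bank of predicted four-channel force sequences, matches tumbling-window
segments of the measured signal against that bank, and robustly refines
the result into path fits and workspace-offset estimates. Everything is
exercisable on built-in synthetic CT phantoms — no patient data needed.

## The model in brief

Each engaged micro-edge of the ball-end cutter (radius *R*, helix angle
β<sub>G</sub>, edge range θ<sub>m</sub> ∈ [0, arccos(h/R)]) contributes
shear and ploughing forces weighted by the normalized CT gray λ at its
position:

    dF_r = λ^μ (K_rc t_n db + K_re ds)
    dF_a = λ^μ (K_ac t_n db + K_ae ds)
    dF_t = λ^μ (K_tc t_n db + K_te ds)

with chip width db = R dθ<sub>m</sub>, edge length
ds = R √(1 + cos⁴θ<sub>m</sub> tan²β<sub>G</sub>) dθ<sub>m</sub>, chip
thickness t<sub>n</sub> the radial projection of the feed per tooth
60 v<sub>d</sub>/(nN), and λ a saturating linear ramp of the voxel gray
between m_min and m_max. Summing rotated micro-forces over the
cutter–workpiece engagement (a constructive-solid test against the swept
volumes of all completed paths) yields the instantaneous wrench
(F<sub>x</sub>, F<sub>y</sub>, F<sub>z</sub>, M<sub>z</sub>).

The measured signal is segmented into windows of *ns* samples (physical
length l = v_d ns / f_s); each window is matched against every grid's
predicted sequence by the dynamic-time-warping distance

    C(i,j) = |a_i − b_j| + min{ C(i−1,j), C(i,j−1), C(i−1,j−1) }

summed over channels (a Pearson-correlation baseline is included). The
best-matching grid's landmark is the raw tip estimate. RANSAC then fits
a 3-D line to each executed path's matches and a second RANSAC stage
estimates the workspace offsets (Δn_r, Δn_l) along the step and depth
axes from the fitted-vs-planned line positions.

## Worked example

Closed loop on the stepped-gradient phantom (10 gray steps, 0–1400,
along the feed direction; 3 layers × 4 paths):

```r
library(lamigrind)
vol  <- make_step_phantom(c(12, 12, 6), 0.25)
plan <- milling_plan(n_layers = 3, n_paths = 4, path_length = 8,
                     origin = c(2, 1.8, 6))
spec <- cutter_spec()
check_phase_condition(plan$feed, spec$flutes, plan$spin, 0.25)
#> $ratio 0.0375   $pass TRUE
bank <- predict_bank(vol, plan, spec)
#> <prediction_bank> 252 grid sequences (ns = 15, 4 channels) over 3 layers x 4 paths
run   <- simulate_run(vol, plan, spec, noise_sigma = c(0, 0), phase = 0, seed = 1)
track <- estimate_track(run$signal, bank, plan, method = "dtw")
mean(track$score < 1e-9)
#> [1] 1
```

Every one of the 252 windows attains DTW distance zero — the matcher is
exact. (Strict index identity is 0.508 on this phantom because it is
homogeneous across paths and lower layers, so whole paths share
bit-identical sequences and tie; see the vignette.)

Full pipeline on a lamina phantom with an injected rigid deviation and a
0.2 mm/s sinusoidal feed disturbance:

```r
st   <- study_setup("feed_sweep", phantom_seed = 7)
bank <- predict_bank(st$vol, st$plan, st$spec, st$coeffs, st$norm)
set.seed(11)
dev <- random_pose_deviation(st$rot_max, st$trans_max)
true_deviation_offsets(st$plan, st$spec, dev)
#>    dnr    dnl
#> -0.445  0.466
run <- simulate_run(st$vol, st$plan, st$spec, st$coeffs, st$norm,
                    deviation = dev, feed = feed_disturbance(0.2, 1, NULL),
                    noise_sigma = st$noise_sigma)
pr <- run_pipeline(run, bank, st$plan, st$spec, n2 = st$n2)
#> dtw      mean err raw 3.408 mm | refined 0.704 mm | dnr err 0.516 | dnl err 0.080
#> pearson  mean err raw 5.174 mm | refined 0.748 mm | dnr err 0.487 | dnl err 0.316
```

The depth offset (0.466 mm injected) is recovered to 0.08 mm; the
lateral offset (−0.445 mm) sits near half the 2.8 mm path step — the
framework's quantization-limited worst case — so its error stays at the
offset's own magnitude, and the refined per-window tip error lands at
0.70 mm (raw matching alone: 3.4 mm). Both behaviours, and why DTW beats
the Pearson baseline, are discussed in the vignette.

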