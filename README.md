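# laminarLFP

Tools for decomposing laminar (depth-resolved) local field potentials into
independent components and for studying what those components do: where
they live along the cortical depth, how their gamma oscillations ride the
theta rhythm, how single neurons lock to them, and whether they suffice to
train a recurrent network to reproduce the animal's movement.

The intended user records multi-channel LFPs with a linear probe spanning
the cortical layers during a repeated behavior (here: a hold-then-pull
lever task), or wants a fully controlled synthetic testbed for such an
analysis.

## What the package computes

**Decomposition.** The LFP is modeled as an instantaneous linear mixture of
spatially fixed sources, `LFP(t) = Σₙ Vₙ sₙ(t)`. After PCA retaining 99% of
the variance, logistic infomax ICA recovers the spatial loadings `Vₙ` and
time courses `sₙ(t)`; each component is summarized by its relative
contribution `Wₙ = ‖Vₙ‖² var(sₙ) / Σₘ ‖Vₘ‖² var(sₘ)` and its reconstructed
trace `ICₙ(t) = Vₙ(k*) sₙ(t)` at the electrode of maximal loading.

**Loading geometry.** Loadings are compared with a Sobolev-type metric,
`d = 1 − |⟨Vₙ,Vₘ⟩| / (‖Vₙ‖‖Vₘ‖)` with
`⟨Vₙ,Vₘ⟩ = ∫ VₙVₘ + κ∇Vₙ∇Vₘ + κ²∇²Vₙ∇²Vₘ dx` (κ = 150 µm²), clustered
across animals with Ward's method, and converted to current-source-density
loadings `I = −σ∇²V` (exactly zero for volume-conducted, depth-linear
components).

**Oscillations and spikes.** Morlet spectrograms and Welch PSDs;
pull-onset-triggered averages; theta-phase/gamma-amplitude coupling via the
18-bin modulation index `MI = (log N − H)/log N` with a 200-surrogate
trial-shuffling null (p < 0.01); spike–field locking via the Rayleigh test
(p < 0.05) and the phase-locking value `PLV = |Σ e^{iθ}|/N`, resolved by
behavioral state (hold: −1000…−500 ms; pull: −200…+300 ms).

**Reservoir learning.** The component traces (10 Hz low-passed, normalized
to [−1, 1]) drive a 300-neuron rate network
(`τ dx/dt = −x + g_G J^{GG} r + J^{Gz} z + J^{GI} I`, `r = [tanh x]₊`,
τ = 50 ms, g_G = 1.5, p = 0.1) whose readout is FORCE-trained on 18 lever
trials; the learned responses are classified into hold-related/movement-off,
movement-related, pre-movement, post-movement and other neurons and sorted
by circular activation time.

**Synthetic data.** `synth_session()` generates the whole testbed — four
depth sources with archetype profiles (one exactly affine), state-modulated
band-limited carriers, controllable theta-gamma coupling, phase-locked
spike trains with target PLV, lever trajectories — with ground truth
exposed, so every stage of the pipeline has a parameter-recovery test.

## Worked example

```r
library(laminarLFP)

# 1. Simulate a session: 18 lever pulls, 8 electrodes, known ground truth
session <- synth_session(n_trials = 18, fs = 500, seed = 11)
session$recording
#> <laminar_recording> 8 channels x 38324 samples @ 500 Hz (76.6 s)
#>   depths: 550..1600 um, spacing 150 um

# 2. Demix into independent components (PCA to 99% variance, infomax ICA)
dec <- run_ica(session$recording, var_frac = 0.99, seed = 3)

# 3. Match recovered loadings to the generator's sources
pars <- loading_distance_params(kappa = 150, h = session$recording$h)
mt <- match_components(dec$V, session$truth$V, pars)
data.frame(source = 1:4,
           component = match(1:4, mt$assignment),
           distance = round(mt$distances[match(1:4, mt$assignment)], 3))
#>   source component distance
#> 1      1         2    0.032
#> 2      2         1    0.003
#> 3      3         7    0.034
#> 4      4         3    0.052

# 4. The affine depth profile has zero curvature: volume conducted
apply(session$truth$V, 2, function(v) is_volume_conducted(v, h = 150)$score)
#> [1] 0.1828 0.3593 0.2661 0.0000

# 5. Theta-gamma coupling of the strongest-coupled component across trials
ic1 <- reconstruct_ic(dec, match(1, mt$assignment))
fs <- session$recording$fs
theta <- theta_reference(session$recording)
phase <- analytic_phase_amp(bandpass(theta$trace, fs, c(4, 10)))$phase
env <- analytic_phase_amp(bandpass(ic1$ic, fs, c(20, 50)))$amplitude
win <- lapply(session$events$pull_onsets, function(on)
  round((on - 1) * fs):round((on + 0.5) * fs))
surrogate_mi(lapply(win, function(i) phase[i]),
             lapply(win, function(i) env[i]), n_surr = 200, seed = 1)
#> <coupling_result> MI = 0.0256 (null 0.0078 +/- 0.0072), p = 0.00697 *, preferred phase 50 deg
```

Reading the numbers: each of the four planted sources is recovered with a
loading dissimilarity of at most 0.05 (0 is identity, 1 is orthogonality);
the fourth source's depth profile has curvature score 0 — the signature of
a volume-conducted generator — while the reversing profiles score an order
of magnitude above the 0.05 flagging threshold; and the slow-gamma envelope
of the strongest component is significantly concentrated near its planted
theta phase (45° planted, 50° bin recovered, p < 0.01 against 200
trial-shuffled surrogates).

`run_pipeline(pipeline_config(...))` chains all stages (synthesis,
decomposition, characterization, coupling, spike locking, reservoir
training, subtype classification) and writes TSV/JSON artifacts plus a
machine-readable `summary.json`; `reservoir_experiment()` runs one
reservoir input condition end to end. The methods vignette
(`vignettes/laminar-lfp-methods.Rmd`) documents the models, defaults and
numerical choices.

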