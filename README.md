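# replayssm

Switching state-space decoding of hippocampal replay trajectories.

## The problem

During sharp-wave ripples (SWRs), hippocampal place cells re-express
("replay") spatial firing sequences. The standard Bayesian decoder analyzes
these events in coarse (≥ 20 ms) time bins and tests them against a single
template — a constant-speed line — so events that are stationary, slow, or
that change speed mid-event are discarded or mislabeled. `replayssm`
implements a switching state-space model that decodes replay at 2 ms
resolution and classifies, moment by moment, *how* the represented position
moves, for neuroscientists analyzing tetrode recordings (sorted or unsorted
spikes) from track-running animals.

## The model

Let `x_k` be the latent position on a discretized track graph and
`I_k ∈ {stationary, continuous, fragmented}` a latent movement dynamic at
2 ms step `k`. The joint posterior `p(x_k, I_k | O_{1:T})` is computed by a
causal filter

```
p(x_k, I_k | O_{1:k}) ∝ p(O_k | x_k) Σ_{I_{k-1}} ∫ p(x_k | x_{k-1}, I_k, I_{k-1})
                         Pr(I_k | I_{k-1}) p(x_{k-1}, I_{k-1} | O_{1:k-1}) dx_{k-1}
```

followed by an acausal (backward) smoother, with integrals approximated by
Riemann sums over 3 cm position bins. The movement kernels are: identity
(stationary), a Gaussian random walk with 6.0 cm² variance evaluated on
track-graph distances (continuous; 95% of per-step displacements within
4.90 cm), and uniform (fragmented). The dynamics chain keeps its state with
probability 0.98 per 2 ms step (expected dwell 100 ms). Observations enter
through either a Poisson likelihood with spline-GLM place fields (sorted
spikes) or a marked-point-process likelihood with kernel joint mark
intensities `λ_i(x, m⃗) = µ_i p_i(x, m⃗)/π(x)` (clusterless decoding).
The posterior is summarized by the probability of each dynamic, a
five-category speed classification at a 0.80 threshold (stationary,
stationary-continuous mixture, continuous, fragmented-continuous mixture,
fragmented), and the 95% highest-posterior-density (HPD) region size as a
spatial-certainty measure.

## Worked example

Simulate the standard study conditions — 19 Poisson cells with Gaussian
place fields (SD 6 cm, 15 Hz peak, 10 cm spacing) on a 180 cm track, 15
encoding traversals — then decode a constructed 280 ms sequence containing
60 ms of stationary, 190 ms of continuous, and 30 ms of fragmented spiking:

```r
library(replayssm)

bank    <- place_field_bank()
run     <- simulate_encoding_run(bank, seed = 1)
track   <- linear_track(180)
grid    <- make_grid_1d(track, bin_size = 3)
linpos  <- linearized_from_1d(track, run$position$time_s,
                              run$position$linear_position,
                              speed = rep(15, nrow(run$position)))
encoder <- fit_sorted_encoder(run$spikes, linpos, grid)

event   <- make_test_sequence(bank, seed = 1)
post    <- decode_replay(event, encoder)
cls     <- classify_dynamics(dynamics_marginal(post),
                             time = post$time, dt = post$dt)
print(cls)
```

```
Replay classification: 140 bins, threshold 0.8
                      category start_s end_s duration_ms
                    stationary   0.000 0.058          58
                  unclassified   0.058 0.060           2
 fragmented-continuous-mixture   0.060 0.062           2
                    continuous   0.062 0.250         188
                    fragmented   0.250 0.280          30
```

The decoder recovers the constructed structure: a 58 ms stationary opening
(the 0.80-threshold label flips within 2 ms of the true 60 ms boundary), a
4 ms transition where the represented position jumps from the stationary
field to the sweep onset (momentarily read as a fragmented-continuous
mixture — jumps are exactly what the fragmented dynamic models), the fast
continuous trajectory, and the terminal fragmented (spatially incoherent)
period. `plot(post)` shows the posterior of position over time, and the
mean 95% HPD region size for this event is 21.2 cm
(`mean(hpd_region(position_marginal(post), widths = grid$widths)$size)`),
i.e. the model localizes the trajectory to about 7 of the 60 track bins.

The same event decodes from unsorted spikes by attaching waveform-amplitude
marks (`attach_marks`) and fitting `fit_clusterless_encoder`; `detect_swr`
finds candidate events in LFP; `standard_posterior` + `radon_fit` /
`linreg_fit` / `map_speed` provide the classical 20 ms-bin baselines.
`run_pipeline(run_config(seed = 1), "out/")` runs this demonstration end to
end and writes all artifacts (a thin CLI wrapper lives in
`inst/cli/replayssm.R`).

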