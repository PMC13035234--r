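# phosphoRNN

Prior-knowledge-constrained recurrent models of phosphoproteomic time
series.

## The problem

Time-resolved phosphoproteomics measures how thousands of phosphorylation
sites respond to a stimulus (e.g. EGF) and to drugs, but the measurements
alone cannot predict how signaling would evolve under an unseen
perturbation. phosphoRNN models the signaling network itself: a recurrent
neural network whose connectivity is fixed by a curated signed, directed
protein-interaction network (a prior-knowledge network, PKN), trained
end to end on phosphosite intensity trajectories. Because every recurrent
weight corresponds to a known interaction with a curated mode of action,
the trained model can be queried mechanistically — e.g. "inhibit PTPN11's
node and report every phosphosite that responds" — including *zero-shot*
prediction of drugs never seen in training, using only their annotated
protein targets.

The package is aimed at computational biologists with (a) a signed directed
interaction network (OmniPath-style edge list), (b) a phosphosite intensity
table over time and perturbations, (c) site-to-protein assignments, and
(d) a perturbation design with drug-target annotations.

## The model

Node activities follow a discrete recurrence with a bounded, leaky
activation `f`:

    h_{t+1} = f(W h_t + b + x),   h_0 = f(b + x)

- `W` is masked by the PKN adjacency `A` (target x source) and penalized
  for violating curated activation/inhibition signs:
  `sum(relu(-sign * W)^2)`; a power-iteration spectral-radius penalty
  `relu(rho_hat(W) - rho*)^2` keeps dynamics convergent.
- `x` encodes sustained perturbations: `+1 * w_ligand` on receptor nodes,
  a fixed strong negative `-5 * w_drug` on drug-target nodes, with
  softplus-positive trainable weights.
- Phosphosite mapping (per site `i`, its assigned node only):
  `S_i = h_site,i * E_i` (trainable d=5 embedding scaled by the node
  activity) and `yhat_i = MLP(S_i)` with one shared hidden layer
  (width 16, tanh).
- Time mapping: one trainable anchor per experimental time,
  `u = L sigmoid(u_raw)`, `anchors = u * g(alpha, norm(cumsum(softplus(delta_raw))))`
  with `g(alpha, c) = (e^{alpha c} - 1)/(e^alpha - 1)`, first anchor fixed
  to step 0; model outputs are read at fractional steps by soft indexing
  `(1 - dm) h_floor(m) + dm h_ceil(m)`.
- Objective: masked MSE over observed entries + L2 (1e-5) + sign and
  spectral penalties; Adam (lr 2e-3) with warm-restart cosine annealing,
  smooth gradient clipping and decaying gradient noise; each mini-batch is
  one sample's full time series. Backpropagation (including through time)
  is hand-derived and validated against finite differences in the tests.

A synthetic-data simulator generates datasets from a known ground-truth
model (network-driven trajectories, exponential per-node site counts,
per-site scaling, log2 transform, single-target drug inhibitions,
subsampling at t = 0,1,2,3,5,8,10,15,20,50 minutes), so every analysis
protocol is testable without external downloads.

## Worked example

```r
library(phosphoRNN)

net <- randomSignedNetwork(30, seed = 2)      # receptor "EGFR" + cascade
gt  <- sampleGroundTruth(net, noiseSd = 0, seed = 3)
gt  <- assignSites(gt, seed = 4)
ds  <- generateTimecourse(gt, drugs = names(gt@drugTargets)[1:4], seed = 5)
ds@timecourse
#> PhosphoTimeCourse: 58 sites x 10 timepoints x 5 samples; 100 % observed
#>   times (min): 0, 1, 2, 3, 5, 8, 10, 15, 20, 50

model <- phosphoModel(net, ds@assignment, ds@design,
                      times = timePoints(ds@timecourse), seed = 1)
fit <- trainModel(model, ds@timecourse, ds@design,
                  trainingConfig(epochs = 300, seed = 1))
round(tail(fit$loss, 1), 5)
#>     epoch      mse      l2 sign spectral   total
#> 300   300 0.00054 0.0011     0        0 0.00163

round(modelAnchors(fit$model), 2)
#> [1]  0.00  7.70 16.25 24.28 32.17 40.54 47.66 56.26 64.50 72.43
```

The masked MSE falls from ~0.19 to ~0.0005 (the generating process is
inside the model family, so noiseless data is fit nearly exactly); the
learned anchors map the ten sampling minutes to increasing fractional
recurrent steps. The trained model can then be queried for unseen
perturbations with `predictModel()`, and the trained edge weights
correlate strongly with the generating weights on the shared support
(`cor ~ 0.87` in this example).

Evaluation protocols mirror the benchmarks used to validate the approach:
`runDownsamplingProtocol()` (interpolation vs. number of timepoint
anchors), `runDrugScalingProtocol()` (zero-shot leave-one-drug-out vs.
training-set size), `runInterpolationProtocol()` (held-out timepoints via
linear / reference-site / one-to-one anchors), `seedStability()`,
`inferKinaseSubstrates()` and `naiveDEInference()`.

A thin command-line front end over the same functions is installed at
`inst/scripts/phosphornn` (subcommands `simulate`, `train`, `predict`,
`prune`).

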