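# mtmspike

Multi-task masked modeling (MtM) of trial-aligned, multi-region neural
spiking data, with a test-time-masking evaluation benchmark — all runnable on
a laptop CPU against a bundled synthetic multi-region spike simulator.

## The problem

Multi-region Neuropixels recordings give trial-aligned spike-count tensors
`(trial × time bin × neuron)` with a brain-region label per neuron and
behavioral covariates per trial. A single population model of such data
should solve qualitatively different prediction tasks with one set of
weights: reconstruct a held-out neuron from the rest of the population
(co-smoothing), predict future bins from past bins (forward prediction),
predict one region from the same or from other regions (intra-/inter-region
prediction), and support behavior decoding from its inferred firing rates.

`mtmspike` implements the MtM training recipe for this setting. Per training
batch, one of four masking schemes is drawn uniformly — **causal** (hide the
final bins), **neuron** (hide whole neurons), **intra-region** (hide part of
one region; only same-region neurons stay visible) and **inter-region**
(hide one region; only the other regions stay visible) — and an NDT1-style
temporal-token transformer reconstructs the hidden activity under a Poisson
emission model:

```
M ~ U(causal, neuron, intra-region, inter-region)
Z = Tokenizer(M ⊙ X);  Z_prompt = [P_M, Z]
λ = Transformer(Z_prompt);   X̂ ~ Poisson(X | λ)
```

A learnable per-scheme **prompt token** `P_M` tells the model which task it
is solving; at evaluation the prompt matching the downstream task switches
the model into that mode. Per-session linear read-in/read-out projections
plus a session embedding (**stitching**) let one trunk train across sessions
with disjoint neuron sets, and fine-tuning registers unseen sessions.
Activity metrics are reported in **bits per spike** against a per-neuron
mean-rate null; behavior decoding uses fixed ridge linear decoders on the
inferred rates. The transformer, its backpropagation and AdamW are
implemented in the package directly on BLAS matrix algebra and verified by
finite-difference gradient checks in the test suite.

The spiking data themselves are simulated: region-coupled linear latent
dynamics (slow shared mode, strong cross-region co-fluctuation), Poisson
counts through an exponential link, a latent-level choice signal and a
motion-energy readout. See `vignette("mtm-methods")` for the model, the
simulator and every numerical choice.

## Worked example

Simulate one repeated-site-style session (3 regions × 40 neurons, 200 trials
of 100 × 20 ms bins), train a small MtM model for a few minutes of CPU, and
run the benchmark:

```r
library(mtmspike)

session <- generate_session(sim_config(seed = 1))
split   <- split_trials(200, seed = 1)

model <- fit_mtm(
  session,
  train_config(epochs = 100, batch_size = 8, learning_rate = 3e-3,
               seed = 1, k_active = 20, eval_every = 10),
  model_config(d_model = 32, n_layers = 2, n_heads = 2, ffn_dim = 64,
               max_bins = 100),
  splits = setNames(list(split), session$session_id))

report <- evaluate_all(model, session, split, model_id = "mtm")
report
#> <eval_report> model 'mtm' on session 'synth-1-s01'
#>   co-smoothing bps:     0.2562
#>   forward bps:          0.2120
#>   intra-region bps:     0.2457
#>   inter-region bps:     0.2468
#>   choice accuracy:      0.7000
#>   motion-energy R^2:    0.8359
```

Positive bits-per-spike means the model beats the per-neuron constant-rate
null on held-out test trials: here the trained model recovers planted
population structure on all four activity tasks (the simulator's true-rate
oracle scores about 0.33 bps on this data, so ~0.21–0.26 from a few minutes
of CPU training is substantial), decodes the planted choice signal above
the 0.5 chance level, and explains most of the motion-energy variance. An
untrained model scores ≈ 0 bps everywhere; a temporal-masking baseline
trained at the same budget falls behind on the region metrics — that
contrast is what the benchmark is for.

The same pipeline is scriptable from a shell via the bundled entry point:

```sh
MTM=$(Rscript -e 'cat(system.file("cli/mtm.R", package = "mtmspike"))')
Rscript $MTM simulate --out runs/sim --seed 1
Rscript $MTM train    --out runs/train --config train.yaml
Rscript $MTM evaluate --out runs/eval \
    --set checkpoint=runs/train/checkpoint.rds \
    --set session_dir=runs/sim/synth-1-s01
Rscript $MTM decode   --out runs/decode \
    --set checkpoint=runs/train/checkpoint.rds \
    --set session_dir=runs/sim/synth-1-s01
```

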