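---
title: "Multi-task masked modeling of multi-region spiking data: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-task masked modeling of multi-region spiking data: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The modeling problem

Modern Neuropixels experiments record hundreds of spiking neurons across
several brain regions simultaneously, trial after trial. A useful population
model of such data should be able to answer qualitatively different questions
with one set of weights: what is a held-out neuron doing given the rest of
the population (co-smoothing)? what will the population do next (forward
prediction)? what does one region's activity say about another region
(inter-region prediction)? and what does the activity say about behavior
(decoding)? `mtmspike` implements multi-task masking (MtM), a self-supervised
training recipe built around exactly this demand, together with the
test-time-masking benchmark used to measure it.

The observation model throughout is Poisson: binned spike counts
$x_{r,t,n}$ (trial $r$, 20 ms bin $t$, neuron $n$) are treated as
$x \sim \text{Poisson}(\lambda)$ with $\lambda$ the model's inferred
firing-rate tensor. Training minimizes the masked Poisson negative
log-likelihood $\sum (\lambda - x\log\lambda + \log x!)$ over *scored*
entries only, normalized by the number of scored entries so that losses are
comparable across masking schemes with very different target sizes.

## Masking schemes: context versus target

Every scheme produces two boolean masks over `(time_bin, neuron)`:

* a **context mask** — what the model is allowed to see; hidden entries are
  zero-filled before tokenization, and the mask itself is carried alongside
  the data for auditing and (optionally) for the model;
* a **target mask** — what the loss scores. Hidden and scored are not the
  same thing: intra-region masking hides all out-of-region neurons without
  scoring them, so that the only usable context is same-region activity.

The four MtM schemes are neuron masking (hide random whole neurons,
reconstruct from the rest), causal masking (hide the final 10% of bins,
reconstruct from the past), intra-region masking (hide part of one region,
context restricted to the same region) and inter-region masking (hide a whole
region, context restricted to the other regions). The temporal baseline
(hide random whole time bins) is implemented for comparison and is never part
of the MtM scheme set. During MtM training one scheme is drawn uniformly per
batch; a learnable per-scheme prompt token is prepended to the token sequence
so the model knows which task it is solving, and the same token is used at
evaluation to switch the model into the task's mode.

Mask ratios are not part of the published recipe; the package defaults are
0.3 for neuron, temporal and intra-region masking, 1.0 for inter-region
(the whole region may be hidden because context comes from elsewhere), and a
0.10 causal horizon at evaluation. Regions with fewer than 5 neurons are
never chosen for region masking (an intra-region context would be empty or
trivial). All are configurable via `mask_params()`.

One training-side choice deserves emphasis. Causal *training* masks place
the cut point uniformly at random within the trial (hiding everything after
it), while causal *evaluation* always hides the fixed final 10%. We first
trained with the fixed tail only and measured the result: the model reached
positive reconstruction on training trials while its test-trial predictions
were uncorrelated with the true rates — with only one cut position, the
cheapest solution is to memorize position-keyed tails rather than learn
past-to-future structure, and no amount of dropout, weight decay or capacity
reduction changed that. Randomizing the cut during training (next-step
prediction at every position, in the GPT spirit the causal scheme descends
from) removes that shortcut; `mask_params(causal_random_start = FALSE)`
restores the fixed-tail behavior.

## Architecture

The model is an NDT1-style temporal-token encoder: one token per 20 ms bin,
carrying all neurons. Per session, a *stitcher* holds an input projection
(`N -> d_model`), an output
projection (`d_model -> N`) and a session context embedding, so that one
transformer trunk serves sessions with disjoint neuron sets. Attention is
bidirectional for every scheme — causality is enforced by the input mask,
not by attention masking — matching the single shared architecture across
tasks. The rate head applies a softplus link with a `1e-6` floor by default;
the exponential GLM link is available but overflows easily early in
training. The output bias of a freshly registered session is initialized to
the inverse-link of the session's per-neuron mean counts, so an untrained
model starts at the mean-rate null rather than spending its first epochs
learning marginal firing rates.

How the mask reaches the model was a genuinely open design choice, and we
resolved it by measurement. The tokenizer can concatenate the binary
context-mask row with the zero-filled counts
(`model_config(mask_channel = TRUE)`), which lets the model distinguish a
hidden entry from an observed zero. We found that feeding the mask defeats
the framework's own purpose on this benchmark: every model can then *see*
which masking scheme it is under, so the temporal baseline smoothly
renormalizes when whole regions are hidden at evaluation (erasing the
scheme-specific failure modes the benchmark is designed to expose), and the
prompt token becomes strictly redundant information. The default is
therefore the NDT convention — a plain linear projection of the zero-filled
counts — and the mask channel remains available as an option. Zero-filled
hidden entries are still never confused with data by the *loss* (unscored
entries contribute exactly zero), and rates remain exactly invariant to the
values of hidden entries.

The prompt token is exempt from embedding dropout: it is the only carrier
of the scheme identity, and stochastically deleting it during training
teaches the model to ignore it — with the exemption (and the mask channel
off), matched-prompt evaluation measurably outperforms a mismatched prompt
on most activity metrics, and the margin grows with training.

Position embeddings are learnable and initialized sinusoidally, and weights
use Xavier-scaled initialization. Both are deliberate: with a fixed small
initialization (the GPT-2 habit, tuned for much wider models) attention
logits at `d_model = 32` start at the 1e-4 scale and the softmax stays
measurably uniform through training, leaving the causal scheme on an
optimization plateau; Xavier scaling plus a sinusoidal position geometry
gives attention usable structure from the first step.

The engine (forward pass, backpropagation, AdamW) is written directly in R
on top of BLAS matrix algebra, and its gradients are verified against finite
differences in the test suite. Default architecture: `d_model = 128`,
4 layers, 4 heads; the examples and tests use smaller configurations
(`d_model` 16–64, 1–2 layers) chosen to keep single-CPU runtimes in minutes,
and the acceptance analyses state their sizes explicitly.

## The synthetic benchmark

The simulator emulates the structure of repeated-site, multi-region
recordings: every session in a cohort shares region labels and
latent-dynamics parameters while recording a disjoint set of neurons with
session-specific loadings. Per trial, each region carries a low-dimensional
latent state evolving as a coupled linear autoregression
$z_{t+1}[r] = \sum_q C_{rq} z_t[q] + \varepsilon$; spike counts are Poisson
with log-rates $\log\lambda_n = b + w_n^\top z[\text{region}(n)]$
(exponential link: the Poisson-GLM convention, guaranteeing positivity);
whisker-like motion energy is a linear readout of the pooled latents plus
Gaussian noise; and a binary per-trial choice shifts the latent initial
condition along a fixed cohort-level direction, so the behavioral signal is
population-level and decays with the dynamics rather than being painted onto
individual neurons.

The default dynamics matter, and they were designed against an explicit
requirement: every one of the four masked tasks must carry recoverable
signal, because the benchmark exists to detect whether a training recipe
recovers it. Self-coupling 0.765 with cross-coupling 0.115 places, for three
regions, a shared latent mode at eigenvalue 0.995 — an engagement-scale
drift with a timescale of several seconds, the slow-state regime
ubiquitously reported in rodent electrophysiology — and idiosyncratic
regional modes at 0.65. Consequences: future bins are genuinely predictable
from a trial's own past (the slow mode persists to the final 10% of the
trial; a six-component linear probe achieves about +0.24 bits per spike on
forward prediction, against an oracle of about +0.33), and a held-out region
is predictable from the others (strong cross-region co-fluctuation), which
is also the regime the published multi-region results exhibit, with
forward-prediction and inter-region scores comparable to co-smoothing.
Development iterations with faster dynamics (latent timescales of 90–400 ms)
left the forward tail statistically independent of the visible past — a
forward-prediction benchmark with no forward-predictable signal — and were
discarded for that reason. The innovation s.d. (0.15) keeps per-neuron
log-rate dispersion near 0.6 despite the slow mode's large stationary
variance. The choice effect size (3.0, about 4.5 stationary s.d. along the
choice direction) is calibrated so that choice is reliably recoverable from
the true rates — a behavior-decoding benchmark needs a recoverable signal —
while remaining invisible to a decoder when the effect is set to 0.

What the simulator does **not** emulate: refractoriness, bursting and other
point-process fine structure; non-Poisson dispersion; stimulus contrasts and
block structure of the real task; non-stationary drift across a session; and
realistic anatomical asymmetries in coupling. Tests passing on this
benchmark therefore show that the pipeline recovers planted low-dimensional
Poisson structure — they do not certify performance on real recordings.

Defaults (3 regions × 40 neurons, 2 latents/region, 200 trials, 100 bins of
20 ms) keep one session at roughly a fifth of a typical repeated-site
recording in neurons and bins, small enough for CPU training in minutes. All randomness derives from
`(seed, session_index)`, so cohorts are bit-reproducible.

## Training, checkpointing, evaluation

Training uses AdamW (constant learning rate, default `1e-3`, weight decay
0.01, batch 32 trials; the acceptance runs use batch 8 and learning rate
`3e-3`, which at these problem sizes reaches the same quality in fewer
wall-clock minutes). Trials are split 80/10/10 into train/validation/test by
a seeded permutation (floor sizes, remainder to train). The checkpoint rule
follows the single-neuron reconstruction criterion: every `eval_every`
epochs the mean R² between predicted rates and observed counts — under
neuron masking of each scored neuron, on validation trials, across the
`k_active` most active neurons — is computed, and the weights of the
best-scoring epoch are kept (ties to the earliest). Neuron masking is used
for this score for consistency with the co-smoothing evaluation; the
published rule does not state the masking condition.

Evaluation is test-time masking: the trained model never changes, only the
input mask does. Bits per spike is computed against the per-neuron mean-rate
null (means over training trials, floored at `1e-9` inside logs), pooled
over all scored entries (micro-average); per-region values are also
reported. Co-smoothing iterates neurons one at a time (the exact reference);
`batch_k > 1` hides groups jointly as a faster approximation. Behavior
decoding uses rates inferred on *unmasked* input — test-time masking applies
to the activity metrics, and whether decoding rates should come from masked
passes is left open by the source recipe — with the neuron prompt for choice
and the causal prompt for motion energy; the prompt choice is exposed as an
argument since it is reported not to matter much. The decoders are fixed
ridge-penalized linear fits (`glmnet`, penalty 1.0): the point of the
benchmark is the representation, not the decoder.

Degenerate cases are flagged rather than thrown: a zero spike count in the
scored entries, a single-region session asked for inter-region scores, or a
zero-variance decoding target all yield `NA` with an `undefined` attribute.
`poisson_nll()` errors on non-positive rates; the rate link makes them
impossible in the model path.

## Multi-session pretraining and fine-tuning

`fit_mtm()` accepts a list of sessions and interleaves their batches;
the trunk, prompt table and position table are shared while each session
keeps its own stitcher entries. `finetune_session()` registers a fresh
stitcher for an unseen session (output bias initialized to that session's
mean rates) and continues the same self-supervised objective on the new
session. Fine-tuning is two-phase: a short warmup trains only the new
session's stitcher with the trunk frozen, then everything is trainable.
The warmup is not cosmetic — a randomly initialized read-in projection
feeds noise through the pretrained trunk, and we measured that immediate
all-weights fine-tuning erases the pretraining benefit at these problem
sizes (paired against from-scratch training on the same session, the mean
co-smoothing improvement was negative without the warmup and positive with
it). The all-weights phase keeps the published convention of freezing
nothing.

## Numerical and design notes

* Bins are half-open `[t, t+dt)`; a spike exactly on an edge belongs to the
  later bin. Spikes outside every trial window are dropped silently (by
  documented contract). Indices are 1-based throughout, as in all of R.
* The session container is a plain directory (JSON metadata + CSV arrays)
  with lossless round-trip, including full-precision `bin_size`; missing
  components are reported by group name. Region maps can also be imported
  from a two-column CSV.
* How the mask is communicated to the model is an engineering choice (the
  source recipe does not specify one): we concatenate the binary context row
  with the zero-filled counts before the input projection. The prompt token
  is always prepended when prompting is enabled, at training and at test.
* Softmax stabilization subtracts the global maximum of each score matrix
  (valid per row, cheaper than row maxima at these sequence lengths).
* The AdamW state lives per parameter leaf; sessions registered after
  optimizer creation (fine-tuning) get fresh moment slots.
* Reproducibility: every stochastic stage (simulation, splitting, batching,
  scheme and mask draws, initialization) derives from explicit seeds;
  repeated runs are bit-identical on one platform, and evaluation is
  deterministic given a model.

## Known limitations

The engine is CPU-oriented and favors small models; it implements exactly
the pieces MtM needs (no dropout, no attention masking, no mixed precision).
Single-scheme models can score far below the null on mismatched metrics —
that is a property of the approach, visible in the published ablations, not
a defect of the implementation. Bits-per-spike values on the synthetic
benchmark are an order of magnitude smaller than on real recordings (the
planted signal is weaker than real population structure); comparisons
between training recipes, which is what the benchmark is for, are unaffected.
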