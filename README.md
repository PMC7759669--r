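# stsaEEG

Four-class motor-imagery EEG decoding with a parallel spatial–temporal
self-attention convolutional network, in R.

Motor imagery (imagined left-hand, right-hand, feet, or tongue movement)
modulates the mu (8–12 Hz) and beta (16–26 Hz) sensorimotor rhythms —
event-related desynchronization and synchronization (ERD/ERS) with a broadly
contralateral layout. Brain–computer interfaces decode these changes from
short multi-channel EEG epochs. `stsaEEG` is for BCI researchers who want a
compact, fully tested CPU implementation of an attention-based end-to-end
decoder: no feature engineering, raw standardized epochs in, class
log-probabilities out.

## The model

One epoch is a matrix `M ∈ R^(H×W)` (channels × time samples, e.g. 22 × 1125
for a [−0.5, 4] s window at 250 Hz). Two parallel self-attention modules
re-represent `M`:

* **Spatial attention** — two 1×1-convolution projections of `M` into F = 8
  maps form query/key images; their dot products give channel-similarity
  scores, row-softmaxed into a row-stochastic map `s3 ∈ R^(H×H)`. Every
  channel is rewritten as a convex combination of all channels,
  `s4 = s3 · M`, and the output is the residual `S = λ1·s4 + M`.
* **Temporal attention** — the same construction on the time axis yields
  `t3 ∈ R^(W×W)` and `t4[c,p] = Σ_q t3[p,q]·M[c,q]`, with
  `T = λ2·t4 + M`.

Both λ are trainable scalars initialized at 0, so the network starts as the
identity plus its classification head and learns how much attention to mix
in. The head stacks `C1 = (M, S, T)` and applies a shallow square/log
convolutional pipeline — 1×25 temporal convolution (40 maps), H×1 spatial
convolution, batch norm, `x²`, 1×75/15 average pooling, `log`, dropout 0.5,
full-width convolution, log-softmax:
`(3, 22, 1125) → (40, 22, 1101) → (40, 1, 1101) → (40, 1, 69) → (4, 1, 1)`.

Training is Adam on the negative log-likelihood with Xavier initialization
and a two-phase early-stopping schedule: phase 1 on a stratified 80/20 split
stops after `patience` epochs without validation improvement and restores the
best state; phase 2 continues on all data until the former-validation loss
falls to the phase-1 training loss. 10-fold cross-validation and
inter-subject transfer (pretrain on other subjects, fine-tune on the target)
protocols are included, as is a synthetic ERD/ERS generator so the whole
stack runs with no downloads.

## Worked example

```r
library(stsaEEG)

spec  <- syntheticSpec()                       # 22 ch, 250 Hz, 4.5 s, 4 classes
train <- generateDataset(spec, 30, seed = 1)   # 120 labeled epochs
test  <- generateDataset(spec, 10, seed = 2)   #  40 held-out epochs

cfg <- trainConfig(lr = 1e-3, patience = 3, maxEpochsPhase1 = 10,
                   maxEpochsPhase2 = 4, seed = 7)
fit <- fitTwoPhase(stsaModel(modelConfig()), train, cfg)
fit
#> STSAFit: 14 epochs trained (phase 1 ended at 10), best validation accuracy 95.83%

pred <- predict(fit@model, test)
accuracy(epochLabels(test), pred)
#> [1] 90
confusionCounts(epochLabels(test), pred)
#>             predicted
#> true         left_hand right_hand feet tongue
#>   left_hand          9          0    1      0
#>   right_hand         0          9    1      0
#>   feet               1          0    8      1
#>   tongue             0          0    0     10
```

The accuracy is percent correct over the held-out epochs (chance is 25% for
four balanced classes); the confusion matrix rows are true classes. λ1 and λ2
move away from 0 during training as the network learns to mix the attention
features into the raw signal (`fit@model@params$lam1`, `...$lam2`).

The same pipeline is scriptable from a shell via the bundled CLI
(`inst/scripts/stsa`): `stsa synth`, `stsa train`, `stsa eval`,
`stsa describe` (prints the architecture shape trace above), `stsa crossval`,
`stsa transfer`, and `stsa preprocess` for EDF/EDF+ recordings.

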