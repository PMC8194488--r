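# resemote

Speech emotion recognition with a residual convolutional network, a
bidirectional LSTM, attention pooling and a softmax classifier — plus the
speaker-independent evaluation protocol and the downstream group-association
analysis that turn clip-level predictions into a person-level
contingency-table study.

## Who this is for and what it does

Researchers in affective computing and computational psychiatry who need a
transparent, fully inspectable implementation of a standard deep
speech-emotion-recognition (SER) pipeline in R: every numerical component —
convolutions, residual blocks, LSTM gates, attention, Adam — is implemented
in plain matrix arithmetic with analytically derived gradients, verified
against independent oracles and central differences in the test suite.  The
package also ships the evaluation and annotation machinery around the
model, so a complete study — from raw WAV files to a group × emotion
chi-square — runs end to end with no external services and no downloads
(a deterministic synthetic-audio generator stands in for real corpora).

## The model

A clip is z-scored, framed (25 ms Hamming windows, 10 ms hop) and passed
through a Mel filterbank to the three-channel log-Mel representation

$$m_i = \log(p_i + \varepsilon), \qquad
m_i^{d} = \frac{\sum_{n=1}^{N} n\,(m_{i+n}-m_{i-n})}{2\sum_{n=1}^{N} n^2}
\;(N=2),$$

with the delta-delta channel the same regression operator applied twice.
The $t \times f \times 3$ array flows through a 1×1 expansion to 128
channels, residual blocks (two 3×3 convolutions, skip connection, 2×4 max
pooling; three blocks by default), a bidirectional LSTM with 128 hidden
units per direction (256-dimensional steps) whose gates include cell-state
feedback terms, attention pooling
$\alpha_t \propto \exp(\sigma(w_1^{\top} h_t + b))$,
$r = \sum_t \alpha_t h_t$, and a two-layer softmax head trained with mean
cross-entropy.  Evaluation is speaker-independent cross-validation scored
by unweighted average recall (UAR), the unweighted mean of per-class
recalls.  See `vignettes/resemote-methods.Rmd` for every design decision.

## Worked example

```r
library(resemote)

# a balanced synthetic corpus: 3 emotion classes x 5 speakers x 5 clips,
# classes separated by spectral band and modulation rate
spec <- synth_spec(n_classes = 3, n_speakers = 5,
                   clips_per_speaker_per_class = 5,
                   duration_s = 0.5, sample_rate = 8000, seed = 11)
dataset <- generate_dataset(spec)

fc  <- feature_config(n_mels = 16, sample_rate = 8000)
cfg <- model_config(n_classes = 3, expand_channels = 8,
                    n_residual_blocks = 2, lstm_hidden = 16,
                    fc_hidden = 16, seed = 1)
dataset <- add_features(dataset, fc)
plan <- speaker_folds(dataset, k = 5, seed = 2)   # leave-one-speaker-out
report <- cross_validate(dataset, cfg, plan, fc,
                         epochs = 15, batch_size = 16, seed = 5)
report
#> <ser_eval> UAR 1.000, ACC 1.000 over 75 predictions
#> Per-class recall:
#> emo1 emo2 emo3
#>    1    1    1
glance(report)
#> # A tibble: 1 × 6
#>     uar   acc     n n_classes fold_uar_mean fold_uar_sd
#>   <dbl> <dbl> <int>     <int>         <dbl>       <dbl>
#> 1     1     1    75         3             1           0
```

Every clip is scored by a model that never saw its speaker; UAR 1.0 means
all three classes were recovered perfectly on held-out speakers.
`autoplot(report)` draws the row-normalized confusion matrix.

The downstream association analysis aggregates three simulated expert
annotations per clip (majority vote), labels each defendant with their
dominant non-neutral emotion, and tests the group × emotion table:

```r
recs <- generate_trial_records(seed = 7)   # 27 vs 27 defendants
res <- associate(recs, emotions = c("angry", "neutral", "fear"))
res$table
#> <ser_contingency> group x emotion counts
#>                emotion
#> group           angry neutral fear
#>   addiction        18       4    5
#>   non_addiction     8      17    2
res$test
#> <ser_assoc> Pearson chi-square (Monte-Carlo p): X^2 = 13.18, dof = 2, p = 0.0012
#> (statistical test added on top of the annotation protocol)
```

The generator plants a higher anger/fear rate in the first group, and the
chain of majority vote → person labeling → contingency table → chi-square
recovers it.  `tidy()` / `glance()` methods return all results as tibbles;
`autoplot()` methods draw the confusion matrix, the contingency bars and
the training-loss curve.

A thin command-line wrapper covers the same workflows
(`exec/resemote synth|extract|train|evaluate|crossval|ablate|emodb-index|associate`);
if a local copy of the Berlin Emotional Database is available,
`emodb-index` turns its filename convention into the shared manifest
schema.

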