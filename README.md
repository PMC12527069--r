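# ecgwolf

Five-class heartbeat classification from single-lead ECG, built around
three pieces that are usually scattered across scripts: a reproducible
preprocessing pipeline (wavelet denoising with the universal hard
threshold), a hybrid 1D-convolutional + recurrent classifier, and a Grey
Wolf Optimizer that tunes the classifier's hyperparameters against
validation accuracy. The package is aimed at biomedical-signal researchers
who want every stage — from raw annotated ECG to a per-class evaluation
report — as tested, seeded, composable R functions, with a synthetic ECG
generator so the whole pipeline runs and is testable without any data
download.

## The method

**Classes.** Beats are consolidated into the five AAMI classes — N
(normal), S (supraventricular ectopic), V (ventricular ectopic), F
(fusion), Q (unclassifiable) — via the standard symbol mapping
(N←{N,L,R,e,j}, S←{A,a,J,S}, V←{V,E}, F←{F}, Q←{/,f,Q}).

**Preprocessing.** Each record passes through R-peak detection (annotated
peaks refined to the local maximum, or an energy-based Pan–Tompkins-style
detector), fixed-window segmentation around each R peak (99 samples
before, 180 after, at 360 Hz), per-segment z-scoring, probabilistic
subsampling of the majority class (each N beat kept with probability
0.15), removal of non-finite segments, and wavelet denoising: a 3-level
sym5 DWT, noise scale

    sigma = median(|c_d|) / 0.6745

estimated from the finest detail band, the universal threshold

    lambda = sigma * sqrt(2 ln n),

and hard thresholding of all detail coefficients (|c| <= lambda set to 0)
before inverse transform.

**Models.** Three classifiers are implemented from scratch (forward and
backward passes, Kaiming-normal initialization, Adam/AdamW, weighted
cross-entropy): a two-block 1D-CNN (Conv 1→256, k=8, s=5 and Conv
256→128, k=7, s=4, each with ReLU/dropout/max-pool, then dense layers); a
stacked LSTM (64→32→16 units, dropout 0.4) built on the standard gate
equations

    i_t = sigmoid(W_i x_t + W_hi h_{t-1} + b_i)        (input gate)
    f_t = sigmoid(W_f x_t + W_fi h_{t-1} + b_f)        (forget gate)
    o_t = sigmoid(W_o x_t + W_oi h_{t-1} + b_o)        (output gate)
    c~_t = tanh(W_c x_t + W_hc h_{t-1} + b_c)
    c_t = f_t ⊙ c_{t-1} + i_t ⊙ c~_t
    h_t = o_t ⊙ tanh(c_t)

and the hybrid model, where the CNN feature map is handed to a single
LSTM layer as a sequence (time steps = spatial positions, features =
channels), then a dense layer and softmax.

**Hyperparameter search.** A from-scratch Grey Wolf Optimizer: candidate
positions are steered by the three best wolves via

    X_k = X_leader - A_k |C_k X_leader - X|,   k in {alpha, beta, delta}
    X(t+1) = (X_1 + X_2 + X_3) / 3

with A = 2 a r1 - a, C = 2 r2 and the control scalar a decreasing
linearly from 2 to 0. The default mixed integer/continuous space covers
filters [8, 320], kernel size [3, 7], stride [2, 8], LSTM units
[20, 256] and dropout [0.001, 0.6]; fitness is validation accuracy.

**Evaluation.** Confusion matrix, one-vs-rest precision/recall/F1 per
class, macro and support-weighted averages, and overall accuracy
(trace/total).

## Worked example

```r
library(ecgwolf)

spec <- synthetic_spec(n_beats = 600, noise_sd = 0.05, seed = 42)
ds <- generate_beat_dataset(spec)
ds
#> <beat_dataset> 600 beats x 280 samples
#>   N   S   V   F   Q
#> 408  40  91   9  52

ds <- normalize_dataset(ds)
ds <- subsample_majority(ds, keep_prob = 0.15, seed = 43)
ds <- denoise_dataset(ds)
parts <- stratified_split(ds, 0.8, seed = 44)

model <- kaiming_init(build_hybrid(), seed = 45)
model
#> <ecg_model:hybrid> 11 layers, 281541 trainable parameters

fit <- train_model(model, parts$train, parts$test,
                   train_config(epochs = 5, batch_size = 20,
                                learning_rate = 1e-3,
                                optimizer_name = "adamw", seed = 46))
evaluate_model(fit$model, parts$test)
#> Metric           N     S     V     F     Q  Average
#> Precision(%)   100   100   100   100   100      100
#> Recall(%)      100   100   100   100   100      100
#> F1(%)          100   100   100   100   100      100
#> Overall accuracy: 100%
```

The generated mixture reproduces the severe class imbalance of ambulatory
arrhythmia data (two thirds normal beats); subsampling the majority class
rebalances it before training. On these cleanly separated synthetic
morphologies the hybrid classifier reaches 100% test accuracy within a
few epochs — real ambulatory recordings, with inter-patient variability
and borderline morphologies, are far harder (see the methods vignette for
what the synthetic benchmark does and does not show).

A hyperparameter search wraps the same pieces:

```r
res <- gwo_optimize(
  function(hp) accuracy_fitness(hp, parts$train, parts$test,
                                train_config(epochs = 2, seed = 1)),
  default_search_space(), n_wolves = 10, n_iters = 20, seed = 1)
res$best_params
```

A command-line entry point with `simulate`, `preprocess`, `train`,
`optimize`, `evaluate` and `run` subcommands is installed at
`inst/cli/ecgwolf.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "ecgwolf.R", package = "ecgwolf"))')" run --seed 3 --epochs 10 --out run-out
```

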