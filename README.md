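# eegfuse

Few-shot epileptic seizure detection from single-channel EEG by fusing four
representations of the same segment — the raw time series x(n), its one-sided
DFT magnitude spectrum |X(k)|, a Hamming-window STFT spectrogram (window 128,
overlap 120), and a two-level db1 (Haar) wavelet coefficient vector laid out
as [cA2, cD2, cA1].  Each representation feeds its own lightweight CNN branch
(one wide standard convolution, then depthwise separable convolutions, batch
norm + ReLU, stride-2 pooling, global average pooling); the four
32-dimensional branch features are concatenated into a 128-dimensional fused
feature F = F1 ⊕ F2 ⊕ F3 ⊕ F4 and classified by a softmax head.  Training
minimises cross-entropy + λ·Σw² (λ = 1e-4) with Adam (initial learning rate
0.005, halved every 20 epochs, batch size 6), all branches jointly.

Evaluation uses the few-shot *inverted* N-fold protocol: train on one
class-stratified fold, validate on the remaining N−1, so 200 segments give
40-sample training sets under 5-fold and 20-sample sets under 10-fold.
Per-fold accuracies are summarised by their mean and sample standard
deviation.

The package is aimed at researchers studying input representations for
EEG classification in label-scarce settings: it contains the transforms, the
network (implemented in R + Rcpp/Armadillo; no external deep-learning
framework), the protocol, a Bonn-layout plain-text reader, and a synthetic
EEG generator for end-to-end testing without the clinical data.

## Worked example

Generate a labeled synthetic dataset (normal: theta-dominant; ictal: 4-fold
amplitude, delta-dominant with extra alpha/beta power), then compare a
single-input baseline with the hybrid model under 5-fold inverted
cross-validation:

```r
library(eegfuse)

segments <- generate_dataset(synth_config(n_per_class = 20, seed = 42))
hybrids  <- make_hybrid_set(segments)      # raw / DFT / STFT / DWT per segment
hybrids[[1]]$shapes
#> $raw : 4097      $dft : 2049      $stft: 65 497      $dwt : 4099

eeg <- run_experiment(hybrids, "EEG", n_folds = 5,
                      train_config(seed = 42), seed = 42, epochs = 30)
hyb <- run_experiment(hybrids, "Hybrid", n_folds = 5,
                      train_config(seed = 42), seed = 42, epochs = 30)
print(eeg)
#> <fold_report> EEG: folds [0.8438, 0.9062, 0.9688, 1.0000, 1.0000]  mean 0.9437  dispersion 0.0677
print(hyb)
#> <fold_report> Hybrid: folds [0.9688, 1.0000, 1.0000, 0.8750, 1.0000]  mean 0.9688  dispersion 0.0541
```

Each fold trains a freshly initialised model on 8 segments (4 per class) and
validates on the other 32; the report lists per-fold validation accuracies,
their mean, and their sample standard deviation (the dispersion statistic).
Even at this very small scale (8 training segments) fusing the four
representations beats the raw-EEG baseline on both mean accuracy and
dispersion; the margins grow with the published 20-40-sample training sets.

Model inspection and persistence:

```r
model <- build_hybrid_model(seed = 1)
count_parameters(model)$breakdown
#>  raw  dft stft  dwt head
#> 3856 3856 5040 3856  258
```

A command-line launcher with `simulate`, `transform`, `train`, `evaluate`,
and `report` verbs is installed at
`system.file("cli", "eegfuse", package = "eegfuse")`.

Real data: `read_bonn_directory(path, sets = c("A", "E"))` reads the public
Bonn/Andrzejak plain-text layout (one value per line, 4097 lines per file;
set aliases Z/O/N/F/S accepted) with A/B labeled normal and C/D/E epileptic.

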