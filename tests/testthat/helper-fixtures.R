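# Shared tiny fixtures.  Auxiliary training tests run on short (length-512)
# segments: the spectrogram is 65 x 49 instead of 65 x 497, which keeps a
# full training fold in fractions of a second without changing any of the
# mechanics under test.

tiny_hybrids <- function(n_per_class = 5, length = 512, seed = 3, ...) {
  cfg <- synth_config(n_per_class = n_per_class, length = length,
                      seed = seed, ...)
  make_hybrid_set(generate_dataset(cfg))
}

# Printed per-fold accuracies of the published cross-validation tables
# (A vs E with 5- and 10-fold protocols, AB vs CD with 10-fold), with the
# Mean and Variance cells they print.
published_tables <- list(
  avse_5fold = list(
    EEG = list(k = c(0.9563, 0.9563, 0.9688, 0.9937, 0.9937),
               mean = 0.9738, disp = 0.0189),
    DWT = list(k = c(0.96875, 0.9875, 1.0, 0.9812, 0.9750),
               mean = 0.9825, disp = 0.0120),
    FFT = list(k = c(0.9312, 0.9312, 0.8438, 0.9812, 0.9500),
               mean = 0.9275, disp = 0.0510),
    STFT = list(k = c(0.9875, 1.0, 0.95, 0.9875, 1.0),
                mean = 0.9850, disp = 0.0205),
    Hybrid = list(k = c(0.9875, 0.9937, 0.9937, 0.9937, 0.9875),
                  mean = 0.9912, disp = 0.0034)
  ),
  avse_10fold = list(
    EEG = list(k = c(0.9556, 0.9667, 0.9778, 0.9278, 0.9611, 0.9167,
                     0.9667, 0.9556, 0.9444, 0.9611),
               mean = 0.9534, disp = 0.0187),
    DWT = list(k = c(0.9278, 0.9389, 0.9833, 0.9611, 0.9889, 0.9833,
                     0.9667, 0.9833, 0.9444, 0.9667),
               mean = 0.9644, disp = 0.0213),
    FFT = list(k = c(0.9222, 0.9889, 0.9889, 0.9722, 0.9667, 1.0,
                     0.9833, 0.8944, 0.8556, 0.9944),
               mean = 0.9567, disp = 0.0491),
    STFT = list(k = c(0.9222, 0.9778, 0.95, 0.9222, 1.0, 0.9889,
                      0.9389, 1.0, 0.9778, 0.9667),
                mean = 0.9644, disp = 0.0297),
    Hybrid = list(k = c(0.9667, 0.9667, 0.9944, 0.9722, 0.9778, 0.9611,
                        0.9833, 0.9944, 0.9944, 0.9833),
                  mean = 0.9794, disp = 0.0125)
  ),
  abvscd_10fold = list(
    EEG = list(k = c(0.9806, 0.9667, 0.9667, 0.9722, 0.9667, 0.9806,
                     0.9861, 0.9556, 0.9861, 0.9417),
               mean = 0.9703, disp = 0.0141),
    DWT = list(k = c(0.9694, 0.9750, 0.9639, 0.9722, 0.9528, 0.9806,
                     0.9833, 0.9167, 0.9306, 0.9472),
               mean = 0.9592, disp = 0.0221),
    FFT = list(k = c(0.8556, 0.8556, 0.8444, 0.8361, 0.7222, 0.8167,
                     0.8583, 0.8694, 0.8444, 0.6),
               mean = 0.8103, disp = 0.0849),
    STFT = list(k = c(0.9917, 0.9778, 0.9861, 0.9611, 0.9417, 0.9833,
                      0.9917, 0.9750, 0.95, 0.9417),
                mean = 0.97, disp = 0.0198),
    Hybrid = list(k = c(0.9917, 0.9778, 0.9833, 0.9778, 0.9722, 0.9889,
                        0.9889, 0.9556, 0.9833, 0.9694),
                  mean = 0.9789, disp = 0.011)
  )
)
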