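test_that("DFT magnitudes match closed forms and a brute-force evaluation", {
  # DC-only signal: all energy in bin 0
  n <- 32
  sp <- compute_dft(eeg_segment(rep(2.5, n)))
  expect_length(sp$magnitudes, n %/% 2 + 1)
  expect_equal(sp$magnitudes[1], n * 2.5, tolerance = 1e-12)
  expect_lt(max(sp$magnitudes[-1]), 1e-9)

  # integer-frequency cosine: magnitude N/2 at its bin, ~0 elsewhere
  k0 <- 5
  x <- cos(2 * pi * k0 * (0:(n - 1)) / n)
  sp <- compute_dft(eeg_segment(x))
  expect_equal(sp$magnitudes[k0 + 1], n / 2, tolerance = 1e-9)
  expect_lt(max(sp$magnitudes[-(k0 + 1)]), 1e-9)

  # brute-force O(N^2) summation oracle on a random length-16 segment
  set.seed(11)
  x <- rnorm(16)
  naive <- vapply(0:8, function(k) {
    Mod(sum(x * exp(-2i * pi * k * (0:15) / 16)))
  }, 0)
  expect_equal(compute_dft(eeg_segment(x))$magnitudes, naive,
               tolerance = 1e-9)

  expect_error(compute_dft(eeg_segment(1)), "at least 2")
  expect_error(eeg_segment(c(1, NA, 3)), "non-finite")
})

test_that("one-sided DFT satisfies Parseval's identity", {
  set.seed(21)
  for (n in c(7, 16, 101, 256, 1024)) {
    x <- rnorm(n)
    m <- compute_dft(eeg_segment(x))$magnitudes
    two_sided <- if (n %% 2 == 0) {
      m[1]^2 + m[n / 2 + 1]^2 + 2 * sum(m[2:(n / 2)]^2)
    } else {
      m[1]^2 + 2 * sum(m[2:((n + 1) / 2)]^2)
    }
    expect_equal(two_sided, n * sum(x^2), tolerance = 1e-6)
  }
})

test_that("STFT framing follows the no-padding drop-tail convention", {
  set.seed(31)
  seg <- eeg_segment(rnorm(4097))
  sp <- compute_stft(seg, 128L, 120L)
  expect_identical(dim(sp$magnitudes), c(65L, 497L))
  expect_identical(sp$hop, 8L)

  # shape contract for assorted (N, window, overlap)
  for (case in list(c(300, 64, 32), c(129, 128, 120), c(1000, 50, 49),
                    c(512, 16, 0))) {
    x <- rnorm(case[1])
    sp2 <- compute_stft(eeg_segment(x), case[2], case[3])
    hop <- case[2] - case[3]
    expect_identical(ncol(sp2$magnitudes),
                     as.integer((case[1] - case[2]) %/% hop + 1))
    expect_identical(nrow(sp2$magnitudes), as.integer(case[2] %/% 2 + 1))
  }

  # all-zero signal: all-zero spectrogram
  expect_true(all(compute_stft(eeg_segment(numeric(300)), 64L,
                               32L)$magnitudes == 0))

  expect_error(compute_stft(eeg_segment(rnorm(100)), 128L, 120L), "exceeds")
  expect_error(compute_stft(eeg_segment(rnorm(300)), 64L, 64L), "overlap")
})

test_that("STFT frames are windowed DFTs and agree with signal::specgram", {
  set.seed(41)
  x <- rnorm(1000)
  seg <- eeg_segment(x)
  sp <- compute_stft(seg, 128L, 120L)
  # frame 0 equals the one-sided DFT of (first 128 samples x Hamming window)
  w <- as.numeric(signal::hamming(128))
  frame0 <- compute_dft(eeg_segment(x[1:128] * w))$magnitudes
  expect_equal(sp$magnitudes[, 1], frame0, tolerance = 1e-9)

  # independent implementation: signal::specgram (drops the Nyquist row and
  # computes one fewer frame under its own tail rule)
  sg <- Mod(signal::specgram(x, n = 128, Fs = seg$sampling_rate_hz,
                             window = signal::hamming(128),
                             overlap = 120)$S)
  expect_equal(sp$magnitudes[1:64, 1:ncol(sg)], unname(sg),
               tolerance = 1e-9)
})

test_that("db1 DWT matches frozen reference coefficients", {
  # Haar on a constant block
  st <- compute_dwt(eeg_segment(c(1, 1, 1, 1)), level = 1L,
                    layout = c("cA1", "cD1"))
  expect_equal(st$coefficients, c(sqrt(2), sqrt(2), 0, 0), tolerance = 1e-12)

  # two-level decomposition of sin(0:10), values frozen from an independent
  # wavelet implementation (half-sample symmetric extension)
  d <- compute_dwt(eeg_segment(sin(0:10)), level = 2L,
                   layout = c("cA2", "cD2", "cD1"))
  expect_equal(unname(d$layout), c(3L, 3L, 6L))
  expect_equal(d$coefficients,
               c(0.94594421, -0.66907783, 0.15671726,      # cA2
                 -0.10447323, -1.04664894, 1.24475948,     # cD2
                 -0.59500984, 0.54318346, 0.14292168,      # cD1
                 -0.66213627, 0.40817015, 0.0),
               tolerance = 1e-7)
})

test_that("db1 DWT reconstructs perfectly and conserves energy", {
  set.seed(51)
  for (n in c(32, 33, 101, 256)) {
    x <- rnorm(n)
    dec <- eegfuse:::dwt_decompose_db1(x, 3L)
    xr <- eegfuse:::dwt_reconstruct_db1(dec$blocks, dec$input_lengths)
    expect_equal(xr, x, tolerance = 1e-9)
  }
  # orthogonality: complete level-J coefficient energy equals input energy
  # (exact for even subband lengths, where no boundary extension occurs)
  for (n in c(64, 256, 1024)) {
    x <- rnorm(n)
    dec <- eegfuse:::dwt_decompose_db1(x, 3L)
    keep <- c("cA3", "cD3", "cD2", "cD1")
    e <- sum(vapply(dec$blocks[keep], function(b) sum(b^2), 0))
    expect_equal(e, sum(x^2), tolerance = 1e-6)
  }
})

test_that("DWT subband lengths follow the odd-length extension rule", {
  seg <- eeg_segment(rnorm(4097))
  wv <- compute_dwt(seg)
  expect_identical(unname(wv$layout), c(1025L, 1025L, 2049L))
  expect_length(wv$coefficients, 4099L)
  expect_identical(names(wv$layout), c("cA2", "cD2", "cA1"))

  expect_error(compute_dwt(seg, wavelet_name = "sym4"), "unknown wavelet")
  expect_error(compute_dwt(seg, level = 2L, layout = c("cA3")),
               "not available")
})

test_that("make_hybrid produces the four standardized representations", {
  set.seed(61)
  seg <- eeg_segment(rnorm(4097))
  h <- make_hybrid(seg)
  expect_identical(h$shapes$raw, 4097L)
  expect_identical(h$shapes$dft, 2049L)
  expect_identical(h$shapes$stft, c(65L, 497L))
  expect_identical(h$shapes$dwt, 4099L)
  for (part in list(h$raw, h$dft, h$stft, h$dwt)) {
    expect_equal(mean(part), 0, tolerance = 1e-10)
    expect_equal(stats::sd(as.vector(part)), 1, tolerance = 1e-10)
  }

  # determinism and purity: label/source_id do not enter the transforms
  seg2 <- eeg_segment(seg$samples, label = "epileptic", source_id = "other")
  h2 <- make_hybrid(seg2)
  expect_identical(h$raw, h2$raw)
  expect_identical(h$stft, h2$stft)
  expect_identical(h$dwt, h2$dwt)
  expect_identical(make_hybrid(seg)$dft, h$dft)

  # zero-variance segment: centring only, no division
  hc <- make_hybrid(eeg_segment(rep(3, 256)))
  expect_true(all(hc$raw == 0))
  expect_true(all(is.finite(hc$dft)))
})
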