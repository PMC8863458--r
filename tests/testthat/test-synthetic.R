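test_that("segment generation is deterministic in (seed, class, index)", {
  cfg <- synth_config(length = 1024, seed = 5)
  a <- generate_segment("normal", cfg, 3L)
  b <- generate_segment("normal", cfg, 3L)
  expect_identical(a$samples, b$samples)
  expect_identical(a$length, 1024L)
  expect_false(identical(a$samples, generate_segment("normal", cfg,
                                                     4L)$samples))
  expect_false(identical(a$samples, generate_segment("epileptic", cfg,
                                                     3L)$samples))
  expect_error(generate_segment("ictal", cfg), "class_label")
  expect_error(synth_config(normal_band_hz = c(8, 4)), "increasing")
  expect_error(synth_config(ictal_amplitude_gain = 0), "gain")
})

test_that("generated classes show the expected spectral contrast", {
  # class-conditional mean one-sided spectra over 100 segments per class:
  # normal peaks in theta (4-8 Hz), ictal in delta (0.5-4 Hz), and the
  # ictal peak dominates
  cfg <- synth_config(n_per_class = 100L, seed = 7)
  ds <- generate_dataset(cfg)
  expect_length(ds, 200L)
  labels <- vapply(ds, `[[`, "", "label")
  expect_identical(sum(labels == "normal"), 100L)

  mean_spec <- function(segs) {
    Reduce(`+`, lapply(segs, function(s) compute_dft(s)$magnitudes)) /
      length(segs)
  }
  sp_n <- mean_spec(ds[labels == "normal"])
  sp_i <- mean_spec(ds[labels == "epileptic"])
  bin_hz <- 173.61 / 4097
  f_n <- (which.max(sp_n) - 1) * bin_hz
  f_i <- (which.max(sp_i) - 1) * bin_hz
  expect_gte(f_n, 4); expect_lte(f_n, 8)
  expect_gte(f_i, 0.5); expect_lte(f_i, 4)
  expect_gt(max(sp_i), max(sp_n))

  # ictal per-sample power exceeds normal for gain > 1
  pw <- function(s) mean(s$samples^2)
  expect_gt(mean(vapply(ds[labels == "epileptic"], pw, 0)),
            mean(vapply(ds[labels == "normal"], pw, 0)))
})

test_that("the null configuration removes class structure", {
  cfg <- synth_config(n_per_class = 50L, length = 1024L,
                      ictal_band_hz = c(4, 8), ictal_amplitude_gain = 1,
                      broadband_gain_ictal = 0, seed = 9)
  ds <- generate_dataset(cfg)
  labels <- vapply(ds, `[[`, "", "label")
  pw <- vapply(ds, function(s) mean(s$samples^2), 0)
  # power distributions of the two classes coincide up to sampling noise
  expect_lt(abs(mean(pw[labels == "normal"]) -
                  mean(pw[labels == "epileptic"])) /
              mean(pw), 0.1)
})

test_that("datasets round-trip through the Bonn plain-text layout", {
  cfg <- synth_config(n_per_class = 3L, length = 256L, seed = 11)
  ds <- generate_dataset(cfg)
  dir <- withr::local_tempdir()
  write_bonn_directory(ds, dir)
  back <- read_bonn_directory(dir, c("A", "E"), expected_length = 256L)
  expect_length(back, 6L)
  expect_identical(vapply(back, `[[`, "", "label"),
                   vapply(ds, `[[`, "", "label"))
  for (i in seq_along(ds)) {
    expect_equal(back[[i]]$samples, ds[[i]]$samples, tolerance = 1e-8)
  }
})

test_that("class separability grows with the ictal amplitude gain", {
  # reduced-scale check of the monotone-separability property: short
  # segments, few samples, reduced epochs
  means <- vapply(c(1.5, 6), function(gain) {
    cfg <- synth_config(n_per_class = 10L, length = 512L,
                        ictal_amplitude_gain = gain,
                        broadband_gain_ictal = 0, noise_sd = 2,
                        seed = 13)
    hy <- make_hybrid_set(generate_dataset(cfg))
    run_experiment(hy, "Hybrid", n_folds = 5L,
                   train_config(seed = 1), seed = 1,
                   epochs = 25)$mean_accuracy
  }, 0)
  expect_gte(means[2], means[1] - 0.05)
  expect_gt(means[2], 0.55)
})
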