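#' One-sided DFT magnitude spectrum of an EEG segment
#'
#' Computes `X(k) = sum_n x(n) exp(-i 2 pi k n / N)` and returns the
#' magnitudes of the one-sided spectrum, bins `k = 0 .. floor(N/2)`.  For a
#' real signal the remaining bins are conjugate-redundant.
#'
#' @param segment An [eeg_segment].
#' @return A `spectrum_vector`: list with `magnitudes` (length
#'   `floor(N/2) + 1`) and `bin_hz` (frequency resolution, Hz per bin).
#' @examples
#' seg <- eeg_segment(cos(2 * pi * 8 * (0:63) / 64))
#' which.max(compute_dft(seg)$magnitudes) - 1  # bin 8
#' @export
compute_dft <- function(segment) {
  x <- segment_samples(segment)
  n <- length(x)
  if (n < 2L) stopf("segment must contain at least 2 samples")
  mags <- Mod(stats::fft(x))[seq_len(n %/% 2L + 1L)]
  structure(
    list(magnitudes = mags,
         bin_hz = segment$sampling_rate_hz / n),
    class = "spectrum_vector"
  )
}

#' Hamming-window magnitude spectrogram (short-time Fourier transform)
#'
#' Frames the segment with a sliding Hamming window (frame `t` covers samples
#' `[t * hop, t * hop + window_length)`, hop = `window_length - overlap`,
#' trailing samples that do not fill a window are dropped) and returns the
#' one-sided DFT magnitude of each windowed frame.
#'
#' @param segment An [eeg_segment].
#' @param window_length Window length in samples (default 128).
#' @param overlap Overlap between adjoining windows in samples (default 120,
#'   i.e. hop 8).
#' @return A `spectrogram`: list with `magnitudes` (matrix, frequency bins
#'   \eqn{\times} time frames, `floor(window_length/2)+1` rows),
#'   `window_length`, `overlap`, `hop`, `bin_hz`.
#' @export
compute_stft <- function(segment, window_length = 128L, overlap = 120L) {
  x <- segment_samples(segment)
  n <- length(x)
  window_length <- as.integer(window_length)
  overlap <- as.integer(overlap)
  if (window_length < 2L) stopf("window_length must be >= 2")
  if (window_length > n) {
    stopf("window_length (%d) exceeds segment length (%d)", window_length, n)
  }
  if (overlap < 0L || overlap >= window_length) {
    stopf("overlap must be in [0, window_length)")
  }
  hop <- window_length - overlap
  n_frames <- (n - window_length) %/% hop + 1L
  win <- signal::hamming(window_length)
  starts <- (seq_len(n_frames) - 1L) * hop
  frames <- matrix(x[outer(seq_len(window_length), starts, `+`)],
                   nrow = window_length) * win
  mags <- Mod(stats::mvfft(frames))[seq_len(window_length %/% 2L + 1L), ,
                                    drop = FALSE]
  structure(
    list(magnitudes = mags, window_length = window_length, overlap = overlap,
         hop = hop, bin_hz = segment$sampling_rate_hz / window_length),
    class = "spectrogram"
  )
}

# db1 (Haar) analysis filter pair.  Only the Haar wavelet is provided: its
# length-2 filters are all the decomposition the network consumes, and they
# admit an exact closed-form inverse used by the reconstruction tests.
dwt_supported_wavelets <- c("db1", "haar")

# One analysis level with half-sample symmetric right-extension for odd
# lengths: an odd-length signal is extended by repeating its final sample, so
# every level has ceiling(n / 2) == floor((n + 1) / 2) coefficients.
dwt_step_db1 <- function(x) {
  n <- length(x)
  if (n %% 2L == 1L) x <- c(x, x[n])
  odd <- x[seq(1L, length(x), by = 2L)]
  even <- x[seq(2L, length(x), by = 2L)]
  list(cA = (odd + even) / sqrt(2), cD = (odd - even) / sqrt(2))
}

# One synthesis level; `out_length` trims the sample appended by the
# odd-length extension, giving perfect reconstruction at every length.
idwt_step_db1 <- function(cA, cD, out_length) {
  y <- numeric(2L * length(cA))
  y[seq(1L, length(y), by = 2L)] <- (cA + cD) / sqrt(2)
  y[seq(2L, length(y), by = 2L)] <- (cA - cD) / sqrt(2)
  y[seq_len(out_length)]
}

# Full multilevel decomposition; internal workhorse behind compute_dwt.
# Returns per-level coefficient blocks and the per-level input lengths needed
# for inversion.
dwt_decompose_db1 <- function(x, level) {
  blocks <- list()
  lengths <- integer(level)
  cur <- x
  for (j in seq_len(level)) {
    lengths[j] <- length(cur)
    st <- dwt_step_db1(cur)
    blocks[[paste0("cA", j)]] <- st$cA
    blocks[[paste0("cD", j)]] <- st$cD
    cur <- st$cA
  }
  list(blocks = blocks, input_lengths = lengths)
}

# Inverse of dwt_decompose_db1 from the complete level-`level` coefficient
# set {cA_level, cD_level, ..., cD_1}.
dwt_reconstruct_db1 <- function(blocks, input_lengths) {
  level <- length(input_lengths)
  cur <- blocks[[paste0("cA", level)]]
  for (j in rev(seq_len(level))) {
    cur <- idwt_step_db1(cur, blocks[[paste0("cD", j)]], input_lengths[j])
  }
  cur
}

#' Multilevel db1 discrete wavelet coefficient vector
#'
#' Performs a multilevel discrete wavelet decomposition (recursive low/high
#' pass filtering with factor-2 downsampling) using the db1/Haar filter pair
#' and concatenates the requested subband blocks into a single coefficient
#' vector.  The default two-level layout `[cA2, cD2, cA1]` matches the
#' coefficient structure used as network input.
#'
#' Odd-length inputs use half-sample symmetric extension (final sample
#' repeated), so each subband has `floor((n + 1) / 2)` coefficients; a
#' 4097-sample segment yields a 1025 + 1025 + 2049 = 4099 element vector.
#'
#' @param segment An [eeg_segment].
#' @param wavelet_name Mother wavelet; only `"db1"` (alias `"haar"`) is
#'   available.
#' @param level Decomposition depth (default 2).
#' @param layout Character vector of subband block names, concatenated in
#'   this order (default `c("cA2", "cD2", "cA1")`).
#' @return A `wavelet_vector`: list with `coefficients`, `layout` (named
#'   integer vector of block lengths), `wavelet_name`, `level`.
#' @export
compute_dwt <- function(segment, wavelet_name = "db1", level = 2L,
                        layout = c("cA2", "cD2", "cA1")) {
  if (!wavelet_name %in% dwt_supported_wavelets) {
    stopf("unknown wavelet '%s' (available: %s)", wavelet_name,
          paste(dwt_supported_wavelets, collapse = ", "))
  }
  x <- segment_samples(segment)
  level <- as.integer(level)
  if (level < 1L) stopf("level must be >= 1")
  if (2^level > length(x)) {
    stopf("level %d too deep for a segment of %d samples", level, length(x))
  }
  dec <- dwt_decompose_db1(x, level)
  missing_blocks <- setdiff(layout, names(dec$blocks))
  if (length(missing_blocks)) {
    stopf("subband block(s) not available at level %d: %s", level,
          paste(missing_blocks, collapse = ", "))
  }
  picked <- dec$blocks[layout]
  structure(
    list(coefficients = unlist(picked, use.names = FALSE),
         layout = stats::setNames(lengths(picked), layout),
         wavelet_name = "db1", level = level),
    class = "wavelet_vector"
  )
}

#' Transform configuration for hybrid input acquisition
#'
#' Bundles the parameters of the three derived representations.  Defaults are
#' the published operating point: 128-sample Hamming window with 120-sample
#' overlap for the spectrogram, and a two-level db1 decomposition laid out as
#' `[cA2, cD2, cA1]`.
#'
#' @param window_length,overlap Spectrogram framing, see [compute_stft()].
#' @param wavelet_name,level,layout Wavelet decomposition, see
#'   [compute_dwt()].
#' @param standardize If `TRUE` (default) each representation is z-scored
#'   over its own entries before model ingestion; zero-variance
#'   representations are only centred.
#' @return A list of class `transform_config`.
#' @export
transform_config <- function(window_length = 128L, overlap = 120L,
                             wavelet_name = "db1", level = 2L,
                             layout = c("cA2", "cD2", "cA1"),
                             standardize = TRUE) {
  structure(
    list(window_length = as.integer(window_length),
         overlap = as.integer(overlap), wavelet_name = wavelet_name,
         level = as.integer(level), layout = layout,
         standardize = isTRUE(standardize)),
    class = "transform_config"
  )
}

#' Compute the four-representation hybrid input for one segment
#'
#' Derives the raw, DFT-magnitude, STFT-magnitude, and DWT-coefficient
#' representations of one segment — the four parallel inputs of the hybrid
#' network.  Each representation is (by default) independently standardized
#' to zero mean and unit variance over its entries.
#'
#' @param segment An [eeg_segment].
#' @param config A [transform_config()].
#' @return A `hybrid_input`: list with numeric `raw` (length N), `dft`
#'   (length `floor(N/2)+1`), `stft` (bins x frames matrix), `dwt`
#'   (concatenated coefficients), plus `label`, `source_id`, and `shapes`.
#' @examples
#' seg <- eeg_segment(rnorm(4097))
#' h <- make_hybrid(seg)
#' h$shapes
#' @export
make_hybrid <- function(segment, config = transform_config()) {
  dft <- compute_dft(segment)
  stft <- compute_stft(segment, config$window_length, config$overlap)
  dwt <- compute_dwt(segment, config$wavelet_name, config$level,
                     config$layout)
  raw <- segment$samples
  parts <- list(raw = raw, dft = dft$magnitudes, stft = stft$magnitudes,
                dwt = dwt$coefficients)
  if (config$standardize) parts <- lapply(parts, standardize_entries)
  structure(
    list(raw = parts$raw, dft = parts$dft, stft = parts$stft,
         dwt = parts$dwt, label = segment$label,
         source_id = segment$source_id,
         shapes = list(raw = length(parts$raw), dft = length(parts$dft),
                       stft = dim(parts$stft), dwt = length(parts$dwt))),
    class = "hybrid_input"
  )
}

#' Compute hybrid inputs for a list of segments
#'
#' @param segments List of [eeg_segment] objects.
#' @param config A [transform_config()].
#' @return List of `hybrid_input` objects (class `hybrid_set`), with the
#'   transform config attached as attribute `config`.
#' @export
make_hybrid_set <- function(segments, config = transform_config()) {
  out <- lapply(segments, make_hybrid, config = config)
  attr(out, "config") <- config
  class(out) <- "hybrid_set"
  out
}

#' Write a hybrid-input set to disk with a sidecar metadata record
#'
#' Stores the transformed representations of a segment set in one container
#' file (RDS) together with a JSON sidecar recording the transform config,
#' its hash, and the block shapes.
#'
#' @param hybrids A `hybrid_set` from [make_hybrid_set()].
#' @param path Output file path (the sidecar is written to
#'   `paste0(path, ".meta.json")`).
#' @return `path`, invisibly.
#' @export
write_hybrid_set <- function(hybrids, path) {
  saveRDS(hybrids, path)
  config <- attr(hybrids, "config")
  meta <- list(
    n_segments = length(hybrids),
    blocks = c("raw", "dft", "stft", "dwt"),
    shapes = if (length(hybrids)) hybrids[[1L]]$shapes else NULL,
    config = unclass(config),
    config_hash = config_hash(unclass(config))
  )
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Read a hybrid-input set written by [write_hybrid_set()]
#' @param path Container file path.
#' @return The `hybrid_set`.
#' @export
read_hybrid_set <- function(path) readRDS(path)

segment_samples <- function(segment) {
  if (inherits(segment, "eeg_segment")) return(segment$samples)
  stopf("expected an eeg_segment")
}
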