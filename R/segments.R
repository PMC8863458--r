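#' Construct a single-channel EEG segment
#'
#' An `eeg_segment` is a fixed-length, uniformly sampled, single-channel EEG
#' recording with an optional class label.  The default length (4097 samples)
#' and sampling rate (173.61 Hz) follow the public Bonn/Andrzejak recordings,
#' in which each file holds one 23.6 s segment.
#'
#' @param samples Numeric vector of finite sample values (microvolt scale;
#'   unitless after standardization).
#' @param sampling_rate_hz Positive sampling rate in Hz.  Used for frequency
#'   axis labelling and band definitions only; the transforms themselves
#'   operate on bins.
#' @param label Class label: `"normal"`, `"epileptic"`, or `NA` for
#'   unlabeled data.
#' @param source_id Free-text identifier of the segment's origin (file name,
#'   generator tag, ...).
#' @return An object of class `eeg_segment`: a list with elements `samples`,
#'   `length`, `sampling_rate_hz`, `label`, `source_id`.
#' @examples
#' seg <- eeg_segment(sin(2 * pi * 5 * (0:1023) / 173.61))
#' seg$length
#' @export
eeg_segment <- function(samples, sampling_rate_hz = 173.61,
                        label = NA_character_, source_id = "") {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stopf("segment must contain at least one sample")
  if (!all(is.finite(samples))) stopf("segment contains non-finite samples")
  if (!is.numeric(sampling_rate_hz) || length(sampling_rate_hz) != 1L ||
      !is.finite(sampling_rate_hz) || sampling_rate_hz <= 0) {
    stopf("sampling_rate_hz must be a positive number")
  }
  if (!is.na(label) && !label %in% c("normal", "epileptic")) {
    stopf("label must be 'normal', 'epileptic' or NA")
  }
  structure(
    list(samples = samples, length = length(samples),
         sampling_rate_hz = sampling_rate_hz, label = label,
         source_id = as.character(source_id)),
    class = "eeg_segment"
  )
}

#' @export
print.eeg_segment <- function(x, ...) {
  cat(sprintf("<eeg_segment> %d samples @ %.2f Hz, label=%s, source=%s\n",
              x$length, x$sampling_rate_hz,
              ifelse(is.na(x$label), "<unlabeled>", x$label),
              ifelse(nzchar(x$source_id), x$source_id, "<none>")))
  invisible(x)
}

# Accepted aliases for the five Bonn recording sets.  Public mirrors name the
# directories either A-E or by the original file prefixes Z,O,N,F,S.
bonn_set_aliases <- c(A = "Z", B = "O", C = "N", D = "F", E = "S")

bonn_canonical_set <- function(name) {
  up <- toupper(name)
  if (up %in% names(bonn_set_aliases)) return(up)
  hit <- names(bonn_set_aliases)[bonn_set_aliases == up]
  if (length(hit) == 1L) return(hit)
  stopf("unknown Bonn set name '%s' (expected A-E or Z,O,N,F,S)", name)
}

# Default clinical label for each set: A/B are surface recordings from
# healthy volunteers, C/D interictal and E ictal recordings from patients.
bonn_set_label <- function(set) {
  switch(set, A = "normal", B = "normal",
         C = "epileptic", D = "epileptic", E = "epileptic")
}

#' Read a Bonn-layout plain-text EEG directory
#'
#' Expects one subdirectory per recording set (named `A`-`E` or by the
#' original aliases `Z`,`O`,`N`,`F`,`S`), each holding plain-text files with
#' one sample value per line (4097 lines in the published data).  Sets A/B
#' are labeled `"normal"` and C/D/E `"epileptic"`.
#'
#' @param path Directory containing the set subdirectories.
#' @param sets Character vector of set names to read (e.g. `c("A", "E")`).
#' @param sampling_rate_hz Sampling rate recorded on each segment.
#' @param expected_length If not `NULL`, files whose sample count differs are
#'   rejected with an error.
#' @return List of [eeg_segment] objects, in set order then file order;
#'   `source_id` records `"set/filename"`.
#' @export
read_bonn_directory <- function(path, sets = c("A", "E"),
                                sampling_rate_hz = 173.61,
                                expected_length = NULL) {
  if (!dir.exists(path)) stopf("directory '%s' does not exist", path)
  segments <- list()
  for (set in sets) {
    canon <- bonn_canonical_set(set)
    sub <- NULL
    for (cand in unique(c(set, canon, bonn_set_aliases[[canon]]))) {
      hit <- c(file.path(path, cand), file.path(path, tolower(cand)))
      hit <- hit[dir.exists(hit)]
      if (length(hit)) { sub <- hit[[1L]]; break }
    }
    if (is.null(sub)) stopf("set '%s' not found under '%s'", set, path)
    files <- sort(list.files(sub, full.names = TRUE))
    files <- files[!dir.exists(files)]
    if (!length(files)) warning(sprintf("set '%s' is empty", set))
    for (f in files) {
      lines <- readLines(f, warn = FALSE)
      lines <- lines[nzchar(trimws(lines))]
      vals <- suppressWarnings(as.numeric(lines))
      if (anyNA(vals)) {
        bad <- which(is.na(vals))[1L]
        stopf("malformed value in '%s' at line %d: '%s'", f, bad, lines[bad])
      }
      if (!is.null(expected_length) && length(vals) != expected_length) {
        stopf("'%s' has %d samples, expected %d", f, length(vals),
              expected_length)
      }
      segments[[length(segments) + 1L]] <- eeg_segment(
        vals, sampling_rate_hz = sampling_rate_hz,
        label = bonn_set_label(canon),
        source_id = file.path(basename(sub), basename(f))
      )
    }
  }
  if (!length(segments)) warning("no segments read")
  segments
}

#' Write EEG segments as a Bonn-layout plain-text directory
#'
#' Inverse of [read_bonn_directory()]: writes one file per segment, one
#' sample value per line, into a subdirectory per class (`"normal"` maps to
#' set `A`, `"epileptic"` to set `E` by default).
#'
#' @param segments List of [eeg_segment] objects.
#' @param path Output directory (created if missing).
#' @param set_for_label Named character vector mapping labels to set names.
#' @return `path`, invisibly.
#' @export
write_bonn_directory <- function(segments, path,
                                 set_for_label = c(normal = "A",
                                                   epileptic = "E")) {
  counters <- new.env(parent = emptyenv())
  for (seg in segments) {
    if (is.na(seg$label)) stopf("cannot export unlabeled segment")
    set <- set_for_label[[seg$label]]
    dir.create(file.path(path, set), recursive = TRUE, showWarnings = FALSE)
    n <- (if (is.null(counters[[set]])) 0L else counters[[set]]) + 1L
    counters[[set]] <- n
    writeLines(format(seg$samples, digits = 10, scientific = FALSE,
                      trim = TRUE),
               file.path(path, set, sprintf("%s%03d.txt", set, n)))
  }
  invisible(path)
}
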