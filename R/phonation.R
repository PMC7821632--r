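#' Construct a phonation object
#'
#' A phonation is a mono sampled waveform with provenance metadata: who
#' produced it, when (trial week), in which session slot, and under which
#' loudness instruction. All signal-processing stages in the package accept
#' and return phonations.
#'
#' @param samples numeric vector of waveform samples in \[-1, 1\].
#' @param sample_rate sampling frequency in Hz.
#' @param subject_id optional subject identifier.
#' @param sex "male" or "female" (used by F0-normative features).
#' @param week trial week of the recording.
#' @param slot session slot 1-6; slots 1-4 are comfortable loudness, 5-6 loud.
#' @param loudness "comfortable" or "loud".
#' @param bit_depth nominal bit depth of the source recording.
#' @param meta free-form list of extra metadata (e.g. synthesis bookkeeping).
#' @return an object of class `phonation`.
#' @export
phonation <- function(samples, sample_rate, subject_id = NA_character_,
                      sex = NA_character_, week = NA_integer_,
                      slot = NA_integer_, loudness = NA_character_,
                      bit_depth = 16L, meta = list()) {
  stopifnot(is.numeric(samples), length(samples) > 0L,
            is.numeric(sample_rate), sample_rate > 0)
  structure(list(samples = as.numeric(samples),
                 sample_rate = as.numeric(sample_rate),
                 subject_id = subject_id, sex = sex,
                 week = week, slot = slot, loudness = loudness,
                 bit_depth = bit_depth, meta = meta),
            class = "phonation")
}

#' @export
print.phonation <- function(x, ...) {
  cat(sprintf("<phonation> %.2f s @ %g Hz", duration(x), x$sample_rate))
  if (!is.na(x$subject_id))
    cat(sprintf("  subject=%s sex=%s week=%s slot=%s (%s)",
                x$subject_id, x$sex, x$week, x$slot, x$loudness))
  cat("\n")
  invisible(x)
}

#' Duration of a phonation in seconds
#' @param x a `phonation`.
#' @return duration in seconds.
#' @export
duration <- function(x) length(x$samples) / x$sample_rate

#' Write a phonation as a 16-bit PCM mono WAV file
#'
#' @param x a `phonation`; samples are clipped to \[-1, 1\].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path) {
  stopifnot(inherits(x, "phonation"))
  s <- pmin(pmax(x$samples, -1), 1)
  pcm <- as.integer(round(s * 32767))
  fs <- as.integer(round(x$sample_rate))
  n <- length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + 2L * n), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")      # PCM
  writeBin(1L, con, size = 2, endian = "little")      # mono
  writeBin(fs, con, size = 4, endian = "little")
  writeBin(as.integer(fs * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2L * n), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM mono WAV file as a phonation
#'
#' @param path WAV file path (PCM, mono, 16-bit).
#' @return a `phonation`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAV file: ", path)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  fs <- NULL; nchan <- NULL; bits <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0L || nchar(id) < 4L) stop("no data chunk in ", path)
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      nchan <- fmt[2]
      fs <- readBin(con, "integer", 1, size = 4, endian = "little")
      invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
      invisible(readBin(con, "integer", 1, size = 2, endian = "little"))
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (sz > 16L) invisible(readBin(con, "raw", sz - 16L))
    } else if (identical(id, "data")) {
      if (is.null(fs)) stop("data chunk before fmt chunk in ", path)
      if (nchan != 1L || bits != 16L)
        stop("only 16-bit PCM mono WAV supported")
      pcm <- readBin(con, "integer", sz / 2L, size = 2, signed = TRUE,
                     endian = "little")
      return(phonation(pcm / 32768, fs))
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2L))
    }
  }
}
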