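#' Read a PCM WAV file
#'
#' Reads an uncompressed RIFF/WAVE file into an [AudioRecording-class].
#' Integer PCM samples (8/16/24/32-bit) are rescaled to \[-1, 1\]; IEEE float
#' WAVs are read as-is. Stereo (or higher channel-count) input is downmixed
#' to mono by channel averaging, with a warning.
#'
#' @param path path to a `.wav` file.
#' @param subject,task,state optional metadata attached to the recording.
#' @return An [AudioRecording-class].
#' @seealso [writeWav()]
#' @export
readWav <- function(path, subject = NA_character_, task = NA_character_,
                    state = NA_character_) {
  if (!file.exists(path)) stop("WAV file not found: ", path)
  if (file.size(path) < 44) stop("not a valid WAV file (too short): ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE"))
    stop("not a RIFF/WAVE file: ", path)
  fmt <- NULL
  dat <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw <- readBin(con, "raw", sz + sz %% 2)
      fmt <- list(
        audioFormat = .le16(raw, 1), nChannels = .le16(raw, 3),
        sampleRate = .le32(raw, 5), bitsPerSample = .le16(raw, 15))
      if (fmt$audioFormat == 65534L && sz >= 40) # WAVE_FORMAT_EXTENSIBLE
        fmt$audioFormat <- .le16(raw, 25)
    } else if (identical(id, "data")) {
      dat <- readBin(con, "raw", sz)
      if (sz %% 2) invisible(readBin(con, "raw", 1))
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2))
    }
    if (!is.null(fmt) && !is.null(dat)) break
  }
  if (is.null(fmt) || is.null(dat))
    stop("corrupt WAV file (missing fmt/data chunk): ", path)
  bps <- fmt$bitsPerSample
  x <- if (fmt$audioFormat == 1L) {
    switch(as.character(bps),
      "8" = (as.numeric(readBin(dat, "integer", length(dat), 1,
                                signed = FALSE)) - 128) / 128,
      "16" = readBin(dat, "integer", length(dat) %/% 2, 2,
                     signed = TRUE, endian = "little") / 32768,
      "24" = .read24(dat) / 8388608,
      "32" = readBin(dat, "integer", length(dat) %/% 4, 4,
                     endian = "little") / 2147483648,
      stop("unsupported PCM bit depth: ", bps))
  } else if (fmt$audioFormat == 3L) {
    readBin(dat, "double", length(dat) %/% (bps %/% 8), bps %/% 8,
            endian = "little")
  } else {
    stop("unsupported (non-PCM) WAV format code: ", fmt$audioFormat)
  }
  if (fmt$nChannels > 1L) {
    warning("downmixing ", fmt$nChannels, "-channel WAV to mono")
    x <- colMeans(matrix(x, nrow = fmt$nChannels))
  }
  AudioRecording(pmin(1, pmax(-1, x)), fmt$sampleRate,
                 subject = subject, task = task, state = state)
}

.le16 <- function(raw, i) as.integer(raw[i]) + 256L * as.integer(raw[i + 1])
.le32 <- function(raw, i) {
  as.integer(raw[i]) + 256 * as.integer(raw[i + 1]) +
    65536 * as.integer(raw[i + 2]) + 16777216 * as.integer(raw[i + 3])
}
.read24 <- function(raw) {
  n <- length(raw) %/% 3
  m <- matrix(as.integer(raw[seq_len(3 * n)]), nrow = 3)
  v <- m[1, ] + 256 * m[2, ] + 65536 * m[3, ]
  ifelse(v >= 8388608, v - 16777216, v)
}

#' Write an AudioRecording as 16-bit PCM WAV
#'
#' @param rec an [AudioRecording-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [readWav()]
#' @export
writeWav <- function(rec, path) {
  stopifnot(is(rec, "AudioRecording"))
  x <- pmin(1, pmax(-1, samples(rec)))
  pcm <- as.integer(pmin(32767, pmax(-32768, round(x * 32768))))
  nBytes <- 2L * length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + nBytes), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(1L, con, 2, endian = "little")                  # PCM
  writeBin(1L, con, 2, endian = "little")                  # mono
  sr <- as.integer(round(sampleRate(rec)))
  writeBin(sr, con, 4, endian = "little")
  writeBin(sr * 2L, con, 4, endian = "little")             # byte rate
  writeBin(2L, con, 2, endian = "little")                  # block align
  writeBin(16L, con, 2, endian = "little")                 # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(nBytes, con, 4, endian = "little")
  writeBin(pcm, con, 2, endian = "little")
  invisible(path)
}
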