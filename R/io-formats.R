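## Minimal binary format support for fixtures: 16-bit PCM mono/stereo WAV
## and NPY v1.0 double matrices (with a JSON sidecar carrying EEG
## metadata). Only the subsets needed by the pipeline are implemented.

#' Write a mono waveform to a 16-bit PCM WAV file
#'
#' Samples are clipped to [-1, 1] and quantized to 16 bits.
#'
#' @param audio an [AudioTrack-class] or numeric vector in [-1, 1].
#' @param path output file path.
#' @param rateHz sampling rate (taken from the AudioTrack if given).
#' @return `path`, invisibly.
#' @export
writeWav <- function(audio, path, rateHz = NULL) {
  if (is(audio, "AudioTrack")) {
    rateHz <- audio@rateHz
    x <- audio@data
  } else {
    x <- as.numeric(audio)
    if (is.null(rateHz)) stop("rateHz required for a bare vector")
  }
  con <- file(path, "wb")
  on.exit(close(con))
  pcm <- as.integer(round(pmax(-1, pmin(1, x)) * 32767))
  nBytes <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + nBytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")          # PCM
  writeBin(1L, con, size = 2, endian = "little")          # mono
  writeBin(as.integer(rateHz), con, size = 4, endian = "little")
  writeBin(as.integer(rateHz) * 2L, con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")          # block align
  writeBin(16L, con, size = 2, endian = "little")         # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(nBytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM WAV file
#'
#' @param path WAV file path.
#' @return an [AudioTrack-class] (stereo is mixed down to mono).
#' @export
readWav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF/WAV file: ", path)
  readBin(con, integer(), size = 4, endian = "little")
  if (readChar(con, 4) != "WAVE") stop("not a WAV file: ", path)
  rate <- NULL; bits <- NULL; channels <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      if (fmt[1] != 1L) stop("only PCM WAV supported")
      channels <- fmt[2]
      rate <- readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 2, endian = "little")
      bits <- readBin(con, integer(), size = 2, endian = "little")
      if (size > 16L) readBin(con, raw(), n = size - 16L)
    } else if (id == "data") {
      if (is.null(bits)) stop("malformed WAV: data before fmt")
      if (bits != 16L) stop("only 16-bit PCM supported")
      samples <- readBin(con, integer(), n = size %/% 2L, size = 2,
                         endian = "little", signed = TRUE)
      break
    } else {
      readBin(con, raw(), n = size)
    }
  }
  if (is.null(samples)) stop("no data chunk in WAV: ", path)
  x <- samples / 32767
  if (channels > 1L) {
    x <- colMeans(matrix(x, nrow = channels))
  }
  AudioTrack(x, rate)
}

#' Write a numeric matrix as NPY (v1.0, float64, C order)
#'
#' @param mat numeric matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeNpy <- function(mat, path) {
  mat <- as.matrix(mat)
  header <- sprintf("{'descr': '<f8', 'fortran_order': False, 'shape': (%d, %d), }",
                    nrow(mat), ncol(mat))
  ## pad so that magic(6) + version(2) + len(2) + header is a multiple of 64
  pad <- 64L - ((10L + nchar(header) + 1L) %% 64L)
  header <- paste0(header, strrep(" ", pad), "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(as.raw(0x93), charToRaw("NUMPY"), as.raw(c(1, 0))), con)
  writeBin(as.integer(nchar(header)), con, size = 2, endian = "little")
  writeChar(header, con, eos = NULL)
  writeBin(as.numeric(t(mat)), con, size = 8, endian = "little")  # C order
  invisible(path)
}

#' Read an NPY file written by [writeNpy()] (or NumPy, float64 2-D)
#'
#' @param path NPY file path.
#' @return numeric matrix.
#' @export
readNpy <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, raw(), n = 6)
  if (!identical(magic, c(as.raw(0x93), charToRaw("NUMPY"))))
    stop("not an NPY file: ", path)
  ver <- readBin(con, raw(), n = 2)
  hlen <- readBin(con, integer(), size = 2, endian = "little", signed = FALSE)
  header <- readChar(con, hlen, useBytes = TRUE)
  if (!grepl("'<f8'", header)) stop("only float64 NPY supported")
  fortran <- grepl("'fortran_order':\\s*True", header)
  shp <- regmatches(header, regexpr("\\(([0-9, ]*)\\)", header))
  dims <- as.integer(strsplit(gsub("[() ]", "", shp), ",")[[1]])
  if (length(dims) == 1L) dims <- c(dims, 1L)
  if (length(dims) != 2L) stop("only 1-D/2-D NPY supported")
  vals <- readBin(con, numeric(), n = prod(dims), size = 8,
                  endian = "little")
  if (length(vals) != prod(dims)) stop("truncated NPY file: ", path)
  if (fortran) matrix(vals, nrow = dims[1]) else
    t(matrix(vals, nrow = dims[2]))
}
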