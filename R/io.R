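#' Write an impulse response as a float WAV file
#'
#' Minimal RIFF/WAVE writer: one channel of IEEE float32 samples at the
#' impulse response's sampling rate (format tag 3, with the `fact` chunk
#' required for non-PCM data).
#'
#' @param ir An `impulse_response`.
#' @param path Output `.wav` path.
#' @param normalize Scale the peak to 0.9 full scale (default `TRUE`;
#'   raw amplitudes are typically tiny).
#' @return `path`, invisibly.
#' @export
write_echo_wav <- function(ir, path, normalize = TRUE) {
  stopifnot(inherits(ir, "impulse_response"))
  fs <- attr(ir, "fs")
  x <- ir$amplitude
  if (normalize && max(abs(x)) > 0) x <- 0.9 * x / max(abs(x))
  n <- length(x)
  data_bytes <- 4L * n
  con <- file(path, "wb")
  on.exit(close(con))
  w_str <- function(s) writeBin(charToRaw(s), con)
  w_u32 <- function(v) writeBin(as.integer(v), con, size = 4, endian = "little")
  w_u16 <- function(v) writeBin(as.integer(v), con, size = 2, endian = "little")
  w_str("RIFF"); w_u32(4 + 24 + 12 + 8 + data_bytes); w_str("WAVE")
  w_str("fmt "); w_u32(16)
  w_u16(3); w_u16(1)                     # IEEE float, mono
  w_u32(fs); w_u32(fs * 4)               # sample rate, byte rate
  w_u16(4); w_u16(32)                    # block align, bits per sample
  w_str("fact"); w_u32(4); w_u32(n)
  w_str("data"); w_u32(data_bytes)
  writeBin(as.numeric(x), con, size = 4, endian = "little")
  invisible(path)
}

#' Write an impulse response as CSV
#'
#' Columns `time` (s) and `amplitude`.
#'
#' @param ir An `impulse_response`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_impulse_csv <- function(ir, path) {
  utils::write.csv(as.data.frame(ir), path, row.names = FALSE)
  invisible(path)
}

#' Write an echo spectrum as CSV
#'
#' Columns `f` (Hz), `re`, `im`.
#'
#' @param spectrum An `echo_spectrum`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  utils::write.csv(as.data.frame(spectrum), path, row.names = FALSE)
  invisible(path)
}
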