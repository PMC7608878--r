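#' Derive a reproducible sub-seed
#'
#' Stable counter-based derivation used throughout the package (per species,
#' per tree, per pose): a linear congruential mix of the master seed and an
#' index, kept within the 32-bit integer range. The mapping is fixed across
#' versions so archived runs stay reproducible.
#'
#' @param master Master seed (integer).
#' @param index Counter (integer).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, index) {
  as.integer((as.double(master) * 48271 + as.double(index) * 104729) %% 2147483647)
}

# magnitude of the analytic signal (FFT-based Hilbert transform)
signal_envelope <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  w <- numeric(n)
  w[1] <- 1
  if (n %% 2 == 0) {
    w[n / 2 + 1] <- 1
    w[2:(n / 2)] <- 2
  } else {
    w[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * w, inverse = TRUE) / n)
}
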