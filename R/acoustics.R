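#' Sonar beam pose and Gaussian mainlobe
#'
#' A monostatic sonar (emitter and receiver co-located) at `position`,
#' looking along `boresight`, with a 2-D Gaussian mainlobe approximating a
#' bat's beampattern. The full -3 dB beamwidths (read on the amplitude gain
#' in dB, `20*log10(S/A0)`) determine the Gaussian spreads via
#' `sigma = (width/2) / sqrt((3/10) * ln 10)`, so the gain at half the
#' beamwidth off boresight is `A0 * 10^(-3/20)`.
#'
#' @param position Sonar position, length-3 (m).
#' @param boresight Beam direction (need not be unit length).
#' @param beamwidth_az,beamwidth_el Full -3 dB beamwidths (radians);
#'   elevation defaults to azimuth.
#' @param A0 Peak amplitude gain on boresight.
#' @param up Reference up vector defining the beam frame (default +z).
#' @return An object of class `sonar_beam` with the orthonormal beam frame
#'   and derived spreads `sigma_az`, `sigma_el`.
#' @export
sonar_beam <- function(position, boresight, beamwidth_az,
                       beamwidth_el = beamwidth_az, A0 = 1, up = c(0, 0, 1)) {
  stopifnot(length(position) == 3, length(boresight) == 3,
            beamwidth_az > 0, beamwidth_az < pi,
            beamwidth_el > 0, beamwidth_el < pi, A0 > 0)
  bx <- vunit(as.numeric(boresight))
  if (abs(sum(bx * vunit(up))) > 1 - 1e-9) up <- c(1, 0, 0)
  by <- vunit(vcross(vunit(up), bx))   # horizontal (azimuth) axis
  bz <- vcross(bx, by)                 # vertical (elevation) axis
  k <- sqrt(0.3 * log(10))             # -3 dB amplitude contour in sigmas
  structure(
    list(position = as.numeric(position), boresight = bx,
         frame = unname(rbind(bx, by, bz)), A0 = A0,
         beamwidth_az = beamwidth_az, beamwidth_el = beamwidth_el,
         sigma_az = (beamwidth_az / 2) / k, sigma_el = (beamwidth_el / 2) / k),
    class = "sonar_beam"
  )
}

#' @export
print.sonar_beam <- function(x, ...) {
  cat(sprintf("<sonar_beam> at (%.2f, %.2f, %.2f), -3 dB widths %.1f x %.1f deg\n",
              x$position[1], x$position[2], x$position[3],
              x$beamwidth_az * 180 / pi, x$beamwidth_el * 180 / pi))
  invisible(x)
}

#' Emission frequency band and sampling grid
#'
#' The emitted call occupies a flat band between `f_lo` and `f_hi`,
#' defaulting to 60-80 kHz: the terminal frequency-modulated part of a
#' greater horseshoe bat call. The spectrum is laid out on an FFT grid of
#' `n_fft` bins at sampling rate `fs`, giving a time record of
#' `n_fft / fs` seconds.
#'
#' @param f_lo,f_hi Band edges (Hz).
#' @param fs Sampling rate (Hz), must exceed `2 * f_hi`.
#' @param n_fft Spectrum length, a power of two.
#' @param v Speed of sound (m/s).
#' @param taper `"rectangular"` (flat band, default) or `"raised-cosine"`
#'   (cosine ramps over the outer 10% of the band to suppress ringing).
#' @return An object of class `frequency_band`.
#' @export
frequency_band <- function(f_lo = 60e3, f_hi = 80e3, fs = 400e3,
                           n_fft = 4096, v = 343,
                           taper = c("rectangular", "raised-cosine")) {
  taper <- match.arg(taper)
  stopifnot(f_lo > 0, f_lo < f_hi, fs > 2 * f_hi, v > 0, n_fft >= 8)
  if (bitwAnd(n_fft, n_fft - 1L) != 0L) {
    stop("n_fft must be a power of two", call. = FALSE)
  }
  structure(
    list(f_lo = f_lo, f_hi = f_hi, fs = fs, n_fft = as.integer(n_fft),
         v = v, taper = taper),
    class = "frequency_band"
  )
}

# positive-frequency grid (bins 0 .. n_fft/2) and in-band mask with taper
band_grid <- function(band) {
  k <- 0:(band$n_fft / 2)
  f <- k * band$fs / band$n_fft
  in_band <- f >= band$f_lo & f <= band$f_hi
  w <- as.numeric(in_band)
  if (band$taper == "raised-cosine" && any(in_band)) {
    ramp <- 0.1 * (band$f_hi - band$f_lo)
    fi <- f[in_band]
    up <- pmin((fi - band$f_lo) / ramp, 1)
    down <- pmin((band$f_hi - fi) / ramp, 1)
    w[in_band] <- 0.5 * (1 - cos(pi * up)) * 0.5 * (1 - cos(pi * down))
  }
  list(f = f, in_band = in_band, weight = w)
}

#' Reflector geometry as seen from the sonar
#'
#' For every leaf disc: the range `r` from the sonar to the disc centre, the
#' azimuth and elevation of the disc in the beam frame (`az = atan2` of the
#' horizontal component, `el = arcsin` of the vertical component), the
#' incident angle `beta` between the disc normal and the disc-to-sonar
#' direction folded to `[0, pi/2]` (discs are two-sided), and the disc
#' radius `a`.
#'
#' @param beam A [sonar_beam()].
#' @param discs A `leaf_discs` tibble.
#' @return A tibble of class `reflector_view` with columns `r`, `az`, `el`,
#'   `beta`, `a`.
#' @export
reflector_view <- function(beam, discs) {
  stopifnot(inherits(beam, "sonar_beam"))
  if (nrow(discs) == 0) {
    return(structure(tibble::tibble(r = numeric(0), az = numeric(0),
                                    el = numeric(0), beta = numeric(0),
                                    a = numeric(0)),
                     class = c("reflector_view", class(tibble::tibble()))))
  }
  d <- cbind(discs$x - beam$position[1],
             discs$y - beam$position[2],
             discs$z - beam$position[3])
  r <- sqrt(rowSums(d^2))
  if (any(r == 0)) stop("disc centre coincides with the sonar position",
                        call. = FALSE)
  u <- d / r
  comp <- u %*% t(beam$frame)   # columns: boresight, azimuth, elevation
  az <- atan2(comp[, 2], comp[, 1])
  el <- asin(pmin(pmax(comp[, 3], -1), 1))
  n <- cbind(discs$nx, discs$ny, discs$nz)
  cosb <- abs(rowSums(n * (-u)))
  beta <- acos(pmin(pmax(cosb, 0), 1))
  out <- tibble::tibble(r = r, az = az, el = el, beta = beta, a = discs$radius)
  class(out) <- c("reflector_view", class(out))
  out
}

#' Gaussian beampattern gain
#'
#' `S(az, el) = A0 * exp{-[az^2 / (2 sigma_az^2) + el^2 / (2 sigma_el^2)]}`
#' with the boresight at `(0, 0)` in the beam frame.
#'
#' @param beam A [sonar_beam()].
#' @param az,el Angles in the beam frame (radians, vectorized).
#' @return Nonnegative amplitude gain.
#' @export
beam_gain <- function(beam, az, el) {
  beam$A0 * exp(-(az^2 / (2 * beam$sigma_az^2) + el^2 / (2 * beam$sigma_el^2)))
}

#' Leaf (disc reflector) beampattern gain
#'
#' Cosine approximation to the backscatter of a circular disc of radius `a`
#' at incident angle `beta`: `L = P1(c) * cos(P2(c) * beta)` with
#' `c = 2 pi a f / v`, `P1(c) = 0.5003 c^2 + 0.6867` and
#' `P2(c) = 0.3999 c^-0.9065 + 0.9979` (fits to numerical disc-scattering
#' evaluations). Beyond the first zero of the cosine the fit is
#' extrapolated and would go negative; by default the gain is clamped at 0.
#'
#' @param beta Incident angle in `[0, pi/2]` (radians, vectorized).
#' @param a Disc radius (m), > 0.
#' @param f Frequency (Hz), > 0 (`c = 0` is excluded: P2 diverges).
#' @param v Speed of sound (m/s).
#' @param clamp Clamp negative gains to zero (default `TRUE`).
#' @return Amplitude gain.
#' @export
leaf_gain <- function(beta, a, f, v = 343, clamp = TRUE) {
  if (any(a <= 0)) stop("disc radius must be positive", call. = FALSE)
  if (any(f <= 0)) stop("frequency must be positive", call. = FALSE)
  cc <- 2 * pi * a * f / v
  L <- leaf_p1(cc) * cos(leaf_p2(cc) * beta)
  if (clamp) pmax(L, 0) else L
}

#' Fitted disc-scattering polynomials
#'
#' `leaf_p1(c) = 0.5003 c^2 + 0.6867` scales the peak backscatter;
#' `leaf_p2(c) = 0.3999 c^-0.9065 + 0.9979` sets how fast the gain falls
#' with incident angle. `c = 2 pi a f / v` is the disc circumference in
#' wavelengths.
#'
#' @param c_ Dimensionless size parameter, > 0 for `leaf_p2`.
#' @return Polynomial value.
#' @export
leaf_p1 <- function(c_) 0.5003 * c_^2 + 0.6867

#' @rdname leaf_p1
#' @export
leaf_p2 <- function(c_) 0.3999 * c_^(-0.9065) + 0.9979

#' Mainlobe membership test
#'
#' A reflector is inside the mainlobe iff it lies within the closed -3 dB
#' ellipse, i.e. where the amplitude gain is at least `A0 * 10^(-3/20)`:
#' `az^2 / (2 sigma_az^2) + el^2 / (2 sigma_el^2) <= (3/20) ln 10`, whose
#' on-axis crossings are exactly `az = +/- beamwidth_az / 2`. Reflectors
#' outside the forward hemisphere (`|az| > pi/2`) are excluded regardless of
#' beamwidth.
#'
#' @param beam A [sonar_beam()].
#' @param az,el Beam-frame angles (radians, vectorized).
#' @return Logical vector.
#' @export
in_mainlobe <- function(beam, az, el) {
  q <- az^2 / (2 * beam$sigma_az^2) + el^2 / (2 * beam$sigma_el^2)
  q <= 0.15 * log(10) + 1e-12 & abs(az) <= pi / 2
}

#' Per-facet echo amplitude
#'
#' `A = S(az, el) * L(beta, a, f) * lambda_f / (2 pi r^2)` with
#' `lambda_f = v / f`: beampattern gain times disc gain times spherical
#' spreading over the round trip.
#'
#' @param view A `reflector_view` tibble (or any data frame with `r`, `az`,
#'   `el`, `beta`, `a`).
#' @param beam A [sonar_beam()].
#' @param f Frequency (Hz, scalar).
#' @param band A [frequency_band()] (supplies the sound speed).
#' @return Nonnegative amplitude per reflector.
#' @export
facet_amplitude <- function(view, beam, f, band = frequency_band()) {
  beam_gain(beam, view$az, view$el) *
    leaf_gain(view$beta, view$a, f, band$v) * (band$v / f) / (2 * pi * view$r^2)
}

#' Per-facet phase delay
#'
#' Monostatic round-trip propagation phase `phi = 2 pi f (2 r) / v`: the
#' echo of a reflector at range `r` arrives after the two-way delay
#' `2 r / v`.
#'
#' @param r Range (m, vectorized), > 0.
#' @param f Frequency (Hz).
#' @param v Speed of sound (m/s).
#' @return Phase in radians (not reduced mod 2 pi).
#' @export
facet_phase <- function(r, f, v = 343) {
  if (any(r <= 0)) stop("range must be positive", call. = FALSE)
  2 * pi * f * (2 * r) / v
}

#' Synthesize the frequency-domain echo
#'
#' For each in-band frequency `f_k`, the Fourier component is the
#' superposition of the echoes of the `m` reflectors inside the mainlobe:
#' `y*_k = sum_i A_ki cos(phi_ki) - j sum_i A_ki sin(phi_ki)` with the
#' round-trip phase delay `phi_ki` of [facet_phase()]. The negative
#' imaginary sign matches the forward-DFT kernel `e^(-j 2 pi f t)`, so the
#' inverse transform places each echo at its physical delay `2 r / v`.
#' Components outside the band are zero. Shading between leaves is
#' neglected, so the spectrum is exactly linear in the disc set.
#'
#' @param beam A [sonar_beam()].
#' @param discs A `leaf_discs` tibble (field coordinates).
#' @param band A [frequency_band()].
#' @return A tibble of class `echo_spectrum` with columns `f`, `re`, `im`
#'   over the positive-frequency grid; attributes `band` and `m` (number of
#'   in-mainlobe reflectors).
#' @export
synthesize_spectrum <- function(beam, discs, band = frequency_band()) {
  stopifnot(inherits(beam, "sonar_beam"), inherits(band, "frequency_band"))
  g <- band_grid(band)
  y <- complex(length(g$f))
  m <- 0L
  if (nrow(discs) > 0) {
    view <- reflector_view(beam, discs)
    keep <- in_mainlobe(beam, view$az, view$el)
    view <- view[keep, , drop = FALSE]
    m <- nrow(view)
    if (m > 0) {
      kk <- which(g$in_band)
      fk <- g$f[kk]
      S <- beam_gain(beam, view$az, view$el)
      cc <- outer(view$a, fk) * (2 * pi / band$v)          # m x K
      L <- pmax(leaf_p1(cc) * cos(leaf_p2(cc) * view$beta), 0)
      A <- (S / (2 * pi * view$r^2)) * L *
        matrix(band$v / fk, nrow = m, ncol = length(fk), byrow = TRUE)
      phi <- outer(view$r, fk) * (4 * pi / band$v)
      y[kk] <- colSums(A * exp(-1i * phi)) * g$weight[kk]
    }
  }
  out <- tibble::tibble(f = g$f, re = Re(y), im = Im(y))
  attr(out, "band") <- band
  attr(out, "m") <- m
  class(out) <- c("echo_spectrum", class(out))
  out
}

#' Time-domain impulse response by inverse FFT
#'
#' Fills the negative-frequency bins with the complex conjugates of the
#' positive ones (conjugate symmetry), applies the inverse FFT and returns
#' the real part; the imaginary residue must be below 1e-10 of the peak
#' magnitude. The time origin is the emission instant, so a reflector at
#' range `r` peaks near sample `fs * 2 r / v`.
#'
#' @param spectrum An `echo_spectrum` from [synthesize_spectrum()].
#' @param band The [frequency_band()] the spectrum was computed on
#'   (defaults to the one recorded in the spectrum).
#' @return A tibble of class `impulse_response` with columns `time` (s) and
#'   `amplitude`; attributes `fs` and `m`.
#' @export
impulse_response <- function(spectrum, band = attr(spectrum, "band")) {
  stopifnot(inherits(spectrum, "echo_spectrum"), inherits(band, "frequency_band"))
  n <- band$n_fft
  if (nrow(spectrum) != n / 2 + 1 ||
      abs(spectrum$f[2] - band$fs / n) > 1e-6) {
    stop("spectrum grid does not match the band", call. = FALSE)
  }
  half <- complex(real = spectrum$re, imaginary = spectrum$im)
  full <- complex(n)
  full[1:(n / 2 + 1)] <- half
  full[1] <- Re(half[1])
  full[n / 2 + 1] <- Re(half[n / 2 + 1])
  full[(n / 2 + 2):n] <- Conj(half[seq(n / 2, 2)])
  y <- stats::fft(full, inverse = TRUE) / n
  peak <- max(Mod(y))
  if (peak > 0 && max(abs(Im(y))) > 1e-10 * peak) {
    stop("inverse FFT left a non-real residue", call. = FALSE)
  }
  out <- tibble::tibble(time = (seq_len(n) - 1) / band$fs, amplitude = Re(y))
  attr(out, "fs") <- band$fs
  attr(out, "m") <- attr(spectrum, "m")
  class(out) <- c("impulse_response", class(out))
  out
}

#' Echo envelope
#'
#' Magnitude of the analytic signal of an impulse response, used to locate
#' and measure arrival peaks.
#'
#' @param ir An `impulse_response`.
#' @return Numeric vector of envelope samples.
#' @export
echo_envelope <- function(ir) {
  stopifnot(inherits(ir, "impulse_response"))
  signal_envelope(ir$amplitude)
}

#' Count reflectors inside the mainlobe
#'
#' @param beam A [sonar_beam()].
#' @param discs A `leaf_discs` tibble.
#' @return Integer count `m`.
#' @export
count_in_mainlobe <- function(beam, discs) {
  if (nrow(discs) == 0) return(0L)
  view <- reflector_view(beam, discs)
  sum(in_mainlobe(beam, view$az, view$el))
}
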