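disc_at <- function(x, y, z, nx = -1, ny = 0, nz = 0, radius = 0.05) {
  n <- sqrt(nx^2 + ny^2 + nz^2)
  tibble::tibble(x = x, y = y, z = z, radius = radius,
                 nx = nx / n, ny = ny / n, nz = nz / n)
}

beam_x <- function(bw_deg = 40, A0 = 1, position = c(0, 0, 0)) {
  sonar_beam(position, c(1, 0, 0), beamwidth_az = bw_deg * pi / 180, A0 = A0)
}

test_that("reflector geometry reduces to the axis-aligned cases", {
  beam <- beam_x()
  v <- reflector_view(beam, disc_at(1, 0, 0))
  expect_equal(c(v$r, v$az, v$el, v$beta), c(1, 0, 0, 0), tolerance = 1e-12)
  # normal perpendicular to the line of sight
  v2 <- reflector_view(beam, disc_at(1, 0, 0, nx = 0, ny = 1))
  expect_equal(v2$beta, pi / 2, tolerance = 1e-12)
  # two-sided discs: flipping the normal leaves beta unchanged
  v3 <- reflector_view(beam, disc_at(1, 0, 0, nx = 1))
  expect_equal(v3$beta, v$beta)
  # behind the sonar: |az| > pi/2, culled from the mainlobe
  v4 <- reflector_view(beam, disc_at(-1, 0, 0))
  expect_gt(abs(v4$az), pi / 2)
  expect_false(in_mainlobe(beam, v4$az, v4$el))
  expect_error(reflector_view(beam, disc_at(0, 0, 0)), "coincides")
})

test_that("Gaussian beampattern honours the -3 dB amplitude convention", {
  beam <- beam_x(bw_deg = 40, A0 = 2)
  expect_equal(beam_gain(beam, 0, 0), 2)
  half <- 20 * pi / 180
  expect_equal(beam_gain(beam, half, 0), 2 * 10^(-3 / 20), tolerance = 1e-12)
  expect_equal(beam_gain(beam, 0, half), 2 * 10^(-3 / 20), tolerance = 1e-12)
  # symmetry in both angles
  expect_equal(beam_gain(beam, 0.2, 0.1), beam_gain(beam, -0.2, 0.1))
  expect_equal(beam_gain(beam, 0.2, 0.1), beam_gain(beam, 0.2, -0.1))
  # the -3 dB contour itself is inside the mainlobe (closed contour)
  expect_true(in_mainlobe(beam, half, 0))
  expect_false(in_mainlobe(beam, half * 1.01, 0))
})

test_that("disc gain follows the fitted cosine model", {
  # beta = 0: gain is P1(c) regardless of c
  for (cc in c(0.3, 1, 4)) {
    f <- cc * 343 / (2 * pi * 0.05)
    expect_equal(leaf_gain(0, 0.05, f), 0.5003 * cc^2 + 0.6867,
                 tolerance = 1e-12)
  }
  # printed-fit evaluation at c = 1, beta = 0.5 rad
  f1 <- 343 / (2 * pi * 0.05)
  expect_equal(leaf_gain(0.5, 0.05, f1), 1.1870 * cos(1.3978 * 0.5),
               tolerance = 1e-12)
  # clamped where the extrapolated cosine goes negative
  expect_equal(leaf_gain(pi / 2, 0.05, f1), 0)
  expect_lt(leaf_gain(pi / 2, 0.05, f1, clamp = FALSE), 0)
  expect_error(leaf_gain(0.1, -1, 60e3), "radius")
  expect_error(leaf_gain(0.1, 0.05, 0), "frequency")
})

test_that("facet amplitude composes beam gain, disc gain and spreading", {
  band <- frequency_band()
  beam <- beam_x(A0 = 1.5)
  v1 <- reflector_view(beam, disc_at(1, 0, 0))
  v2 <- reflector_view(beam, disc_at(2, 0, 0))
  f <- 70e3
  a1 <- facet_amplitude(v1, beam, f, band)
  a2 <- facet_amplitude(v2, beam, f, band)
  expect_equal(a1 / a2, 4, tolerance = 1e-12)  # inverse-square law
  # on boresight with beta = 0: A = A0 * P1(c) * v / (2 pi f r^2)
  cc <- 2 * pi * 0.05 * f / band$v
  expect_equal(a1, 1.5 * (0.5003 * cc^2 + 0.6867) * band$v / (2 * pi * f),
               tolerance = 1e-12)
})

test_that("phase is the monostatic round-trip delay", {
  f <- 70e3
  expect_equal(facet_phase(343 / (4 * f), f), pi, tolerance = 1e-12)
  expect_equal(facet_phase(2, f) / facet_phase(1, f), 2)
  # linear regression of phi on f recovers tau = 2 r / v
  r <- 1.7
  fs <- seq(60e3, 80e3, length.out = 50)
  phi <- facet_phase(r, fs)
  fit <- stats::lm(phi ~ fs)
  expect_equal(unname(stats::coef(fit)[2]) / (2 * pi), 2 * r / 343,
               tolerance = 1e-9)
  expect_error(facet_phase(0, f), "range")
})

test_that("band validation rejects unusable grids", {
  expect_error(frequency_band(n_fft = 1000), "power of two")
  expect_error(frequency_band(fs = 150e3))   # violates fs > 2 f_hi
  expect_error(frequency_band(f_lo = 90e3))  # violates f_lo < f_hi
})

test_that("spectrum superposes in-mainlobe reflectors and is zero out of band", {
  band <- frequency_band()
  beam <- beam_x()
  spec <- synthesize_spectrum(beam, disc_at(1, 0, 0), band)
  expect_s3_class(spec, "echo_spectrum")
  expect_equal(attr(spec, "m"), 1L)
  out_band <- spec$f < band$f_lo | spec$f > band$f_hi
  expect_true(all(spec$re[out_band] == 0 & spec$im[out_band] == 0))
  # single reflector: modulus equals the amplitude at every in-band bin
  kk <- which(!out_band)
  v <- reflector_view(beam, disc_at(1, 0, 0))
  amp <- vapply(spec$f[kk], function(f) facet_amplitude(v, beam, f, band),
                numeric(1))
  expect_equal(sqrt(spec$re[kk]^2 + spec$im[kk]^2), amp, tolerance = 1e-12)
  # no reflector in the lobe: all-zero spectrum
  empty <- synthesize_spectrum(beam, disc_at(-1, 0, 0), band)
  expect_true(all(empty$re == 0 & empty$im == 0))
  expect_equal(attr(empty, "m"), 0L)
})

test_that("echo synthesis is exactly linear in the disc set", {
  band <- frequency_band()
  beam <- beam_x()
  A <- dplyr::bind_rows(disc_at(1, 0.05, 0.02), disc_at(1.4, -0.1, 0.06))
  B <- dplyr::bind_rows(disc_at(2.1, 0.12, -0.04, ny = 0.4),
                        disc_at(1.8, 0, 0.1, nz = 0.3))
  sAB <- synthesize_spectrum(beam, dplyr::bind_rows(A, B), band)
  sA <- synthesize_spectrum(beam, A, band)
  sB <- synthesize_spectrum(beam, B, band)
  expect_equal(sAB$re, sA$re + sB$re, tolerance = 1e-15)
  expect_equal(sAB$im, sA$im + sB$im, tolerance = 1e-15)
  irAB <- impulse_response(sAB)
  irA <- impulse_response(sA)
  irB <- impulse_response(sB)
  expect_equal(irAB$amplitude, irA$amplitude + irB$amplitude, tolerance = 1e-15)
})

test_that("impulse response peaks at the round-trip delay", {
  band <- frequency_band(fs = 400e3, n_fft = 4096)
  beam <- beam_x()
  ir <- impulse_response(synthesize_spectrum(beam, disc_at(1, 0, 0), band))
  env <- echo_envelope(ir)
  peak_sample <- which.max(env) - 1  # 0-based sample index
  expect_lte(abs(peak_sample - round(400e3 * 2 / 343)), 1)
  # doubling the range attenuates the envelope peak fourfold (within 1%);
  # the 2 m round trip (11.7 ms) needs the longer record to avoid wrap-around
  long <- frequency_band(fs = 400e3, n_fft = 8192)
  env1 <- echo_envelope(impulse_response(synthesize_spectrum(beam, disc_at(1, 0, 0), long)))
  env2 <- echo_envelope(impulse_response(synthesize_spectrum(beam, disc_at(2, 0, 0), long)))
  expect_equal(max(env1) / max(env2), 4, tolerance = 0.01)
  expect_lte(abs((which.max(env2) - 1) - round(400e3 * 4 / 343)), 1)
})

test_that("two discs separated beyond the bandwidth resolution give two peaks", {
  band <- frequency_band()
  beam <- beam_x()
  # resolution limit v / (2 (f_hi - f_lo)) = 8.6 mm; use 0.5 m
  discs <- dplyr::bind_rows(disc_at(1, 0, 0), disc_at(1.5, 0, 0))
  env <- echo_envelope(impulse_response(synthesize_spectrum(beam, discs, band)))
  s1 <- round(400e3 * 2 / 343)
  s2 <- round(400e3 * 3 / 343)
  w <- 30
  p1 <- max(env[(s1 - w):(s1 + w)])
  p2 <- max(env[(s2 - w):(s2 + w)])
  trough <- min(env[(s1 + w):(s2 - w)])
  expect_gt(p1, 5 * trough)
  expect_gt(p2, 5 * trough)
})

test_that("impulse responses are real and Parseval-consistent", {
  band <- frequency_band()
  beam <- beam_x()
  discs <- dplyr::bind_rows(disc_at(1, 0.1, 0), disc_at(1.3, -0.05, 0.08),
                            disc_at(2.2, 0.2, -0.1, ny = 0.5))
  spec <- synthesize_spectrum(beam, discs, band)
  ir <- impulse_response(spec)
  expect_type(ir$amplitude, "double")
  n <- band$n_fft
  # Parseval: time energy equals band energy (positive bins doubled)
  band_energy <- (spec$re[1]^2 + spec$im[1]^2 +
                    spec$re[n / 2 + 1]^2 + spec$im[n / 2 + 1]^2 +
                    2 * sum(spec$re[2:(n / 2)]^2 + spec$im[2:(n / 2)]^2)) / n
  expect_equal(sum(ir$amplitude^2), band_energy, tolerance = 1e-9)
})

test_that("scenes mirrored about the boresight plane echo identically", {
  band <- frequency_band()
  beam <- beam_x()
  scene <- dplyr::bind_rows(disc_at(1, 0.2, 0.05, ny = 0.3, nz = 0.1),
                            disc_at(1.6, -0.1, -0.12, ny = -0.2))
  mirror <- scene
  mirror$y <- -mirror$y
  mirror$ny <- -mirror$ny
  ir <- impulse_response(synthesize_spectrum(beam, scene, band))
  irm <- impulse_response(synthesize_spectrum(beam, mirror, band))
  expect_equal(abs(ir$amplitude), abs(irm$amplitude), tolerance = 1e-12)
})

test_that("enlarging the beamwidth never sheds in-mainlobe reflectors", {
  sk <- lsys_interpret(lsys_expand(default_grammar(), 2), geometry_params(),
                       seed = 21)
  tree <- assemble_tree(sk, make_branch_template(leaf_count = 25, seed = 2),
                        seed = 21)
  discs <- place_tree(tree)
  pos <- canopy_centroid(tree) - c(1.5, 0, 0)  # close enough that the canopy
  aim <- c(1, 0, 0)                            # overfills the narrow beams
  counts <- vapply(c(10, 20, 30, 40, 50, 65), function(bw) {
    beam <- sonar_beam(pos, aim, beamwidth_az = bw * pi / 180)
    count_in_mainlobe(beam, discs)
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
  expect_gt(counts[length(counts)], counts[1])
})

test_that("spectra and impulse responses survive file export", {
  band <- frequency_band()
  beam <- beam_x()
  spec <- synthesize_spectrum(beam, disc_at(1, 0, 0), band)
  ir <- impulse_response(spec)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_impulse_csv(ir, csv)
  expect_equal(nrow(utils::read.csv(csv)), band$n_fft)
  scsv <- withr::local_tempfile(fileext = ".csv")
  write_spectrum_csv(spec, scsv)
  expect_equal(nrow(utils::read.csv(scsv)), band$n_fft / 2 + 1)
  wav <- withr::local_tempfile(fileext = ".wav")
  write_echo_wav(ir, wav)
  con <- file(wav, "rb")
  hdr <- readBin(con, "raw", 12)
  expect_equal(rawToChar(hdr[1:4]), "RIFF")
  expect_equal(rawToChar(hdr[9:12]), "WAVE")
  seek(con, 24)
  expect_equal(readBin(con, "integer", 1, size = 4, endian = "little"), 400000L)
  close(con)
  expect_equal(file.size(wav), 12 + 24 + 12 + 8 + 4 * band$n_fft)
})

test_that("grid mismatches between spectrum and band are rejected", {
  band <- frequency_band()
  beam <- beam_x()
  spec <- synthesize_spectrum(beam, disc_at(1, 0, 0), band)
  other <- frequency_band(n_fft = 2048)
  expect_error(impulse_response(spec, other), "grid")
})
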