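test_that("band edges follow the dyadic halving rule", {
  be <- band_edges(173.61, 4)
  # one-decimal truncation, the convention behind the published edge table
  # (fs/16 = 10.850625 prints as 10.8)
  edges <- setNames(trunc(be$high_hz * 10) / 10, be$subband)
  expect_equal(edges[["A4"]], 5.4)
  expect_equal(edges[["D4"]], 10.8)
  expect_equal(edges[["D3"]], 21.7)
  expect_equal(edges[["D2"]], 43.4)
  expect_equal(edges[["D1"]], 86.8)
  expect_equal(trunc(be$low_hz[be$subband == "D1"] * 10) / 10, 43.4)
  expect_equal(be$low_hz[be$subband == "A4"], 0)

  be2 <- band_edges(64, 2)
  expect_equal(be2$low_hz, c(16, 8, 0))
  expect_equal(be2$high_hz, c(32, 16, 8))

  # each successive level halves the band
  expect_equal(be$high_hz[1:4] / 2, be$low_hz[1:4])
  expect_error(band_edges(-1, 4))
})

test_that("decomposition matches the reference db4 filter-bank values", {
  # frozen independently computed db4 coefficients (symmetric extension)
  ramp_cA <- c(7.064531462580935, 4.2307361111495991, 1.4136071660758236,
               2.8360542803424087, 5.6633905987769202, 8.497185950208257,
               11.314314895282033)
  ramp_cD <- c(0.023713130626226167, 0.040962086395866203,
               -0.064675217022092238, 9.540979117872439e-17,
               -0.023713130626226174, -0.040962086395866425,
               0.064675217022092779)
  flt <- wavelet_filters("db4")
  st <- eegseize:::.dwt_step(as.numeric(1:8), flt, "symmetric")
  expect_equal(st$cA, ramp_cA, tolerance = 1e-12)
  expect_equal(st$cD, ramp_cD, tolerance = 1e-10)

  x32 <- c(1.690526, -0.465937, 0.03282, 0.407516, -0.788923, 0.002066,
           -0.00089, -1.754724, 1.017658, 0.600499, -0.625429, -0.171548,
           0.505299, -0.261356, -0.242749, -1.453241, 0.55458, 0.123881,
           0.27446, -1.526525, 1.6507, 0.154336, -0.38714, 2.029072,
           -0.045386, -1.450679, -0.405228, -2.288315, 1.049397, -0.416474,
           -0.742554, 1.07247)
  sb <- dwt_decompose(eeg_segment(x32, 64), levels = 2,
                      representation = "coefficients")
  x32_cA2 <- c(-0.046449830135525561, 1.3209810503235633, -0.65860384075787115,
               0.94750123229005145, 0.63419794220593317, -0.65119127449949799,
               0.22361211403584821, -0.63220393349477899, -0.35071975024816349,
               1.2516483586781315, -1.4675705462851534, 0.096192072221374131,
               1.1013781623479177)
  x32_cD1 <- c(0.30695370227754332, 0.47264126202605122, -0.90810744166323865,
               0.49902502532725118, 1.658480993291422, -1.1348154238175894,
               0.74856031373869547, 0.23010520810662813, 1.2704853937509826,
               0.1781468464161452, 2.1904500052194908, -1.174758571856968,
               -0.84044438548260947, 1.4989757159738351, 1.9657513866894882,
               -0.93681480901978098, 0.31590900120975368, 0.079240358622278809,
               -2.3260323536437801)
  expect_equal(sb$subbands$A2, x32_cA2, tolerance = 1e-12)
  expect_equal(sb$subbands$D1, x32_cD1, tolerance = 1e-12)
})

test_that("reconstructed subbands sum back to the original signal", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(c(128, 200, 333, 512), 1)
    x <- rnorm(n)
    for (bnd in if (n %% 16 == 0) c("symmetric", "periodic") else "symmetric") {
      sb <- dwt_decompose(eeg_segment(x, 173.61), representation = "reconstructed",
                          boundary = bnd)
      expect_named(sb$subbands, c("D1", "D2", "D3", "D4", "A4"))
      tot <- Reduce(`+`, sb$subbands)
      expect_lt(max(abs(tot - x)) / max(abs(x)), 1e-10)
    }
  }
})

test_that("orthogonality conserves coefficient energy (periodized)", {
  for (seed in 1:5) {
    set.seed(100 + seed)
    x <- rnorm(256)
    sb <- dwt_decompose(eeg_segment(x, 100), representation = "coefficients",
                        boundary = "periodic")
    expect_lt(abs(sum(unlist(sb$subbands)^2) - sum(x^2)) / sum(x^2), 1e-12)
  }
})

test_that("constant input puts everything in the approximation", {
  sb <- dwt_decompose(eeg_segment(rep(3.7, 128), 100),
                      representation = "coefficients")
  for (d in c("D1", "D2", "D3", "D4")) {
    expect_lt(max(abs(sb$subbands[[d]])), 1e-10)
  }
  rec <- dwt_decompose(eeg_segment(rep(3.7, 128), 100),
                       representation = "reconstructed")
  expect_equal(rec$subbands$A4, rep(3.7, 128), tolerance = 1e-10)
})

test_that("a tone lands in the subband covering its frequency", {
  fs <- 173.61
  n <- 1024
  t <- (0:(n - 1)) / fs
  # one tone per band, at roughly each band's centre
  tones <- c(A4 = 3, D4 = 8, D3 = 16, D2 = 32, D1 = 60)
  for (band in names(tones)) {
    x <- sin(2 * pi * tones[[band]] * t)
    sb <- dwt_decompose(eeg_segment(x, fs), representation = "reconstructed")
    energies <- vapply(sb$subbands, function(s) sum(s^2), numeric(1))
    expect_equal(names(which.max(energies)), band)
  }
  # the 3 Hz case concentrates strongly: >= 80% of total energy in A4
  x <- sin(2 * pi * 3 * t)
  sb <- dwt_decompose(eeg_segment(x, fs), representation = "reconstructed")
  energies <- vapply(sb$subbands, function(s) sum(s^2), numeric(1))
  expect_gte(energies[["A4"]] / sum(energies), 0.8)
})

test_that("decomposition rejects too-short input and unknown wavelets", {
  expect_error(dwt_decompose(eeg_segment(rnorm(8), 100), levels = 4),
               "too short")
  expect_error(wavelet_filters("sym5"), "unsupported")
  expect_error(dwt_decompose(eeg_segment(rnorm(100), 100), boundary = "periodic"),
               "even-length")
})

test_that("band-pass filtering preserves mid-band tones and kills drift", {
  fs <- 173.61
  n <- 4097
  t <- (0:(n - 1)) / fs
  tone <- eeg_segment(sin(2 * pi * 10 * t), fs)
  expect_warning(out <- bandpass(tone, 0.01, 86.8), "Nyquist")
  expect_length(out$samples, n)
  rms <- function(v) sqrt(mean(v^2))
  expect_lt(abs(rms(out$samples) / rms(tone$samples) - 1), 0.05)

  drift <- eeg_segment(sin(2 * pi * 0.001 * t), fs)
  outd <- suppressWarnings(bandpass(drift, 0.01, 86.8))
  expect_lt(rms(outd$samples) / rms(drift$samples), 0.2)

  zeros <- suppressWarnings(bandpass(eeg_segment(numeric(100), fs), 0.01, 86.8))
  expect_equal(zeros$samples, numeric(100))

  # true band-pass branch keeps an in-band tone
  bp <- bandpass(tone, 5, 20)
  expect_lt(abs(rms(bp$samples) / rms(tone$samples) - 1), 0.05)

  expect_error(bandpass(tone, 20, 5), "low < high")
  expect_error(bandpass(tone, 100, 120), "Nyquist")
})

test_that("wavelet denoising shrinks noise without touching clean signals", {
  fs <- 173.61
  n <- 2048
  t <- (0:(n - 1)) / fs
  clean <- sin(2 * pi * 5 * t)
  set.seed(11)
  # SNR 5 dB additive white noise
  noisy <- clean + rnorm(n, 0, sqrt(mean(clean^2)) / 10^(5 / 20))
  den <- wavelet_denoise(eeg_segment(noisy, fs))
  expect_length(den$samples, n)
  rmse <- function(a, b) sqrt(mean((a - b)^2))
  expect_lt(rmse(den$samples, clean), rmse(noisy, clean))

  den0 <- wavelet_denoise(eeg_segment(clean, fs))
  expect_lt(rmse(den0$samples, clean) / sqrt(mean(clean^2)), 0.05)

  denz <- wavelet_denoise(eeg_segment(numeric(64), fs))
  expect_equal(denz$samples, numeric(64))

  expect_error(wavelet_denoise(eeg_segment(rnorm(8), fs), levels = 4),
               "too short")
})
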