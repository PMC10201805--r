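test_that("population standard deviation uses the N divisor", {
  expect_equal(std(rep(2.5, 10)), 0)
  expect_equal(std(c(1, 2, 3, 4)), sqrt(1.25))
  set.seed(0)
  x <- rnorm(50)
  expect_equal(std(-2 * x), 2 * std(x))
  expect_error(std(numeric(0)), "empty")
})

test_that("entropy fast paths agree with the naive oracles", {
  p <- entropy_params()
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(100:300, 1)
    x <- rnorm(n)
    r_abs <- 0.2 * pop_sd(x)
    expect_equal(apen(x, p), apen_oracle(x, 2, r_abs), tolerance = 1e-13)
    expect_equal(sampen(x, p), sampen_oracle(x, 2, r_abs), tolerance = 1e-13)
    expect_equal(fuzzyen(x, p), fuzzyen_oracle(x, 2, r_abs, 2),
                 tolerance = 1e-13)
    # SampEn is one log of two exact integer counts: compare those too
    expect_identical(
      as.integer(eegseize:::.sampen_counts_cpp(x, 2L, r_abs)),
      as.integer(sampen_oracle_counts(x, 2, r_abs)[c("B", "A")]))
  }
})

test_that("constant sequences carry zero entropy", {
  x <- rep(4.2, 60)
  p <- entropy_params()
  expect_equal(apen(x, p), 0)
  expect_equal(sampen(x, p), 0)
  expect_equal(fuzzyen(x, p), 0)
})

test_that("entropies see periodic signals as more regular than noise", {
  p <- entropy_params()
  d_ap <- d_se <- d_fz <- numeric(20)
  for (s in 1:20) {
    set.seed(s)
    n <- 300
    tone <- sin(2 * pi * 3 * (1:n) / 173.61) + 0.01 * rnorm(n)
    noise <- rnorm(n)
    d_ap[s] <- apen(noise, p) - apen(tone, p)
    d_se[s] <- sampen(noise, p) - sampen(tone, p)
    d_fz[s] <- fuzzyen(noise, p) - fuzzyen(tone, p)
  }
  expect_gt(mean(d_ap), 0)
  expect_gt(mean(d_se), 0)
  expect_gt(mean(d_fz), 0)
})

test_that("a periodic sequence is no more complex than its shuffle", {
  p <- entropy_params()
  deltas <- matrix(0, 20, 3)
  for (s in 1:20) {
    set.seed(300 + s)
    periodic <- rep(sin(2 * pi * (1:25) / 25), 8) + 0.001 * rnorm(200)
    shuffled <- sample(periodic)
    deltas[s, ] <- c(apen(shuffled, p) - apen(periodic, p),
                     sampen(shuffled, p) - sampen(periodic, p),
                     fuzzyen(shuffled, p) - fuzzyen(periodic, p))
  }
  expect_true(all(colMeans(deltas) > 0))
})

test_that("SampEn is affine-invariant under relative tolerance", {
  set.seed(0)
  x <- rnorm(200)
  p <- entropy_params(relative = TRUE)
  expect_equal(sampen(3 * x - 7, p), sampen(x, p), tolerance = 1e-12)
})

test_that("SampEn raises a typed condition when no templates match", {
  x <- 1:50 # strictly increasing, nearest templates 1 apart
  p <- entropy_params(r = 1e-6, relative = FALSE)
  expect_error(sampen(x, p), class = "eegseize_sampen_undefined")
  expect_error(sampen(rnorm(3), entropy_params()), "too short")
})

test_that("FuzzyEn is non-negative across random inputs", {
  p <- entropy_params()
  for (s in 1:100) {
    set.seed(s)
    expect_gte(fuzzyen(rnorm(100), p), -1e-12)
  }
})

test_that("extraction emits the 20 named features in fixed order", {
  expected <- c(paste(c("D1", "D2", "D3", "D4", "A4"), "STD"),
                paste(c("D1", "D2", "D3", "D4", "A4"), "SampEn"),
                paste(c("D1", "D2", "D3", "D4", "A4"), "ApEn"),
                paste(c("D1", "D2", "D3", "D4", "A4"), "FuzzyEn"))
  expect_identical(feature_names(4), expected)

  seg <- generate_segment(synth_config("background", n_samples = 256, seed = 1))
  sb <- dwt_decompose(seg)
  fv <- extract_features(sb)
  expect_identical(names(fv), expected)
  expect_true(all(is.finite(fv)))

  # insertion order of the subband map must not matter
  sb_shuffled <- sb
  sb_shuffled$subbands <- sb$subbands[c("A4", "D2", "D4", "D1", "D3")]
  expect_identical(extract_features(sb_shuffled), fv)
})

test_that("a constant segment yields all-zero features", {
  sb <- dwt_decompose(eeg_segment(rep(5, 128), 100))
  fv <- extract_features(sb)
  expect_true(all(abs(fv) < 1e-8))
})

test_that("undefined SampEn is capped, or re-raised when asked", {
  # spiky segment whose D1 subband has no matching templates at tiny r
  seg <- eeg_segment(1:128, 100)
  sb <- dwt_decompose(seg)
  p <- entropy_params(r = 1e-12, relative = FALSE)
  fv <- extract_features(sb, p, cap_undefined = TRUE)
  n <- length(sb$subbands$D1)
  expect_lte(max(fv[grep("SampEn", names(fv))]),
             log(n - 2) + log(n - 3) - log(2) + 1e-9)
  expect_error(extract_features(sb, p, cap_undefined = FALSE),
               class = "eegseize_sampen_undefined")
})

test_that("synthetic classes separate in at least one feature", {
  ds <- generate_dataset(25, c("background", "ictal_like"),
                         base_cfg = list(n_samples = 256), seed = 0)
  cfg <- pipeline_config(bandpass = FALSE, denoise = FALSE)
  fm <- segments_to_features(ds, cfg)
  d <- vapply(seq_len(ncol(fm$values)), function(j) {
    a <- fm$values[fm$labels == 1, j]
    b <- fm$values[fm$labels == 0, j]
    sp <- sqrt((var(a) + var(b)) / 2)
    abs(mean(a) - mean(b)) / sp
  }, numeric(1))
  expect_gt(max(d), 1) # |Cohen's d| > 1 somewhere
})
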