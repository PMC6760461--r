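# Oracles for the spectral stage: closed-form DFT of a sinusoid, hand
# computation of 3x3 complex outer products, and Monte-Carlo null behavior.

test_that("normalized spectra are unit-norm, amplitude-invariant vectors", {
  set.seed(1)
  x <- array(rnorm(3 * 128), dim = c(3, 128))
  sp <- normalized_spectra(x, 64)
  nrm <- sqrt(colSums(Mod(sp)^2))
  expect_equal(unname(nrm), rep(1, length(nrm)), tolerance = 1e-12)
  sp2 <- normalized_spectra(7.3 * x, 64)
  expect_equal(sp, sp2, tolerance = 1e-12)
})

test_that("a pure on-bin sinusoid concentrates in its bin along its axis", {
  fs <- 1024; w <- 2048
  t <- (seq_len(w) - 1) / fs
  x <- array(0, dim = c(3, w))
  x[1, ] <- sin(2 * pi * 10 * t)
  sp <- normalized_spectra(x, fs)
  freq <- attr(sp, "freq")
  b <- which(abs(freq - 10) < 1e-9)
  # all energy on the first spatial dimension: vector is (e^{i theta}, 0, 0)
  expect_equal(Mod(sp[1, b]), 1, tolerance = 1e-9)
  expect_equal(Mod(sp[2, b]), 0, tolerance = 1e-9)
  # closed-form DFT phase of sin at an exact bin: -pi/2
  expect_equal(Arg(sp[1, b]), -pi / 2, tolerance = 1e-9)
})

test_that("all-zero windows are flagged rather than normalized", {
  x <- array(0, dim = c(3, 64))
  sp <- normalized_spectra(x, 64)
  expect_true(all(attr(sp, "flagged")))
  expect_true(all(is.na(sp)))
})

test_that("covariances average segment outer products (hand computation)", {
  # two segments with hand-picked unit 3-vectors at one bin
  tr <- toy_trial(2, fs = 4, dur = 2)
  segs <- segment_trial(tr, window = 1, step = 1)
  cov <- accumulate_covariances(segs, band = NULL)
  v <- cov$vectors
  nseg <- dim(v)[2]
  for (b in c(1, 2)) for (r in c(1, 2)) {
    manual <- matrix(0i, 3, 3)
    for (s in seq_len(nseg))
      manual <- manual + v[, s, r, b] %*% Conj(t(v[, s, r, b]))
    expect_equal(cov$auto[, , b, r], manual / nseg, tolerance = 1e-12)
    # Hermitian with unit trace (amplitude factored out)
    expect_equal(cov$auto[, , b, r], Conj(t(cov$auto[, , b, r])),
                 tolerance = 1e-12)
    expect_equal(Re(sum(diag(cov$auto[, , b, r]))), 1, tolerance = 1e-12)
  }
  # cross of (j, i) is the conjugate transpose of (i, j)
  expect_equal(cov$cross[, , 1, 2, 1], Conj(t(cov$cross[, , 1, 1, 2])),
               tolerance = 1e-12)
})

test_that("identical ROIs give pure instantaneous dependence", {
  tr <- toy_trial(2, fs = 64, dur = 10)
  tr$data[2, , ] <- tr$data[1, , ]  # v_j = v_i at every segment
  segs <- segment_trial(tr, 2, 1)
  cov <- accumulate_covariances(segs, band = c(8.5, 12))
  p <- lps_pair(cov, 1, 2, bin = 1)
  expect_gt(p$total, 0.9)
  expect_lt(p$lagged, 0.1)
  # with v_j = v_i, cross equals auto
  expect_equal(cov$cross[, , 1, 1, 2], cov$auto[, , 1, 1],
               tolerance = 1e-12)
})

test_that("independent sources give near-zero lagged values (MC null)", {
  # many segments (long trials), per the asymptotic null expectation
  set.seed(42)
  vals <- replicate(8, {
    tr <- toy_trial(2, fs = 64, dur = 60)
    cov <- accumulate_covariances(segment_trial(tr, 2, 1), band = c(8.5, 12))
    mean(vapply(seq_along(cov$freq), function(b)
      lps_pair(cov, 1, 2, bin = b)$lagged_raw, numeric(1)))
  })
  expect_lt(abs(mean(vals)), 0.1)
})

test_that("band averaging equals the direct mean of per-bin values", {
  set.seed(3)
  tr <- toy_trial(3, fs = 64, dur = 10)
  cov <- accumulate_covariances(segment_trial(tr, 2, 1), band = c(8.5, 12))
  m <- band_average_lps(cov, band = c(8.5, 12))
  raw <- vapply(seq_along(cov$freq), function(b)
    lps_pair(cov, 1, 2, bin = b)$lagged_raw, numeric(1))
  expect_equal(m[1, 2], min(max(mean(raw), 0), 1), tolerance = 1e-12)
  expect_equal(m, t(m))
  # inclusive 0.5 Hz endpoints: 8 bins between 8.5 and 12 Hz
  expect_length(cov$freq, 8)
})

test_that("compiled and reference paths agree", {
  cfg <- simulation_config(n_rois_per_brain = 3, sampling_rate = 256,
                           trial_duration = 10, seed = 2)
  dy <- suppressWarnings(
    generate_dyad_trial(cfg, ground_truth(1, 2, lag = 0.025)))
  fast <- lps_matrix_for_trial(dy$J1, use_compiled = TRUE)
  slow <- lps_matrix_for_trial(dy$J1, use_compiled = FALSE)
  expect_equal(unclass(fast), unclass(slow), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("LPS matrices are symmetric, in [0, 1], amplitude-invariant", {
  cfg <- simulation_config(n_rois_per_brain = 4, sampling_rate = 256,
                           trial_duration = 10, seed = 6)
  dy <- suppressWarnings(
    generate_dyad_trial(cfg, ground_truth(1, 3, lag = 6 / 256)))
  m <- lps_matrix_for_trial(dy$J1)
  expect_equal(unclass(m), t(unclass(m)))
  expect_true(all(m[upper.tri(m)] >= 0 & m[upper.tri(m)] <= 1))
  # rescaling one ROI's series leaves every value unchanged
  scaled <- dy$J1
  scaled$data[2, , ] <- 100 * scaled$data[2, , ]
  m2 <- lps_matrix_for_trial(scaled)
  expect_equal(unclass(m), unclass(m2), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("pair counts: 325 intra, 676 inter, 1326 hyperbrain values", {
  cfg <- simulation_config(trial_duration = 10, seed = 4)
  dy <- generate_dyad_trial(cfg, truth_none())
  solo <- lps_matrix_for_trial(dy$J1)
  expect_equal(dim(solo), c(26, 26))
  expect_equal(sum(!is.na(solo[upper.tri(solo)])), 325)
  hyper <- lps_matrix_for_trial(list(dy$J1, dy$J2))
  expect_equal(dim(hyper), c(52, 52))
  expect_equal(sum(!is.na(hyper[upper.tri(hyper)])), 1326)
  bl <- attr(hyper, "blocks")
  expect_equal(bl, c(26, 26))
  expect_equal(26 * 26, 676)  # inter block size
  # mismatched trials are rejected
  short <- dy$J2
  short$data <- short$data[, , 1:5120, drop = FALSE]
  expect_error(lps_matrix_for_trial(list(dy$J1, short)), "sample counts")
})
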