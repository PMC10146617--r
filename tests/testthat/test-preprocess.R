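mk_erp <- function(x, fs = 1000) {
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  structure(list(data = X, fs_hz = fs, pulse_sample = ncol(X) / 2,
                 channel_labels = paste0("ch", seq_len(nrow(X))),
                 n_trials_used = 1), class = "erp_signal")
}

test_that("amplitude rejection drops exactly the offending trials", {
  clean <- matrix(rnorm(2 * 100, 0, 5), 2)
  bad <- clean; bad[1, 40] <- 80
  ep <- epochs_from_trials(list(clean, bad, clean * 0.5), fs = 100)
  out <- reject_artifacts(ep, 75)
  expect_equal(dim(out$data)[1], 2L)
  expect_equal(out$data[1, , ], clean)       # order preserved
  expect_equal(out$data[2, , ], clean * 0.5)
  # all-clean set passes unchanged; rejection is idempotent
  out2 <- reject_artifacts(out, 75)
  expect_identical(out2$data, out$data)
  # nothing survives -> explicit error naming the subject
  allbad <- epochs_from_trials(list(bad, bad), fs = 100)
  expect_error(reject_artifacts(allbad, 75), "T01")
})

test_that("ERP averaging is the pointwise trial mean", {
  tr <- matrix(rnorm(300), 3)
  ep <- epochs_from_trials(list(tr, tr, tr), fs = 100)
  expect_equal(unname(average_erp(ep)$data), tr)     # identical trials
  # hand example: trials [1,2] and [3,4] -> [2,3]
  ep2 <- epochs_from_trials(list(matrix(c(1, 2), 1), matrix(c(3, 4), 1)), fs = 2)
  expect_equal(unname(average_erp(ep2)$data), matrix(c(2, 3), 1))
  expect_equal(average_erp(ep2)$n_trials_used, 2L)
})

test_that("averaging N white-noise trials shrinks the noise by sqrt(N)", {
  set.seed(20)
  N <- 60
  trials <- replicate(N, matrix(rnorm(2000, 0, 3), 1), simplify = FALSE)
  erp <- average_erp(epochs_from_trials(trials))
  expect_equal(sd(erp$data), 3 / sqrt(N), tolerance = 0.1)
})

test_that("FIR bandpass meets its passband/stopband contract", {
  fs <- 1000; t <- seq_len(2000) / fs
  core <- 500:1500   # avoid edge transients when measuring gain
  f10 <- bandpass_fir(mk_erp(sin(2 * pi * 10 * t)))$data[1, core]
  expect_lt(abs(max(abs(f10)) - 1), 0.05)           # in-band tone preserved
  f80 <- bandpass_fir(mk_erp(sin(2 * pi * 80 * t)))$data[1, core]
  expect_lt(20 * log10(max(abs(f80))), -40)         # stopband >= 40 dB
  fdc <- bandpass_fir(mk_erp(rep(7, 2000)))$data[1, core]
  expect_lt(max(abs(fdc)), 1e-10)                   # DC removed
  expect_error(bandpass_fir(mk_erp(sin(t)), 50, 1), "invalid band")
})

test_that("decimation halves samples and rate while preserving in-band tones", {
  fs <- 1000; t <- seq_len(2000) / fs
  d <- decimate_erp(mk_erp(sin(2 * pi * 10 * t)), 2)
  expect_equal(ncol(d$data), 1000L)
  expect_equal(d$fs_hz, 500)
  expect_equal(d$pulse_sample, 500L)
  expect_lt(abs(max(abs(d$data[1, 200:800])) - 1), 0.05)
  # factor 1 is the identity
  e <- mk_erp(rnorm(2000))
  expect_identical(decimate_erp(e, 1), e)
  expect_error(decimate_erp(mk_erp(rnorm(2001 - 1)), 3), "does not divide")
})

test_that("common-average reference zeroes the channel mean at every sample", {
  set.seed(21)
  X <- matrix(rnorm(5 * 300), 5)
  out <- rereference_common_average(mk_erp(X))
  expect_lt(max(abs(colMeans(out$data))), 1e-12)
  # idempotent on already re-referenced data
  out2 <- rereference_common_average(out)
  expect_equal(out2$data, out$data)
  # two channels [a, b] -> [(a-b)/2, (b-a)/2]
  ab <- matrix(c(3, 1, 5, -1), 2, byrow = TRUE)
  ref <- rereference_common_average(mk_erp(ab))$data
  expect_equal(unname(ref), rbind((ab[1, ] - ab[2, ]) / 2, (ab[2, ] - ab[1, ]) / 2))
  expect_error(rereference_common_average(mk_erp(rnorm(10))), ">= 2 channels")
})

test_that("the preprocessing chain is order-sensitive and reproducible", {
  set.seed(22)
  trials <- replicate(8, matrix(rnorm(4 * 2000, 0, 5), 4), simplify = FALSE)
  trials[[3]][2, 100] <- 90   # one artifact trial
  ep <- epochs_from_trials(trials)
  out <- preprocess_epochs(ep)
  expect_equal(dim(out$data), c(4L, 1000L))
  expect_equal(out$fs_hz, 500)
  expect_equal(out$n_trials_used, 7L)
  expect_lt(max(abs(colMeans(out$data))), 1e-10)
  # permuting stages changes the result: re-referencing before filtering and
  # decimation is not equivalent because rejection/averaging interact
  alt <- decimate_erp(bandpass_fir(rereference_common_average(
    average_erp(ep))), 2)
  expect_gt(max(abs(alt$data - out$data)), 0)
  # determinism
  expect_identical(out, preprocess_epochs(ep))
})
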