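test_that("cohort specs carry the study's default group sizes", {
  expect_equal(unlist(cohort_spec("left_motor")[c("n_patients", "n_controls")]),
               c(n_patients = 22L, n_controls = 27L))
  expect_equal(unlist(cohort_spec("left_prefrontal")[c("n_patients", "n_controls")]),
               c(n_patients = 9L, n_controls = 18L))
  expect_equal(unlist(cohort_spec("vermis")[c("n_patients", "n_controls")]),
               c(n_patients = 12L, n_controls = 25L))
  expect_error(cohort_spec("left_motor", n_patients = 0), "positive integer")
})

test_that("ground truth is exchangeable unless an effect is planted", {
  nws <- tiny_networks()
  g0 <- ground_truth(nws, seed = 3, planted_delta_j = 0)
  expect_identical(g0$models$patient$post, g0$models$control$post)
  expect_identical(g0$models$patient$pre, g0$models$patient$post)
  g1 <- ground_truth(nws, seed = 3, planted_delta_j = 0.5)
  # only the planted network's patients-post couplings move, by exactly 0.5
  expect_identical(g1$models$control, g0$models$control)
  dj <- g1$models$patient$post$sensorimotor$J - g0$models$patient$post$sensorimotor$J
  off <- dj[upper.tri(dj)]
  expect_true(all(abs(off - 0.5) < 1e-12))
  expect_identical(g1$models$patient$post$visual, g0$models$patient$post$visual)
  for (m in g1$models$patient$post) {
    expect_equal(m$J, t(m$J))
    expect_equal(diag(m$J), rep(0, m$M))
  }
})

test_that("a fixed seed reproduces the cohort bit for bit", {
  nws <- tiny_networks()
  head <- tiny_head()
  truth <- ground_truth(nws, seed = 3)
  spec <- cohort_spec("left_motor", n_patients = 2, n_controls = 1,
                      n_trials_per_subject = 3, seed = 7)
  c1 <- synthesize_cohort(spec, truth, head)
  c2 <- synthesize_cohort(spec, truth, head)
  expect_identical(c1$subjects, c2$subjects)
  expect_equal(nrow(c1$manifest), 3L)
  # growing the cohort does not reshuffle existing subjects
  spec2 <- cohort_spec("left_motor", n_patients = 3, n_controls = 1,
                       n_trials_per_subject = 3, seed = 7)
  c3 <- synthesize_cohort(spec2, truth, head)
  expect_identical(c3$subjects[[1]], c1$subjects[[1]])
  expect_identical(c3$subjects[[2]], c1$subjects[[2]])
})

test_that("the default left-motor cohort has 22 + 27 = 49 subjects", {
  nws <- tiny_networks()
  head <- tiny_head()
  truth <- ground_truth(nws, seed = 3)
  spec <- cohort_spec("left_motor", n_trials_per_subject = 1, seed = 5)
  co <- synthesize_cohort(spec, truth, head)
  expect_length(co$subjects, 49L)
  expect_equal(sum(co$manifest$group == "patient"), 22L)
  expect_equal(sum(co$manifest$group == "control"), 27L)
  # epochs are 11 x 2000 at 1000 Hz with the pulse at midpoint
  s1 <- co$subjects[[1]]
  expect_equal(dim(s1$data)[2:3], c(11L, 2000L))
  expect_equal(s1$fs_hz, 1000)
  expect_equal(s1$pulse_sample, 1000L)
})

test_that("injected artifacts cross the gate at the configured rate", {
  nws <- tiny_networks()
  head <- tiny_head()
  truth <- ground_truth(nws, seed = 3)
  spec <- cohort_spec("left_motor", n_patients = 3, n_controls = 3,
                      n_trials_per_subject = 60, artifact_fraction = 0.1, seed = 9)
  co <- synthesize_cohort(spec, truth, head)
  n_rej <- vapply(co$subjects, function(s) {
    60L - dim(reject_artifacts(s)$data)[1]
  }, integer(1))
  n_inj <- vapply(co$subjects, function(s) length(attr(s, "artifact_trials")),
                  integer(1))
  # every injected artifact trial is rejected; spontaneous rejections are rare
  expect_true(all(n_rej >= n_inj))
  expect_lt(sum(n_rej) - sum(n_inj), 0.05 * 360)
  # binomial expectation: about 6 of 60 trials per subject
  total <- sum(n_inj)
  expect_lt(abs(total - 36), 4 * sqrt(360 * 0.1 * 0.9))
})

test_that("empirical state moments match the generating model", {
  nws <- tiny_networks()
  truth <- ground_truth(nws, seed = 3, planted_delta_j = 0)
  m <- truth$models$control$pre$sensorimotor
  X <- sample_ising(m, 5e4, seed = 11)
  mom <- ising_moments(m)
  expect_lt(max(abs(colMeans(X) - mom$m)), 0.02)
  expect_lt(max(abs(crossprod(X) / 5e4 - mom$C)), 0.02)
})

test_that("the noiseless chain ranks a lone active region first", {
  # with sensor noise and artifacts off, a single strongly active ROI ends
  # up with the highest alpha-band ROI power after the full chain
  nws <- tiny_networks()
  head <- tiny_head()
  fs <- 1000; t_raw <- seq_len(2000) / fs
  set.seed(12)
  for (roi in c("Left Precentral Gyrus", "Cuneus Gyrus")) {
    vx <- which(head$voxel_roi == roi)
    mom <- matrix(0, 3 * head$n_voxels, 2000)
    for (v in vx) {
      ph <- runif(1, 0, 2 * pi)
      mom[(3 * v - 2):(3 * v), ] <- outer(head$voxel_orient[v, ],
                                          8 * sin(2 * pi * 10 * t_raw + ph))
    }
    phi <- head$K %*% mom
    ep <- epoch_set(array(rep(phi, each = 2), c(2, 11, 2000)), fs, 1000,
                    head$electrode_labels, subject_id = "clean")
    rs <- subject_to_roi_series(ep, head, default_config(n_voxels = head$n_voxels))
    ranking <- names(sort(rowMeans(rs$values), decreasing = TRUE))
    expect_equal(ranking[1], roi)
  }
})

test_that("subject matrices round-trip through the delimited writer", {
  nws <- tiny_networks()
  head <- tiny_head()
  truth <- ground_truth(nws, seed = 3)
  spec <- cohort_spec("left_motor", n_patients = 1, n_controls = 1,
                      n_trials_per_subject = 2, seed = 13)
  co <- synthesize_cohort(spec, truth, head)
  dir <- withr::local_tempdir()
  man <- write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  back <- read_subject(file.path(dir, man$file[1]))
  orig <- co$subjects[[1]]
  expect_equal(back$data, orig$data, tolerance = 1e-12)
  expect_identical(back$channel_labels, orig$channel_labels)
  expect_equal(back$fs_hz, orig$fs_hz)
  expect_equal(back$pulse_sample, orig$pulse_sample)
})
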