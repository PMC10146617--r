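test_that("binarization thresholds at the window mean with strict inequality", {
  vals <- rbind(a = c(1, 2, 3, 5, 5, 5), b = c(2, 2, 2, 1, 3, 2))
  rs <- list(values = vals, window_pre = 1:3, window_post = 4:6)
  nw <- network_definition("toy", c("a", "b"))
  bp <- binarize(rs, nw, "pre")
  # region a: mean 2 -> [-1, -1, +1] (equality maps to inactive)
  expect_equal(unname(bp$patterns[, "a"]), c(-1, -1, 1))
  # constant region: nothing exceeds the mean
  bp_post <- binarize(rs, nw, "post")
  expect_equal(unname(bp_post$patterns[, "a"]), c(-1, -1, -1))
  expect_equal(sum(bp$counts), 3L)
  expect_error(binarize(rs, network_definition("bad", c("a", "zz")), "pre"), "zz")
})

test_that("binarization agrees with an independent one-line oracle", {
  set.seed(10)
  vals <- matrix(rnorm(7 * 200), 7, dimnames = list(paste0("r", 1:7), NULL))
  rs <- list(values = vals, window_pre = 1:100, window_post = 101:200)
  nw <- network_definition("toy", paste0("r", c(2, 5, 7)))
  for (win in c("pre", "post")) {
    idx <- if (win == "pre") rs$window_pre else rs$window_post
    expect_equal(unname(binarize(rs, nw, win)$patterns),
                 unname(t(naive_binarize(vals, nw$regions, idx))))
  }
})

test_that("stable states match brute-force enumeration on random models", {
  set.seed(11)
  for (i in 1:40) {
    M <- sample(2:8, 1)
    ls <- energy_landscape(random_model(M))
    expect_identical(ls$local_minima, brute_minima(ls$energies, M))
  }
})

test_that("separable and ferromagnetic landscapes have the known minima", {
  # J = 0, h nonzero: unique minimum at sign(h)
  h <- c(0.5, -1, 2, -0.2)
  ls <- energy_landscape(maxent_model(h, matrix(0, 4, 4)))
  expect_equal(ls$local_minima, pattern_code(sign(h)))
  # ferromagnetic J > 0, h = 0: the two uniform patterns tie as global minima
  J <- matrix(0.6, 3, 3); diag(J) <- 0
  lsf <- energy_landscape(maxent_model(rep(0, 3), J))
  expect_setequal(lsf$local_minima, c(0L, 7L))
  expect_equal(lsf$energies[1], lsf$energies[8])
  # truncation keeps the lowest-energy states
  expect_equal(find_stable_states(lsf, 1), 0L)  # tie broken by code ascending
  expect_error(find_stable_states(lsf, 0), "k must be")
})

test_that("disconnectivity barriers equal brute-force minimax paths", {
  set.seed(12)
  for (i in 1:15) {
    M <- sample(3:7, 1)
    ls <- energy_landscape(random_model(M))
    mins <- ls$local_minima
    expect_equal(ls$barriers, brute_barriers(ls$energies, M, mins))
    # barrier >= both joined minima's energies
    off <- ls$barriers[upper.tri(ls$barriers)]
    if (length(off)) {
      pairs <- which(upper.tri(ls$barriers), arr.ind = TRUE)
      lo <- pmax(ls$energies[mins[pairs[, 1]] + 1L], ls$energies[mins[pairs[, 2]] + 1L])
      expect_true(all(off >= lo - 1e-12))
    }
  }
})

test_that("a single-minimum landscape yields a trivial tree", {
  ls <- energy_landscape(maxent_model(c(3, 3, 3), matrix(0, 3, 3)))
  expect_length(ls$local_minima, 1L)
  dg <- disconnectivity_graph(ls)
  expect_equal(nrow(dg$merges), 0L)
  expect_equal(dim(dg$barriers), c(1L, 1L))
})

test_that("subject energies table has the contracted shape and determinism", {
  set.seed(13)
  nw <- network_definition("toy", paste0("r", 1:4))
  mk_rs <- function(id, vals) {
    structure(list(values = vals, window_pre = 1:150, window_post = 151:300,
                   subject_id = id, group = "control", site = "left_motor"),
              class = "roi_series")
  }
  vals <- matrix(rnorm(4 * 300), 4, dimnames = list(paste0("r", 1:4), NULL))
  rsl <- list(mk_rs("S1", vals), mk_rs("S2", vals))
  sel <- c(0L, 15L)
  tab <- subject_energies(rsl, nw, sel)
  expect_equal(nrow(tab), 2 * 2 * 2)  # subjects x conditions x patterns
  expect_setequal(unique(tab$pattern_code), sel)
  # identical subjects -> identical rows
  expect_equal(tab$energy[tab$subject == "S1"], tab$energy[tab$subject == "S2"])
})

test_that("subject energies approach group energies at large per-subject n", {
  set.seed(14)
  tru <- random_model(4, h_sd = 0.3, j_sd = 0.2)
  nw <- network_definition("toy", paste0("r", 1:4))
  X <- sample_ising(tru, 4e4, seed = 15)
  # encode the sampled patterns as an ROI series that binarizes back to X:
  # values 2 (active) / 0 (inactive) around a window mean strictly between
  vals <- t(X) + 1
  rownames(vals) <- nw$regions
  rs <- structure(list(values = cbind(vals, vals), window_pre = 1:4e4,
                       window_post = (4e4 + 1):8e4, subject_id = "S1",
                       group = "control", site = "x"), class = "roi_series")
  sel <- energy_landscape(tru)$local_minima
  tab <- subject_energies(list(rs), nw, sel)
  expect_lt(max(abs(tab$energy[tab$condition == "pre"] -
                      ising_energy(tru, pattern_decode(sel, 4)))), 0.15)
})

test_that("group-level fits are invariant to subject concatenation order", {
  set.seed(16)
  tru <- random_model(3)
  X1 <- sample_ising(tru, 400, seed = 17)
  X2 <- sample_ising(tru, 600, seed = 18)
  f12 <- fit_maxent(rbind(X1, X2))
  f21 <- fit_maxent(rbind(X2, X1))
  expect_equal(f12$h, f21$h, tolerance = 1e-3)
  expect_equal(f12$J, f21$J, tolerance = 1e-3)
})
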