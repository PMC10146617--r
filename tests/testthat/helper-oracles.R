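# Independent oracles and small fixtures used across the test files.

# random pairwise max-ent model
random_model <- function(M, h_sd = 0.5, j_sd = 0.4) {
  h <- rnorm(M, 0, h_sd)
  J <- matrix(0, M, M)
  J[upper.tri(J)] <- rnorm(M * (M - 1) / 2, 0, j_sd)
  maxent_model(h, J + t(J))
}

# closed-form M = 2 fit from the four cell probabilities
closed_form_m2 <- function(patterns) {
  p <- as.numeric(table(factor(pattern_code(patterns), levels = 0:3)) / nrow(patterns))
  list(h = c(0.25 * log(p[4] * p[2] / (p[3] * p[1])),
             0.25 * log(p[4] * p[3] / (p[2] * p[1]))),
       J12 = 0.25 * log(p[4] * p[1] / (p[2] * p[3])))
}

# brute-force local minima by explicit neighbour comparison
brute_minima <- function(E, M) {
  codes <- 0:(2^M - 1)
  ok <- rep(TRUE, 2^M)
  for (j in seq_len(M)) {
    ok <- ok & (E <= E[bitwXor(codes, bitwShiftL(1L, j - 1L)) + 1L])
  }
  mins <- codes[ok]
  mins[order(E[mins + 1L], mins)]
}

# minimax-path barriers by Floyd-Warshall over the single-flip hypercube
# (cost of a path = maximum node energy en route, endpoints included)
brute_barriers <- function(E, M, mins) {
  n <- 2^M
  codes <- 0:(n - 1)
  D <- matrix(Inf, n, n)
  for (j in seq_len(M)) {
    nb <- bitwXor(codes, bitwShiftL(1L, j - 1L))
    idx <- cbind(codes + 1L, nb + 1L)
    D[idx] <- pmax(E[codes + 1L], E[nb + 1L])
  }
  diag(D) <- E
  for (k in seq_len(n)) {
    D <- pmin(D, pmax(matrix(D[, k], n, n), matrix(D[k, ], n, n, byrow = TRUE)))
  }
  out <- D[mins + 1L, mins + 1L, drop = FALSE]
  dimnames(out) <- list(mins, mins)
  out
}

# one-line re-implementation of the binarization rule
naive_binarize <- function(vals, regions, idx) {
  t(apply(vals[regions, idx, drop = FALSE], 1L, function(v) ifelse(v > mean(v), 1, -1)))
}

# small two-network setup used by localization / end-to-end unit tests
tiny_networks <- function() default_networks()[c("sensorimotor", "visual")]

tiny_head <- function(seed = 1) make_head_model(30, seed = seed, networks = tiny_networks())

# epoch set with prescribed per-trial channel x sample matrices
epochs_from_trials <- function(trials, fs = 1000) {
  n_ch <- nrow(trials[[1]])
  n_s <- ncol(trials[[1]])
  arr <- array(0, dim = c(length(trials), n_ch, n_s))
  for (k in seq_along(trials)) arr[k, , ] <- trials[[k]]
  epoch_set(arr, fs, n_s / 2, paste0("ch", seq_len(n_ch)), subject_id = "T01")
}
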