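#' Enumerate all activity patterns of an M-region network
#'
#' A network of M regions, each active (+1) or inactive (-1), has 2^M possible
#' activity patterns. Patterns are indexed by an integer code in `[0, 2^M)`:
#' bit `i - 1` of the code is 1 exactly when region `i` is active.
#'
#' @param M number of regions (2 <= M <= 12; enumeration is exact).
#' @return a `2^M x M` matrix with entries in {-1, +1}; row `k` is the pattern
#'   with code `k - 1`.
#' @export
ising_states <- function(M) {
  stop_if_not_count(M, "M")
  if (M > 12) stop("exact enumeration requires M <= 12, got M = ", M, call. = FALSE)
  codes <- 0:(2^M - 1)
  S <- vapply(seq_len(M), function(i) ifelse(bitwAnd(codes, bitwShiftL(1L, i - 1L)) > 0L, 1, -1),
              numeric(length(codes)))
  matrix(S, ncol = M)
}

#' Convert patterns to integer codes and back
#'
#' @param patterns matrix (n x M) with entries in {-1, +1}, or a single vector.
#' @return `pattern_code`: integer codes in `[0, 2^M)`.
#' @export
pattern_code <- function(patterns) {
  if (is.vector(patterns)) patterns <- matrix(patterns, nrow = 1L)
  M <- ncol(patterns)
  as.integer((patterns > 0) %*% 2^(seq_len(M) - 1L))
}

#' @rdname pattern_code
#' @param codes integer codes.
#' @param M number of regions.
#' @return `pattern_decode`: an n x M matrix in {-1, +1}.
#' @export
pattern_decode <- function(codes, M) {
  ising_states(M)[codes + 1L, , drop = FALSE]
}

#' Energy of activity patterns under a pairwise maximum-entropy model
#'
#' The model assigns each pattern `s` in {-1,+1}^M the energy
#' `E(s) = -sum_i h_i s_i - sum_{i<j} J_ij s_i s_j`; lower energy means a more
#' probable pattern under the Boltzmann distribution.
#'
#' @param model a `maxent_model` (or any list with elements `h` and `J`).
#' @param patterns a pattern vector, or an n x M matrix of patterns.
#' @return numeric vector of energies, one per pattern.
#' @export
ising_energy <- function(model, patterns) {
  h <- model$h; J <- model$J
  if (is.vector(patterns)) patterns <- matrix(patterns, nrow = 1L)
  if (ncol(patterns) != length(h)) {
    stop(sprintf("pattern length %d does not match model size M = %d",
                 ncol(patterns), length(h)), call. = FALSE)
  }
  drop(-(patterns %*% h) - 0.5 * rowSums((patterns %*% J) * patterns))
}

#' Boltzmann distribution over all 2^M patterns
#'
#' `P(s) = exp(-E(s)) / sum_s' exp(-E(s'))`, computed by exact enumeration
#' with max-subtraction to guard against overflow.
#'
#' @param model a `maxent_model` (list with `h`, `J`).
#' @return numeric vector of length `2^M` summing to 1; element `k` is the
#'   probability of the pattern with code `k - 1`.
#' @export
ising_boltzmann <- function(model) {
  M <- length(model$h)
  E <- ising_energy(model, ising_states(M))
  w <- exp(-(E - min(E)))
  w / sum(w)
}

#' Exact model moments by enumeration
#'
#' @param model a `maxent_model`.
#' @return list with `m` (vector of `<s_i>`) and `C` (matrix of `<s_i s_j>`).
#' @export
ising_moments <- function(model) {
  M <- length(model$h)
  S <- ising_states(M)
  p <- ising_boltzmann(model)
  list(m = drop(crossprod(S, p)), C = crossprod(S, S * p))
}

#' Draw i.i.d. activity patterns from an Ising model
#'
#' Samples patterns from the exact Boltzmann distribution (enumeration over
#' all 2^M states), emulating independent visits to network states.
#'
#' @param model a `maxent_model` (list with `h`, `J`).
#' @param n number of samples.
#' @param seed optional integer seed for reproducibility.
#' @return n x M matrix with entries in {-1, +1}.
#' @export
sample_ising <- function(model, n, seed = NULL) {
  stop_if_not_count(n, "n")
  M <- length(model$h)
  if (M > 12) stop("exact enumeration requires M <= 12, got M = ", M, call. = FALSE)
  p <- ising_boltzmann(model)
  draw <- function() sample.int(2^M, n, replace = TRUE, prob = p) - 1L
  codes <- if (is.null(seed)) draw() else with_seed(seed, draw())
  pattern_decode(codes, M)
}

#' Construct a pairwise maximum-entropy model object
#'
#' @param h bias (field) vector of length M.
#' @param J symmetric M x M coupling matrix with zero diagonal.
#' @param ... further diagnostic fields stored on the object.
#' @return an object of class `maxent_model`.
#' @export
maxent_model <- function(h, J, ...) {
  h <- as.numeric(h)
  J <- as.matrix(J)
  M <- length(h)
  stopifnot(nrow(J) == M, ncol(J) == M)
  if (max(abs(J - t(J))) > 1e-10) stop("J must be symmetric", call. = FALSE)
  if (max(abs(diag(J))) > 1e-10) stop("J must have zero diagonal", call. = FALSE)
  if (!all(is.finite(h)) || !all(is.finite(J))) stop("model parameters must be finite", call. = FALSE)
  J <- (J + t(J)) / 2
  diag(J) <- 0
  structure(list(h = h, J = J, M = M, ...), class = "maxent_model")
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf("Pairwise maximum-entropy model, M = %d regions\n", x$M))
  cat("h:", paste(sprintf("% .3f", x$h), collapse = " "), "\n")
  if (!is.null(x$iterations)) {
    cat(sprintf("fit: %d iterations, final moment mismatch %.2e (%s)\n",
                x$iterations, x$mismatch,
                if (isTRUE(x$converged)) "converged" else "NOT converged"))
  }
  invisible(x)
}

#' Fit a pairwise maximum-entropy model to binarized activity patterns
#'
#' Maximizes the log-likelihood of the observed pattern counts under
#' `P(s) proportional to exp(-E(s))` by gradient ascent; at each step model
#' moments `<s_i>` and `<s_i s_j>` are computed by exact enumeration over all
#' `2^M` states, so at convergence they match the empirical moments to within
#' `tol_moment` (the gradient is exactly the moment mismatch).
#'
#' Degenerate data — a region (or region pair) constant across all samples,
#' i.e. an empirical moment of exactly +/-1 — has no finite maximizer; the
#' corresponding parameters are clipped to `+/- h_max` with a warning and
#' excluded from the convergence check.
#'
#' @param patterns n x M matrix in {-1,+1}, or a `binary_pattern_series`.
#' @param lr learning rate of the gradient ascent.
#' @param tol_moment convergence tolerance on the maximum absolute mismatch
#'   between empirical and model moments.
#' @param max_iter maximum number of gradient steps; exceeding it raises an
#'   error of class `maxent_convergence_error` carrying the diagnostics.
#' @param h_max clip bound for parameters of degenerate moments.
#' @return a `maxent_model` with fit diagnostics (`iterations`, `mismatch`,
#'   `converged`, `clipped`).
#' @export
fit_maxent <- function(patterns, lr = 0.1, tol_moment = 1e-4,
                       max_iter = 1e5, h_max = 20) {
  if (inherits(patterns, "binary_pattern_series")) patterns <- patterns$patterns
  patterns <- as.matrix(patterns)
  if (nrow(patterns) < 1L) stop("at least one sample is required", call. = FALSE)
  if (!all(patterns %in% c(-1, 1))) stop("patterns must take values in {-1, +1}", call. = FALSE)
  M <- ncol(patterns)
  if (M > 12) stop("exact enumeration requires M <= 12, got M = ", M, call. = FALSE)

  n <- nrow(patterns)
  emp_m <- colMeans(patterns)
  emp_C <- crossprod(patterns) / n

  free_h <- abs(emp_m) < 1
  free_J <- abs(emp_C) < 1
  diag(free_J) <- FALSE
  if (!all(free_h)) {
    warning(sprintf("region(s) %s constant across all samples; h clipped to +/-%g",
                    paste(which(!free_h), collapse = ", "), h_max), call. = FALSE)
  }

  fit <- fit_maxent_core(ising_states(M), emp_m, emp_C, lr, tol_moment,
                         as.integer(max_iter), h_max,
                         as.integer(free_h),
                         matrix(as.integer(free_J), M, M))
  if (!fit$converged) {
    cond <- structure(
      class = c("maxent_convergence_error", "error", "condition"),
      list(message = sprintf(
             "maximum-entropy fit did not converge in %d iterations (moment mismatch %.3e > tol %.1e)",
             as.integer(max_iter), fit$mismatch, tol_moment),
           call = sys.call(-1), diagnostics = fit))
    stop(cond)
  }
  maxent_model(drop(fit$h), fit$J,
               iterations = fit$iterations, mismatch = fit$mismatch,
               converged = fit$converged, clipped = !free_h,
               n_samples = n, empirical_m = emp_m, empirical_C = emp_C)
}
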