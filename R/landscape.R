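#' Binarize ROI activity into network patterns
#'
#' For each region of the network, the threshold is the mean of that region's
#' values within the requested window; values strictly above the threshold
#' map to +1 (active), all others (including ties) to -1 (inactive). The
#' threshold is computed per window, so pre- and post-stimulation segments
#' are binarized against their own baselines.
#'
#' @param series a `roi_series` (see [aggregate_rois()]) or any list with a
#'   `values` matrix (ROI x samples, rownames = ROI names) and
#'   `window_pre` / `window_post` index vectors.
#' @param network a `network_definition`.
#' @param window `"pre"` or `"post"`.
#' @return an object of class `binary_pattern_series`: list with `patterns`
#'   (samples x M in {-1,+1}), `codes`, `counts` (named visit counts by code)
#'   and `network`.
#' @export
binarize <- function(series, network, window = c("pre", "post")) {
  window <- match.arg(window)
  idx <- if (window == "pre") series$window_pre else series$window_post
  vals <- series$values
  missing <- setdiff(network$regions, rownames(vals))
  if (length(missing)) {
    stop(sprintf("region(s) not present in ROI series: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  seg <- vals[network$regions, idx, drop = FALSE]
  thr <- rowMeans(seg)
  patterns <- t(ifelse(seg > thr, 1, -1))
  colnames(patterns) <- network$regions
  codes <- pattern_code(patterns)
  counts <- table(factor(codes, levels = 0:(2^ncol(patterns) - 1)))
  structure(list(patterns = patterns, codes = codes,
                 counts = as.integer(counts), network = network$name,
                 window = window),
            class = "binary_pattern_series")
}

#' Local minima of an energy landscape
#'
#' A pattern is a local minimum (stable state) when its energy is less than
#' or equal to the energy of all M patterns reachable by flipping a single
#' region.
#'
#' @param energies numeric vector of length `2^M`, element `k` being the
#'   energy of the pattern with code `k - 1`.
#' @param M number of regions.
#' @return integer vector of local-minimum codes, sorted by energy (ties
#'   broken by code ascending).
#' @export
local_minima <- function(energies, M) {
  codes <- 0:(2^M - 1)
  is_min <- rep(TRUE, length(codes))
  for (j in seq_len(M)) {
    nb <- bitwXor(codes, bitwShiftL(1L, j - 1L))
    is_min <- is_min & (energies <= energies[nb + 1L])
  }
  mins <- codes[is_min]
  mins[order(energies[mins + 1L], mins)]
}

#' Energy landscape of a fitted maximum-entropy model
#'
#' Enumerates all `2^M` pattern energies and Boltzmann probabilities, finds
#' the local minima, and builds the disconnectivity structure (the energy
#' barriers at which minima's basins merge as the energy level is raised).
#'
#' @param model a `maxent_model`.
#' @return an object of class `energy_landscape`: `energies`, `probabilities`,
#'   `local_minima` (codes by increasing energy), `merges` (data.frame
#'   `min_a`, `min_b`, `barrier` of basin-merge events) and `barriers`
#'   (symmetric matrix of pairwise barrier energies between minima).
#' @export
energy_landscape <- function(model) {
  M <- model$M %||% length(model$h)
  E <- ising_energy(model, ising_states(M))
  p <- ising_boltzmann(model)
  mins <- local_minima(E, M)
  dg <- disconnectivity_filtration(E, M, mins)
  structure(list(M = M, energies = E, probabilities = p,
                 local_minima = mins, merges = dg$merges,
                 barriers = dg$barriers, model = model),
            class = "energy_landscape")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.energy_landscape <- function(x, ...) {
  cat(sprintf("Energy landscape over %d patterns (M = %d): %d local minima\n",
              2^x$M, x$M, length(x$local_minima)))
  for (m in x$local_minima) {
    cat(sprintf("  code %4d  %s  E = %.4f  P = %.4f\n", m,
                paste(ifelse(pattern_decode(m, x$M) > 0, "+", "-"), collapse = ""),
                x$energies[m + 1], x$probabilities[m + 1]))
  }
  invisible(x)
}

#' Stable states: lowest-energy local minima
#'
#' @param landscape an `energy_landscape`.
#' @param k maximum number of states to return (default: all local minima).
#' @return integer codes of the selected stable patterns, ranked by energy
#'   (ties broken by code ascending).
#' @export
find_stable_states <- function(landscape, k = Inf) {
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  mins <- landscape$local_minima
  mins[seq_len(min(length(mins), k))]
}

# Threshold filtration over the M-cube: activate states in order of
# increasing energy; union-find merges components through single-flip edges;
# when two components each holding a local minimum join, the activating
# state's energy is the barrier between every minima pair across the two.
disconnectivity_filtration <- function(energies, M, mins) {
  n <- 2^M
  ord <- order(energies, 0:(n - 1))
  parent <- integer(n)               # 0 = inactive; else 1-based parent index
  comp_mins <- vector("list", n)     # minima held by each root
  find <- function(i) {
    r <- i
    while (parent[r] != r) r <- parent[r]
    while (parent[i] != r) { nxt <- parent[i]; parent[i] <<- r; i <- nxt }
    r
  }
  is_min <- logical(n); is_min[mins + 1L] <- TRUE
  nm <- length(mins)
  bmat <- matrix(NA_real_, nm, nm, dimnames = list(mins, mins))
  diag(bmat) <- energies[mins + 1L]
  merges <- list()
  shifts <- bitwShiftL(1L, seq_len(M) - 1L)
  for (s in ord) {
    code <- s - 1L
    parent[s] <- s
    comp_mins[[s]] <- if (is_min[s]) code else integer(0)
    for (d in shifts) {
      nb <- bitwXor(code, d) + 1L
      if (parent[nb] == 0L) next
      ra <- find(s); rb <- find(nb)
      if (ra == rb) next
      A <- comp_mins[[ra]]; B <- comp_mins[[rb]]
      if (length(A) && length(B)) {
        lvl <- energies[s]
        ia <- match(A, mins); ib <- match(B, mins)
        bmat[ia, ib] <- lvl; bmat[ib, ia] <- lvl
        merges[[length(merges) + 1L]] <-
          data.frame(min_a = min(A[1L], B[1L]), min_b = max(A[1L], B[1L]),
                     barrier = lvl)
      }
      parent[rb] <- ra
      comp_mins[[ra]] <- c(A, B)
      comp_mins[[rb]] <- integer(0)
    }
  }
  merges <- if (length(merges)) do.call(rbind, merges) else
    data.frame(min_a = integer(0), min_b = integer(0), barrier = numeric(0))
  list(merges = merges, barriers = bmat)
}

#' Disconnectivity graph of an energy landscape
#'
#' The barrier between two local minima is the lowest energy level at which
#' their basins become connected on the single-flip hypercube, i.e. the
#' minimum over all connecting paths of the maximum energy en route
#' (endpoints included). The graph is the tree of basin merges.
#'
#' @param landscape an `energy_landscape`.
#' @return list with `minima` (codes), `merges` (data.frame of merge events
#'   `min_a`, `min_b`, `barrier`) and `barriers` (pairwise barrier matrix).
#' @export
disconnectivity_graph <- function(landscape) {
  if (length(landscape$local_minima) < 1) stop("no local minima", call. = FALSE)
  list(minima = landscape$local_minima, merges = landscape$merges,
       barriers = landscape$barriers)
}

#' Subject-wise energies of selected stable patterns
#'
#' For every subject and condition (pre/post window), fits a subject-level
#' maximum-entropy model to that subject's binarized network activity and
#' evaluates the energy of each selected group-level pattern. Alternatively
#' (`subject_fit = FALSE`) the group model's energies are attached unchanged,
#' which is only useful for diagnostics since they carry no between-subject
#' variation.
#'
#' @param roi_series_list named list of per-subject `roi_series` objects
#'   (each carrying `subject_id`, `group`, `site`).
#' @param network a `network_definition`.
#' @param selected_patterns integer codes of the group-level stable states.
#' @param subject_fit fit a per-subject model (default) rather than reusing
#'   the group model.
#' @param group_model group-level `maxent_model`, required when
#'   `subject_fit = FALSE`.
#' @param ... passed to [fit_maxent()].
#' @return a tidy data.frame: subject, group, site, condition, network,
#'   pattern_code, pattern_string, energy.
#' @export
subject_energies <- function(roi_series_list, network, selected_patterns,
                             subject_fit = TRUE, group_model = NULL, ...) {
  M <- length(network$regions)
  pats <- pattern_decode(selected_patterns, M)
  pat_str <- apply(pats, 1L, function(s) paste(ifelse(s > 0, "+", "-"), collapse = ""))
  rows <- list()
  for (rs in roi_series_list) {
    for (cond in c("pre", "post")) {
      bp <- binarize(rs, network, cond)
      en <- if (subject_fit) {
        fit <- tryCatch(fit_maxent(bp, ...), error = function(e) {
          stop(sprintf("subject '%s' (%s, %s): %s", rs$subject_id, network$name,
                       cond, conditionMessage(e)), call. = FALSE)
        })
        ising_energy(fit, pats)
      } else {
        if (is.null(group_model)) stop("group_model required when subject_fit = FALSE", call. = FALSE)
        ising_energy(group_model, pats)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        subject = rs$subject_id, group = rs$group, site = rs$site,
        condition = cond, network = network$name,
        pattern_code = selected_patterns, pattern_string = pat_str,
        energy = en, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
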