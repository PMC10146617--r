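#' Cohort specification
#'
#' Default subject counts per stimulation site follow the study design the
#' generator emulates: left motor cortex 22 patients / 27 controls, left
#' prefrontal cortex 9 / 18, vermis 12 / 25; about 60 TMS-locked trials per
#' subject.
#'
#' @param site_label one of `"left_motor"`, `"left_prefrontal"`, `"vermis"`.
#' @param n_patients,n_controls group sizes; defaults depend on the site.
#' @param n_trials_per_subject trials per subject.
#' @param artifact_fraction fraction of trials carrying an injected
#'   high-amplitude artifact (exercises the rejection gate).
#' @param seed integer seed; a fixed seed makes the cohort byte-identical.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(site_label = c("left_motor", "left_prefrontal", "vermis"),
                        n_patients = NULL, n_controls = NULL,
                        n_trials_per_subject = 60, artifact_fraction = 0.1,
                        seed = 1) {
  site_label <- match.arg(site_label)
  defaults <- list(left_motor = c(22L, 27L), left_prefrontal = c(9L, 18L),
                   vermis = c(12L, 25L))[[site_label]]
  n_patients <- if (is.null(n_patients)) defaults[1] else n_patients
  n_controls <- if (is.null(n_controls)) defaults[2] else n_controls
  stop_if_not_count(n_patients, "n_patients")
  stop_if_not_count(n_controls, "n_controls")
  stop_if_not_count(n_trials_per_subject, "n_trials_per_subject")
  stopifnot(artifact_fraction >= 0, artifact_fraction < 1)
  structure(list(site_label = site_label, n_patients = as.integer(n_patients),
                 n_controls = as.integer(n_controls),
                 n_trials_per_subject = as.integer(n_trials_per_subject),
                 artifact_fraction = artifact_fraction, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Ground-truth Ising parameters per group, condition and network
#'
#' Builds one base model (h, J) per network, shared across both groups and
#' both conditions, so that with `planted_delta_j = 0` the groups are
#' exchangeable by construction. A nonzero `planted_delta_j` is added to
#' every coupling of `planted_network` in the patients' post-TMS model only —
#' the planted group-difference effect that downstream stages must recover.
#'
#' Like the toy anatomy, the population model is a fixed study condition:
#' the default dispersions are zero, so the base model sits exactly at the
#' designed operating point (fields -0.1, couplings +0.15 — weakly
#' cooperative networks whose landscapes are dominated by the collective
#' all-active / all-inactive states the signature analysis reads out) and
#' `seed` matters only when nonzero dispersions are requested.
#'
#' @param networks named list of `network_definition`s.
#' @param seed integer seed (used when `h_sd` or `j_sd` is nonzero).
#' @param planted_network network receiving the planted effect.
#' @param planted_delta_j coupling shift applied to patients post-TMS.
#' @param h_mean,h_sd mean and dispersion of the base fields; the slightly
#'   negative mean biases regions toward inactivity.
#' @param j_mean,j_sd mean and dispersion of the base couplings.
#' @return object of class `ground_truth`: nested list
#'   `models[[group]][[condition]][[network]]` of `maxent_model`s plus the
#'   planted-effect description.
#' @export
ground_truth <- function(networks, seed = 1, planted_network = "sensorimotor",
                         planted_delta_j = 0.5, h_mean = -0.1, h_sd = 0,
                         j_mean = 0.15, j_sd = 0) {
  if (planted_delta_j != 0 && !planted_network %in% names(networks)) {
    stop(sprintf("planted network '%s' is not among the networks", planted_network),
         call. = FALSE)
  }
  base <- with_seed(seed, lapply(networks, function(nw) {
    M <- length(nw$regions)
    h <- stats::rnorm(M, h_mean, h_sd)
    J <- matrix(0, M, M)
    J[upper.tri(J)] <- stats::rnorm(M * (M - 1) / 2, j_mean, j_sd)
    J <- J + t(J)
    maxent_model(h, J)
  }))
  models <- list()
  for (g in c("patient", "control")) {
    models[[g]] <- list()
    for (cond in c("pre", "post")) models[[g]][[cond]] <- base
  }
  if (planted_delta_j != 0) {
    m <- models$patient$post[[planted_network]]
    J <- m$J
    J[upper.tri(J) | lower.tri(J)] <- J[upper.tri(J) | lower.tri(J)] + planted_delta_j
    models$patient$post[[planted_network]] <- maxent_model(m$h, J)
  }
  structure(list(models = models, planted_network = planted_network,
                 planted_delta_j = planted_delta_j, seed = seed),
            class = "ground_truth")
}

# raised-cosine smoothing of a piecewise-constant envelope (edge-padded)
smooth_envelope <- function(x, len) {
  if (len <= 1) return(x)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(len) / (len + 1))
  w <- w / sum(w)
  pad <- length(w)
  xp <- c(rep(x[1], pad), x, rep(x[length(x)], pad))
  stats::filter(xp, w, sides = 2)[(pad + 1):(pad + length(x))]
}

#' Synthesize one subject's TMS-locked EEG epochs
#'
#' Network states are drawn i.i.d. from the subject's (group, condition)
#' ground-truth Ising model, one pattern per 200 ms frame (5 frames per 1-s
#' window, matched to the alpha filter's ~5 Hz envelope bandwidth: faster
#' switching cannot survive an 8-12 Hz filter), and held fixed across trials: only trial-locked signal survives
#' ERP averaging, so the planted structure must be deterministic within a
#' subject. Each ROI is driven by the first network containing it; its state
#' modulates the amplitude (active 2.0, inactive 0.6, smoothed 50 ms ramps)
#' of an alpha carrier (9-11 Hz, subject-fixed frequency and phase). Voxel
#' dipole moments point along the head model's fixed orientations, scalp
#' data are `K %*% moments` plus Gaussian sensor noise, and a configurable
#' fraction of trials receives a +/-120 uV 100-ms square pulse on one random
#' channel to exercise the rejection gate.
#'
#' @param subject_id,group subject metadata (`group` is `"patient"` or
#'   `"control"`).
#' @param spec a `cohort_spec`.
#' @param truth a `ground_truth`.
#' @param head a `toy_head_model`.
#' @param seed subject-level integer seed.
#' @param noise_sd_uv sensor noise standard deviation (microvolts).
#' @param amp_active,amp_inactive source amplitudes (arbitrary units).
#' @param dwell_ms state frame duration in milliseconds.
#' @param fs_hz raw sampling rate; the epoch is 2 s centred on the pulse.
#' @return an `epoch_set` with attribute `"states"`: the drawn ground-truth
#'   frame patterns per network and condition.
#' @export
synthesize_subject <- function(subject_id, group, spec, truth, head, seed,
                               noise_sd_uv = 5, amp_active = 8,
                               amp_inactive = 0.8, dwell_ms = 200,
                               fs_hz = 1000) {
  n_samp <- 2L * fs_hz          # 1 s pre + 1 s post
  half <- fs_hz
  dwell <- round(dwell_ms * fs_hz / 1000)
  frames_per_window <- half %/% dwell
  stopifnot(frames_per_window * dwell == half)
  networks <- head$networks
  owner <- roi_owner(networks)
  rois <- names(owner)

  with_seed(seed, {
    # ground-truth frame states per network and condition
    states <- list()
    for (cond in c("pre", "post")) {
      states[[cond]] <- lapply(names(networks), function(nwname) {
        sample_ising(truth$models[[group]][[cond]][[nwname]], frames_per_window)
      })
      names(states[[cond]]) <- names(networks)
    }
    # ROI envelopes over the raw epoch; one alpha frequency per subject
    # (a subject's alpha rhythm is shared across regions; distinct per-region
    # frequencies would beat against each other at < 2 Hz, i.e. exactly in
    # the envelope band the landscape stage reads)
    t_raw <- seq_len(n_samp) / fs_hz
    alpha_freq <- stats::runif(1, 9, 11)
    roi_amp <- matrix(0, length(rois), n_samp, dimnames = list(rois, NULL))
    for (i in seq_along(rois)) {
      nw <- owner[i]
      ridx <- match(rois[i], networks[[nw]]$regions)
      s_seq <- c(rep(states$pre[[nw]][, ridx], each = dwell),
                 rep(states$post[[nw]][, ridx], each = dwell))
      amp <- amp_inactive + (amp_active - amp_inactive) * (s_seq + 1) / 2
      roi_amp[i, ] <- smooth_envelope(amp, round(0.05 * fs_hz))
    }
    # voxel moments along the head model's orthogonal-triad orientations;
    # each dipole gets its own carrier phase, so a region radiates like an
    # unpolarized oscillator: its envelope reaches the scalp through three
    # orthogonal topographies that cannot jointly cancel, while
    # cross-region interference in estimated power has random sign instead
    # of systematically masquerading as envelope modulation
    nv <- head$n_voxels
    moments <- matrix(0, 3L * nv, n_samp)
    nvox_roi <- table(head$voxel_roi)
    for (v in seq_len(nv)) {
      r <- head$voxel_roi[v]
      i <- match(r, rois)
      ph <- stats::runif(1, 0, 2 * pi)
      x <- roi_amp[i, ] * sin(2 * pi * alpha_freq * t_raw + ph) /
        sqrt(nvox_roi[[r]])
      moments[(3L * v - 2L):(3L * v), ] <- outer(head$voxel_orient[v, ], x)
    }
    phi0 <- head$K %*% moments
    n_ch <- nrow(phi0)
    n_tr <- spec$n_trials_per_subject
    artifact <- stats::runif(n_tr) < spec$artifact_fraction
    # one noise draw for all trials; the clean scalp pattern recycles per
    # trial slab, then the trial dimension moves first
    data <- aperm(array(stats::rnorm(n_tr * n_ch * n_samp, 0, noise_sd_uv),
                        dim = c(n_ch, n_samp, n_tr)) + as.vector(phi0),
                  c(3L, 1L, 2L))
    pulse_len <- round(0.1 * fs_hz)
    for (k in which(artifact)) {
      ch <- sample.int(n_ch, 1L)
      start <- sample.int(n_samp - pulse_len, 1L)
      data[k, ch, start:(start + pulse_len - 1L)] <-
        data[k, ch, start:(start + pulse_len - 1L)] + sample(c(-120, 120), 1L)
    }
    es <- epoch_set(data, fs_hz, half, head$electrode_labels,
                    subject_id = subject_id, group = group,
                    site = spec$site_label)
    attr(es, "states") <- states
    attr(es, "artifact_trials") <- which(artifact)
    es
  })
}

#' Synthesize a full cohort for one stimulation site
#'
#' One `epoch_set` per subject (patients then controls), each generated from
#' a per-subject substream of the cohort seed, so cohorts are reproducible
#' and adding subjects does not reshuffle existing ones.
#'
#' @param spec a `cohort_spec`.
#' @param truth a `ground_truth`.
#' @param head a `toy_head_model`.
#' @param ... passed to [synthesize_subject()].
#' @return list with `subjects` (list of `epoch_set`s), `manifest`
#'   (data.frame subject_id, group, site, seed) and `truth`.
#' @export
synthesize_cohort <- function(spec, truth, head, ...) {
  ids <- c(sprintf("%s_P%02d", spec$site_label, seq_len(spec$n_patients)),
           sprintf("%s_C%02d", spec$site_label, seq_len(spec$n_controls)))
  groups <- rep(c("patient", "control"), c(spec$n_patients, spec$n_controls))
  subjects <- vector("list", length(ids))
  seeds <- integer(length(ids))
  for (i in seq_along(ids)) {
    seeds[i] <- derive_seed(spec$seed, i)
    subjects[[i]] <- synthesize_subject(ids[i], groups[i], spec, truth, head,
                                        seed = seeds[i], ...)
  }
  names(subjects) <- ids
  manifest <- data.frame(subject_id = ids, group = groups,
                         site = spec$site_label, seed = seeds,
                         stringsAsFactors = FALSE)
  list(subjects = subjects, manifest = manifest, truth = truth, spec = spec)
}
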