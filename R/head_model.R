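#' Standard 11-channel electrode montage
#'
#' Approximate extended 10-20 positions (unit-sphere coordinates) for the
#' 11-channel cap: F3, FZ, F4, T3, CZ, T4, P3, PZ, P4, O1, O2. In head
#' coordinates +x is right (T4 side), +y anterior (FZ side), +z the vertex.
#'
#' @return 11 x 3 matrix of electrode positions with row names.
#' @keywords internal
electrode_positions <- function() {
  # (theta from vertex, phi azimuth) in degrees, then to cartesian
  ang <- rbind(
    F3 = c(50, 130), FZ = c(45, 90), F4 = c(50, 50),
    T3 = c(90, 180), CZ = c(0, 0),  T4 = c(90, 0),
    P3 = c(50, 230), PZ = c(45, 270), P4 = c(50, 310),
    O1 = c(80, 255), O2 = c(80, 285))
  th <- ang[, 1] * pi / 180
  ph <- ang[, 2] * pi / 180
  pos <- cbind(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
  rownames(pos) <- rownames(ang)
  pos
}

# schematic centroid direction (anterior y, up z) per network; laterality
# comes from the region name
network_centroids <- function() {
  rbind(sensorimotor   = c(0, 0.00, 1.00),   # central strip, under the vertex
        auditory       = c(0, -0.20, 0.45),  # temporal, strongly lateralized
        default_mode   = c(0, -0.35, 0.90),  # medial parietal / precuneus
        visual         = c(0, -0.95, 0.40),  # occipital, under O1/O2
        frontoparietal = c(0, 0.80, 0.65),   # frontal with a parietal wing
        salience       = c(0, 0.45, 0.90),   # cingulo-opercular, fronto-medial
        attention      = c(0, -0.50, 0.75))  # temporo-parietal
}

# deterministic schematic position for each ROI: its owner network's
# centroid, a lateral shift read off the region name (Left/Right; midline
# regions stay medial), and a small within-network anterior-posterior fan so
# same-side regions do not coincide
roi_positions <- function(networks, radius = 0.62) {
  rois <- all_rois(networks)
  owner <- roi_owner(networks)
  cents <- network_centroids()
  pos <- matrix(0, length(rois), 3, dimnames = list(rois, NULL))
  idx_in_nw <- stats::ave(seq_along(rois), owner, FUN = seq_along)
  n_in_nw <- stats::ave(seq_along(rois), owner, FUN = length)
  for (i in seq_along(rois)) {
    nm <- rois[i]
    base <- cents[owner[i], ]
    x <- if (grepl("^Left ", nm)) -0.55 else if (grepl("^Right ", nm)) 0.55 else
      0.18 * (((idx_in_nw[i] - 1L) %% 3L) - 1L)
    fan <- 0.25 * ((idx_in_nw[i] - 0.5) / n_in_nw[i] - 0.5)
    d <- c(x, base[2] + fan, base[3])
    pos[i, ] <- radius * d / sqrt(sum(d^2))
  }
  pos
}

#' Build a toy head model (lead field + ROI lookup tables)
#'
#' Schematic-anatomy forward model for the 11-channel montage. Each ROI has
#' a deterministic position on a cortical shell (radius 0.62 under the
#' unit-radius electrode sphere): its owner network's canonical centroid
#' (sensorimotor central, visual occipital, auditory temporal, and so on),
#' lateralized according to the Left/Right prefix of the region name, with a
#' small within-network fan so regions do not coincide — anatomy is a fixed
#' study condition, identical across seeds (the `seed` argument is kept for
#' interface stability but the construction is fully deterministic). The
#' lead field `K` (channels x 3*n_voxels) maps free-orientation dipole
#' moments to scalp potentials with the infinite-homogeneous-medium kernel
#' `(r_e - r_v) / (4 pi |r_e - r_v|^3)` and is rescaled to unit mean column
#' norm. A region's voxels cycle through an orthonormal orientation triad,
#' making each regional source unpolarized: its scalp visibility cannot be
#' cancelled by any orientation or phase draw. Voxels are assigned
#' round-robin to the distinct ROIs referenced by the networks, so every ROI
#' owns at least one voxel.
#'
#' @param n_voxels number of voxels; must be at least the number of distinct
#'   ROIs across all networks.
#' @param seed integer seed, unused by the deterministic construction.
#' @param networks named list of `network_definition`s.
#' @return object of class `toy_head_model`: `K`, `electrode_labels`,
#'   `voxel_roi` (character, length n_voxels), `voxel_pos`, `voxel_orient`
#'   (fixed source orientations used by the generator), `roi_to_network`
#'   (data.frame roi/network, one row per membership), `networks`.
#' @export
make_head_model <- function(n_voxels = 78, seed = 1, networks = default_networks()) {
  stop_if_not_count(n_voxels, "n_voxels")
  rois <- all_rois(networks)
  if (n_voxels < length(rois)) {
    uncovered <- rois[(n_voxels + 1L):length(rois)]
    stop(sprintf("n_voxels = %d leaves ROI(s) without voxels: %s",
                 n_voxels, paste(uncovered, collapse = ", ")), call. = FALSE)
  }
  if (!all(roi_owner(networks) %in% rownames(network_centroids()))) {
    stop("every network needs a schematic centroid; known networks: ",
         paste(rownames(network_centroids()), collapse = ", "), call. = FALSE)
  }
  epos <- electrode_positions()
  voxel_roi <- rois[((seq_len(n_voxels) - 1L) %% length(rois)) + 1L]
  centers <- roi_positions(networks)
  # anatomy is deterministic: voxels scatter around their region centre
  # with a fixed (internally seeded) draw, the same for every model built
  # with the same networks and voxel count
  axis <- diag(3)[((seq_len(n_voxels) - 1L) %% 3L) + 1L, , drop = FALSE]
  vpos <- centers[voxel_roi, , drop = FALSE] +
    with_seed(1L, matrix(stats::rnorm(3 * n_voxels, 0, 0.05), ncol = 3))
  # cortex stays below the electrode shell
  r <- sqrt(rowSums(vpos^2))
  vpos <- vpos * ifelse(r > 0.8, 0.8 / r, 1)
  # a region's dipoles span all three axes (cycling an orthonormal triad):
  # the regional source is unpolarized, so no orientation or phase draw can
  # cancel its scalp visibility, and neighbouring regions never share a
  # single common topography
  orient <- axis
  K <- matrix(0, nrow(epos), 3L * n_voxels)
  for (v in seq_len(n_voxels)) {
    d <- sweep(epos, 2L, vpos[v, ])           # r_e - r_v, per electrode
    dist3 <- rowSums(d^2)^1.5
    K[, (3L * v - 2L):(3L * v)] <- d / (4 * pi * dist3)
  }
  model <- list(vpos = vpos, orient = orient, K = K)
  K <- model$K / mean(sqrt(colSums(model$K^2)))
  if (qr(K)$rank < nrow(K)) stop("degenerate lead field: K is not full row rank", call. = FALSE)
  r2n <- do.call(rbind, lapply(networks, function(nw)
    data.frame(roi = nw$regions, network = nw$name, stringsAsFactors = FALSE)))
  rownames(r2n) <- NULL
  structure(list(K = K, electrode_labels = rownames(epos),
                 voxel_roi = voxel_roi, voxel_pos = model$vpos,
                 voxel_orient = model$orient, roi_centers = centers,
                 roi_to_network = r2n,
                 networks = networks, n_voxels = n_voxels, seed = seed),
            class = "toy_head_model")
}

#' @export
print.toy_head_model <- function(x, ...) {
  cat(sprintf("Toy head model: %d electrodes x %d voxels (K is %d x %d), %d ROIs, %d networks\n",
              nrow(x$K), x$n_voxels, nrow(x$K), ncol(x$K),
              length(unique(x$voxel_roi)), length(x$networks)))
  invisible(x)
}
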