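#' Simulate two-channel ciliary image volumes with a target-channel reduction
#'
#' Generates two groups of two-channel 3D stacks ("control" and
#' "knockdown"): the marker channel defines `n_regions` elongated,
#' capsule-shaped ciliary regions per volume; the target channel carries a
#' mean intensity that is `(1 - reduction_fraction)` times the control mean
#' in the knockdown group, modulated by a per-volume lognormal staining
#' factor and voxel-level Gaussian noise. Regions are laid out on a jittered
#' grid, so masks are disjoint and inside the volume by construction.
#'
#' Optionally, each region carries a "ciliary dilation" sub-region at its
#' distal (+x) end; with probability `dilation_signal_prob` the target
#' channel receives extra signal there, and the ground truth records which
#' cilia are positive.
#'
#' @param reduction_fraction Target-channel reduction in the knockdown
#'   group, in `[0, 1)`.
#' @param n_regions Ciliary regions per volume (> 0).
#' @param n_volumes_per_group Volumes ("antennae") per group.
#' @param dims Volume dimensions `c(z, y, x)` in voxels.
#' @param voxel_size_um Voxel size `c(z, y, x)` in micrometres.
#' @param marker_level,target_level Mean in-region intensities (counts).
#' @param background Mean out-of-region intensity (counts).
#' @param noise_sd Voxel Gaussian noise SD (counts).
#' @param volume_cv Per-volume lognormal staining coefficient of variation.
#' @param dilation_signal_prob Probability a cilium carries dilation signal
#'   (`NULL` to disable dilation simulation).
#' @param seed RNG seed (mandatory).
#' @return A list with `volumes` (list of `labeled_volume`s: `channels`
#'   (marker, target), `voxel_size_um`, `group_label`) and `truth`
#'   (`label_arrays`, `dilation_arrays`, `dilation_positive`, `groups`,
#'   `volume_factors`, `reduction_fraction`).
#' @export
simulate_quant_volume <- function(reduction_fraction = 0.09, n_regions = 10,
                                  n_volumes_per_group = 10,
                                  dims = c(16, 64, 64),
                                  voxel_size_um = c(0.4, 0.13, 0.13),
                                  marker_level = 150, target_level = 100,
                                  background = 20, noise_sd = 10,
                                  volume_cv = 0.03,
                                  dilation_signal_prob = NULL,
                                  seed = 1) {
  stopifnot(reduction_fraction >= 0, reduction_fraction < 1,
            n_regions >= 1, n_volumes_per_group >= 1,
            length(dims) == 3, all(dims >= 8), all(voxel_size_um > 0))
  set.seed(seed)

  nz <- dims[1]; nyy <- dims[2]; nxx <- dims[3]
  # jittered grid of region anchors (disjoint by cell construction)
  n_cols <- ceiling(sqrt(n_regions))
  n_rows <- ceiling(n_regions / n_cols)
  cell_y <- floor(nyy / n_rows)
  cell_x <- floor(nxx / n_cols)
  half_len <- 6L   # capsule half-length along x (voxels)
  radius <- 2L     # capsule radius in y and z (voxels)
  stopifnot(cell_y >= 2 * radius + 2, cell_x >= 2 * half_len + 2)

  make_volume <- function(group) {
    lab <- array(0L, dims)
    dil <- array(0L, dims)
    rid <- 0L
    for (gy in seq_len(n_rows)) {
      for (gx in seq_len(n_cols)) {
        if (rid >= n_regions) break
        rid <- rid + 1L
        cy <- (gy - 1) * cell_y + radius + 1 +
          sample.int(cell_y - 2 * radius - 1, 1)
        cx <- (gx - 1) * cell_x + half_len +
          sample.int(max(1, cell_x - 2 * half_len - 3), 1)
        cz <- radius + 1 + sample.int(nz - 2 * radius - 1, 1)
        zr <- max(1, cz - radius):min(nz, cz + radius)
        yr <- max(1, cy - radius):min(nyy, cy + radius)
        xr <- max(1, cx - half_len):min(nxx, cx + half_len)
        # capsule: within radius of the x-axis through (cz, cy)
        for (z in zr) for (y in yr) {
          if ((z - cz)^2 + (y - cy)^2 <= radius^2) {
            lab[z, y, xr] <- rid
          }
        }
        # dilation: a small blob just distal (+x) of the capsule tip, so a
        # negative cilium's dilation sees only background
        dz <- max(1, cz - 1):min(nz, cz + 1)
        dy <- max(1, cy - 1):min(nyy, cy + 1)
        dx <- min(nxx, cx + half_len + 1):min(nxx, cx + half_len + 2)
        dil[dz, dy, dx] <- rid
      }
    }
    factor <- exp(stats::rnorm(1, 0, volume_cv))
    eff <- if (group == "knockdown") 1 - reduction_fraction else 1
    inside <- lab > 0
    marker <- array(background, dims) + marker_level * inside
    # the knockdown factor scales the whole in-region staining (baseline
    # included), so the group mean ratio is (1 - reduction) by construction
    target <- array(background, dims)
    target[inside] <- (background + target_level * factor) * eff
    dil_pos <- logical(n_regions)
    if (!is.null(dilation_signal_prob)) {
      dil_pos <- stats::runif(n_regions) < dilation_signal_prob
      for (r in which(dil_pos)) {
        target[dil == r] <- target[dil == r] + target_level * factor
      }
    }
    marker <- marker + stats::rnorm(length(marker), 0, noise_sd)
    target <- target + stats::rnorm(length(target), 0, noise_sd)
    list(
      volume = structure(
        list(channels = list(marker = pmax(marker, 0),
                             target = pmax(target, 0)),
             voxel_size_um = voxel_size_um, group_label = group),
        class = "labeled_volume"
      ),
      lab = lab, dil = dil, dil_pos = dil_pos, factor = factor
    )
  }

  groups <- rep(c("control", "knockdown"), each = n_volumes_per_group)
  made <- lapply(groups, make_volume)
  list(
    volumes = lapply(made, `[[`, "volume"),
    truth = list(
      label_arrays = lapply(made, `[[`, "lab"),
      dilation_arrays = lapply(made, `[[`, "dil"),
      dilation_positive = lapply(made, `[[`, "dil_pos"),
      groups = groups,
      volume_factors = vapply(made, `[[`, numeric(1), "factor"),
      reduction_fraction = reduction_fraction
    )
  )
}
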