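#' Segment marker-positive ciliary regions in a volume
#'
#' Otsu threshold on the marker channel, then 26-connected components in
#' 3D; components smaller than `min_voxels` are removed. This replaces
#' interactive surface segmentation with a deterministic, reproducible
#' procedure.
#'
#' @param vol A `labeled_volume` (see [simulate_quant_volume()]).
#' @param marker_channel Name of the marker channel (default `"marker"`).
#' @param min_voxels Minimum component size in voxels (default 20).
#' @return Integer label array of the volume's shape; 0 = background.
#'   Possibly all-zero if every component is below `min_voxels`.
#' @export
segment_marker_regions <- function(vol, marker_channel = "marker",
                                   min_voxels = 20) {
  stopifnot(inherits(vol, "labeled_volume"))
  x <- vol$channels[[marker_channel]]
  if (is.null(x)) stop("marker channel '", marker_channel, "' not found")
  rng <- range(x)
  if (diff(rng) == 0) stop("no threshold: marker channel is constant")
  xn <- (x - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(matrix(xn, nrow = dim(x)[2])),
                       range = c(0, 1))
  fg <- xn > thr
  label_components_3d(fg, min_voxels = min_voxels)
}

# 26-connected component labelling of a logical 3D array, via a voxel
# adjacency graph (igraph); components below min_voxels get label 0.
label_components_3d <- function(fg, min_voxels = 1) {
  d <- dim(fg)
  idx <- which(fg)
  lab <- array(0L, d)
  if (!length(idx)) return(lab)
  coord <- arrayInd(idx, d)
  vox_id <- seq_along(idx)
  pos <- array(0L, d)
  pos[idx] <- vox_id
  offsets <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offsets <- offsets[rowSums(abs(offsets)) > 0, ]
  offsets <- offsets[offsets[, 1] > 0 |
                       (offsets[, 1] == 0 & offsets[, 2] > 0) |
                       (offsets[, 1] == 0 & offsets[, 2] == 0 &
                          offsets[, 3] > 0), , drop = FALSE]
  edges <- NULL
  for (k in seq_len(nrow(offsets))) {
    nb <- sweep(coord, 2, offsets[k, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
      nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (!any(ok)) next
    nb_id <- pos[nb[ok, , drop = FALSE]]
    src <- vox_id[ok]
    hit <- nb_id > 0
    if (any(hit)) edges <- c(edges, rbind(src[hit], nb_id[hit]))
  }
  g <- igraph::make_graph(edges = if (is.null(edges)) integer(0) else edges,
                          n = length(idx), directed = FALSE)
  comp <- igraph::components(g)
  sizes <- comp$csize[comp$membership]
  keep <- sizes >= min_voxels
  relab <- integer(comp$no)
  kept_comps <- sort(unique(comp$membership[keep]))
  relab[kept_comps] <- seq_along(kept_comps)
  lab[idx[keep]] <- relab[comp$membership[keep]]
  lab
}

#' Per-region target-channel intensity statistics
#'
#' Mean target intensity per segmented region plus the per-volume
#' ("per antenna") average across regions - the summary the group
#' comparison operates on.
#'
#' @param vol A `labeled_volume`.
#' @param masks Integer label array from [segment_marker_regions()] (or
#'   ground truth).
#' @param target_channel Name of the target channel (default `"target"`).
#' @return A `region_stats` list: `regions` data frame (`id`,
#'   `voxel_count`, `target_mean_intensity`) and `volume_mean`.
#' @export
region_intensity_stats <- function(vol, masks, target_channel = "target") {
  stopifnot(inherits(vol, "labeled_volume"))
  tgt <- vol$channels[[target_channel]]
  if (is.null(tgt)) stop("target channel '", target_channel, "' not found")
  stopifnot(all(dim(masks) == dim(tgt)))
  ids <- sort(unique(masks[masks > 0]))
  if (!length(ids)) {
    return(structure(list(
      regions = data.frame(id = integer(), voxel_count = integer(),
                           target_mean_intensity = numeric()),
      volume_mean = NA_real_), class = "region_stats"))
  }
  means <- vapply(ids, function(i) mean(tgt[masks == i]), numeric(1))
  counts <- vapply(ids, function(i) sum(masks == i), integer(1))
  structure(
    list(regions = data.frame(id = ids, voxel_count = counts,
                              target_mean_intensity = means),
         volume_mean = mean(means)),
    class = "region_stats"
  )
}

#' Normalise intensity values to the control group
#'
#' Divides every value by the control-group median (per experiment batch),
#' so the normalised control median is 1 by construction.
#'
#' @param values Numeric values to normalise.
#' @param control_values Control-group values of the same batch.
#' @return Normalised values.
#' @export
normalize_to_control <- function(values, control_values) {
  if (!length(control_values)) stop("control group is empty")
  m <- stats::median(control_values)
  if (m == 0) stop("control median is zero")
  values / m
}

#' Percentage of cilia with target signal at the ciliary dilation
#'
#' A cilium counts as positive when the mean target intensity over its
#' dilation mask exceeds the background mean by more than `positivity_k`
#' background standard deviations. Background statistics come from voxels
#' outside all dilation and region masks.
#'
#' @param volumes List of `labeled_volume`s.
#' @param dilation_masks List of integer label arrays (one per volume)
#'   marking each cilium's dilation.
#' @param target_channel Name of the target channel.
#' @param positivity_k Threshold in background SDs (default 2).
#' @param region_masks Optional list of region label arrays also excluded
#'   from the background estimate.
#' @return Percentage (0-100) of positive cilia across all volumes, with
#'   attribute `"n"` (total cilia assessed).
#' @export
dilation_positive_fraction <- function(volumes, dilation_masks,
                                       target_channel = "target",
                                       positivity_k = 2,
                                       region_masks = NULL) {
  stopifnot(length(volumes) == length(dilation_masks))
  n_pos <- 0L
  n_tot <- 0L
  for (i in seq_along(volumes)) {
    tgt <- volumes[[i]]$channels[[target_channel]]
    dil <- dilation_masks[[i]]
    excl <- dil > 0
    if (!is.null(region_masks)) excl <- excl | region_masks[[i]] > 0
    bg <- tgt[!excl]
    bg_mean <- mean(bg)
    bg_sd <- stats::sd(bg)
    for (r in sort(unique(dil[dil > 0]))) {
      n_tot <- n_tot + 1L
      if (mean(tgt[dil == r]) > bg_mean + positivity_k * bg_sd) {
        n_pos <- n_pos + 1L
      }
    }
  }
  if (n_tot == 0) stop("no cilia to assess")
  structure(100 * n_pos / n_tot, n = n_tot)
}

#' Bending angle between dendrite and cilium
#'
#' Fits a principal axis to each point set and returns the deviation from
#' collinear continuation, folded to [0, 90] degrees: 0 means the cilium
#' projects straight out of the dendrite, 90 means perpendicular. Invariant
#' under rigid rotation and reflection.
#'
#' @param dendrite_pts,cilium_pts Matrices (>= 2 rows) of point
#'   coordinates (2D or 3D).
#' @return Angle in degrees.
#' @export
bending_angle <- function(dendrite_pts, cilium_pts) {
  axis_of <- function(p) {
    p <- as.matrix(p)
    if (nrow(p) < 2) stop("need at least 2 points per segment")
    pc <- sweep(p, 2, colMeans(p))
    if (all(abs(pc) < .Machine$double.eps^0.5)) {
      stop("coincident points: no direction defined")
    }
    v <- svd(pc)$v[, 1]
    v / sqrt(sum(v^2))
  }
  d <- axis_of(dendrite_pts)
  c_ <- axis_of(cilium_pts)
  cosang <- min(1, abs(sum(d * c_)))
  acos(cosang) * 180 / pi
}

#' Mann-Whitney comparison of two groups
#'
#' Two-sided Mann-Whitney U test: exact distribution for small untied
#' samples (both n <= 8), normal approximation with tie correction
#' otherwise. Also reports the median percent change of `b` relative to
#' `a`.
#'
#' @param a,b Numeric vectors (>= 3 values each).
#' @return A `group_comparison` list: `U`, `p`, `median_pct_change`,
#'   `n_a`, `n_b`.
#' @export
compare_groups <- function(a, b) {
  if (!length(a) || !length(b)) stop("empty group")
  stopifnot(length(a) >= 3, length(b) >= 3)
  exact <- length(a) <= 8 && length(b) <= 8 &&
    !any(duplicated(c(a, b)))
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = !exact)
  )
  structure(
    list(U = unname(wt$statistic), p = wt$p.value,
         median_pct_change = 100 * (stats::median(b) / stats::median(a) - 1),
         n_a = length(a), n_b = length(b)),
    class = "group_comparison"
  )
}
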