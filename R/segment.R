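#' Segmentation parameters for the 3D foci pipeline
#'
#' @param blur_sigma_px lateral Gaussian sigma (pixels) applied to the DAPI
#'   channel before per-slice thresholding.
#' @param min_nucleus_volume_vox minimum nucleus size (voxels).
#' @param min_focus_volume_vox minimum focus size (voxels).
#' @param connectivity 3D connectivity for component labeling: 6, 18 or 26.
#' @param fish_otsu `"global"` (one Otsu threshold on the whole 3D FISH
#'   volume, the default) or `"per-slice"`.
#' @param slice_threshold_frac guard for per-slice DAPI thresholds: a
#'   slice's Otsu threshold is used only if it is at least this fraction of
#'   the global 3D Otsu threshold of the blurred DAPI volume; slices failing
#'   the guard (e.g. slices with no nucleus, where Otsu would split the
#'   background noise) contribute no foreground.
#' @param assignment_rule `"overlap"` (maximal voxel overlap, default) or
#'   `"centroid"` (containment of the focus centroid voxel).
#' @return a list of class `seg_params`.
#' @export
seg_params <- function(blur_sigma_px = 2.0,
                       min_nucleus_volume_vox = 500L,
                       min_focus_volume_vox = 2L,
                       connectivity = 26L,
                       fish_otsu = c("global", "per-slice"),
                       slice_threshold_frac = 0.5,
                       assignment_rule = c("overlap", "centroid")) {
  fish_otsu <- match.arg(fish_otsu)
  assignment_rule <- match.arg(assignment_rule)
  stopifnot(blur_sigma_px >= 0, min_nucleus_volume_vox >= 1,
            min_focus_volume_vox >= 1, connectivity %in% c(6L, 18L, 26L))
  structure(list(blur_sigma_px = blur_sigma_px,
                 min_nucleus_volume_vox = as.integer(min_nucleus_volume_vox),
                 min_focus_volume_vox = as.integer(min_focus_volume_vox),
                 connectivity = as.integer(connectivity),
                 fish_otsu = fish_otsu,
                 slice_threshold_frac = slice_threshold_frac,
                 assignment_rule = assignment_rule),
            class = "seg_params")
}

# Gaussian kernel identical to the compiled one (3.5-sigma truncation).
.gauss_kernel <- function(sigma) {
  r <- ceiling(3.5 * sigma)
  k <- exp(-0.5 * ((-r:r) / sigma)^2)
  k / sum(k)
}

#' Separable 3D Gaussian blur
#'
#' @param vol 3D numeric array `(z, y, x)`.
#' @param sigma_vox sigmas in voxels `(z, y, x)`; zero skips an axis.
#' @return blurred array of the same dimensions.
#' @export
blur3d <- function(vol, sigma_vox) {
  stopifnot(length(dim(vol)) == 3L, length(sigma_vox) == 3L,
            all(sigma_vox >= 0))
  blur3d_cpp(vol, dim(vol), as.numeric(sigma_vox))
}

# Fill holes in a binary slice: background 4-connected components not
# touching the slice border are holes.
.fill_holes_slice <- function(mask2d) {
  d <- dim(mask2d)
  inv <- !mask2d
  lab <- label3d_cpp(array(inv, c(1L, d)), c(1L, d), 6L)
  lab <- array(lab, d)
  border <- unique(c(lab[1, ], lab[d[1], ], lab[, 1], lab[, d[2]]))
  border <- border[border > 0]
  holes <- inv & !(lab %in% border)
  mask2d | holes
}

# Centroid (um) of each label in a 3D label array; returns a data.frame.
.measure_labels <- function(labels, spacing, values = NULL) {
  pos <- which(labels > 0L)
  if (length(pos) == 0L)
    return(data.frame(label = integer(), volume_vox = integer(),
                      volume_um3 = numeric(), centroid_z_um = numeric(),
                      centroid_y_um = numeric(), centroid_x_um = numeric(),
                      integrated_intensity = numeric()))
  d <- dim(labels)
  lab <- labels[pos]
  z <- (pos - 1L) %% d[1] + 1L
  y <- ((pos - 1L) %/% d[1]) %% d[2] + 1L
  x <- (pos - 1L) %/% (d[1] * d[2]) + 1L
  ids <- sort(unique(lab))
  f <- factor(lab, levels = ids)
  vol <- as.integer(tabulate(f, nbins = length(ids)))
  # voxel-center physical coordinates
  cz <- tapply((z - 0.5) * spacing[1], f, mean)
  cy <- tapply((y - 0.5) * spacing[2], f, mean)
  cx <- tapply((x - 0.5) * spacing[3], f, mean)
  ii <- if (is.null(values)) rep(NA_real_, length(ids)) else
    as.numeric(tapply(values[pos], f, sum))
  data.frame(label = ids, volume_vox = vol,
             volume_um3 = vol * prod(spacing),
             centroid_z_um = as.numeric(cz),
             centroid_y_um = as.numeric(cy),
             centroid_x_um = as.numeric(cx),
             integrated_intensity = ii)
}

#' Segment nuclei from the DAPI channel
#'
#' Per-slice pipeline: lateral Gaussian blur, Otsu threshold on the slice
#' histogram (guarded against empty slices, see [seg_params()]), binary
#' fill-holes; then 3D connected-component labeling across slices.
#' Components touching the X or Y image border anywhere are removed, as are
#' components below `min_nucleus_volume_vox`. Z borders are not an exclusion
#' criterion (stacks routinely truncate nuclei axially).
#'
#' @param stack an [image_stack()].
#' @param dapi_channel channel index of the nuclear stain.
#' @param params a [seg_params()].
#' @return list of class `xi_nuclei`: `table` (one row per retained nucleus:
#'   label, volume, centroid, `touches_xy_edge` flag — always `FALSE` for
#'   retained nuclei), `labels` (3D integer array; only retained labels are
#'   non-zero), `spacing`, `n_removed_edge`, `n_removed_small`.
#' @export
segment_nuclei <- function(stack, dapi_channel = 1L, params = seg_params()) {
  stopifnot(inherits(stack, "xi_stack"))
  d <- dim(stack$voxels)
  if (dapi_channel < 1 || dapi_channel > d[4]) stop("no such DAPI channel")
  v <- stack$voxels[, , , dapi_channel, drop = TRUE]
  dim(v) <- d[1:3]
  s <- params$blur_sigma_px
  vb <- blur3d(v, c(0, s, s))

  gh <- .int_hist(vb)
  t_global <- otsu_threshold(gh$levels, gh$counts)

  mask <- array(FALSE, d[1:3])
  for (z in seq_len(d[1])) {
    sl <- vb[z, , ]
    h <- .int_hist(sl)
    if (length(h$levels) < 2L) next  # zero-contrast slice: no foreground
    ts <- otsu_threshold(h$levels, h$counts)
    if (ts < params$slice_threshold_frac * t_global) next
    m <- sl > ts
    if (!any(m)) next
    mask[z, , ] <- .fill_holes_slice(m)
  }
  labels <- label3d_cpp(mask, dim(mask), params$connectivity)

  # XY edge exclusion
  edge <- unique(c(labels[, 1, ], labels[, d[2], ],
                   labels[, , 1], labels[, , d[3]]))
  edge <- edge[edge > 0]
  n_edge <- length(edge)
  if (n_edge > 0) labels[labels %in% edge] <- 0L

  meas <- .measure_labels(labels, stack$spacing)
  small <- meas$label[meas$volume_vox < params$min_nucleus_volume_vox]
  if (length(small) > 0) labels[labels %in% small] <- 0L
  meas <- meas[!(meas$label %in% small), , drop = FALSE]
  meas$integrated_intensity <- NULL
  meas$touches_xy_edge <- logical(nrow(meas))
  rownames(meas) <- NULL
  structure(list(table = meas, labels = labels, spacing = stack$spacing,
                 n_removed_edge = n_edge, n_removed_small = length(small)),
            class = "xi_nuclei")
}

#' Segment RNA-FISH foci
#'
#' One global Otsu threshold on the whole 3D FISH volume (or per-slice
#' thresholds when `params$fish_otsu == "per-slice"`), 3D connected
#' components at `params$connectivity`, components below
#' `min_focus_volume_vox` dropped.
#'
#' @inheritParams segment_nuclei
#' @param fish_channel channel index of the RNA-FISH signal.
#' @return list of class `xi_foci`: `table` (label, volume, centroid,
#'   integrated intensity, `assigned_nucleus` — `NA` until [assign_foci()]),
#'   `labels`, `spacing`, `threshold`.
#' @export
segment_foci <- function(stack, fish_channel = 2L, params = seg_params()) {
  stopifnot(inherits(stack, "xi_stack"))
  d <- dim(stack$voxels)
  if (fish_channel < 1 || fish_channel > d[4]) stop("no such FISH channel")
  v <- stack$voxels[, , , fish_channel, drop = TRUE]
  dim(v) <- d[1:3]

  if (params$fish_otsu == "global") {
    h <- .int_hist(v)
    thr <- otsu_threshold(h$levels, h$counts)
    mask <- v > thr
  } else {
    mask <- array(FALSE, d[1:3])
    thr <- rep(NA_real_, d[1])
    for (z in seq_len(d[1])) {
      h <- .int_hist(v[z, , ])
      if (length(h$levels) < 2L) next
      thr[z] <- otsu_threshold(h$levels, h$counts)
      mask[z, , ] <- v[z, , ] > thr[z]
    }
  }
  labels <- label3d_cpp(mask, dim(mask), params$connectivity)
  meas <- .measure_labels(labels, stack$spacing, values = v)
  small <- meas$label[meas$volume_vox < params$min_focus_volume_vox]
  if (length(small) > 0) labels[labels %in% small] <- 0L
  meas <- meas[!(meas$label %in% small), , drop = FALSE]
  meas$assigned_nucleus <- rep(NA_integer_, nrow(meas))
  rownames(meas) <- NULL
  structure(list(table = meas, labels = labels, spacing = stack$spacing,
                 threshold = thr),
            class = "xi_foci")
}
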