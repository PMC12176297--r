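#' Parameters for the synthetic two-channel nucleus image generator
#'
#' The generator emulates the confocal acquisitions used for 3D RNA-FISH
#' foci counting: ellipsoidal nuclei filled with a DAPI-like stain, plus an
#' RNA-FISH channel in which a fixed number of puncta per nucleus are either
#' concentrated in a sub-resolution "territory" (the Xi-like cloud) or
#' dispersed through the nucleoplasm. Puncta are convolved with an
#' anisotropic Gaussian PSF, photon shot noise is Poisson, read noise is
#' additive Gaussian, and intensities are digitized to 8-bit range by
#' default — bright territories saturate the detector, as real XIST clouds
#' do under acquisition settings that keep single molecules visible.
#'
#' @param stack_shape voxels `(n_z, n_y, n_x)`.
#' @param spacing micrometres `(dz, dy, dx)`; the 0.2 um z-step matches the
#'   acquisition protocol, the 0.1 um lateral pitch is a Nyquist-ish choice
#'   for a 1.4 NA lens.
#' @param n_nuclei nuclei per image (placed fully inside the XY field).
#' @param nucleus_radii list with `axial` and `lateral` min/max semi-axes
#'   (um).
#' @param n_puncta RNA puncta per nucleus (about 50 XIST copies per
#'   nucleus).
#' @param territory_radius radius (um) of the cluster sphere holding the
#'   localized puncta.
#' @param dispersed_fraction fraction of puncta placed uniformly in the
#'   nucleus instead of in the territory; 0 = fully localized, 1 = fully
#'   dispersed.
#' @param psf_sigma Gaussian PSF sigmas in um, `c(lateral, axial)`.
#' @param photon_scale mean photon count at the peak of one punctum.
#' @param dapi_scale mean photon count inside the nucleus (DAPI channel).
#' @param background offset counts added to both channels.
#' @param read_noise_sd SD of the additive Gaussian read noise (counts).
#' @param max_intensity digitizer ceiling (counts); default 255 (8-bit).
#' @param include_edge_nucleus add one deliberately edge-touching nucleus
#'   per image (to exercise the XY edge-exclusion rule); its ground truth is
#'   flagged `edge = TRUE`.
#' @return list of class `image_sim_params`.
#' @export
image_sim_params <- function(stack_shape = c(64L, 256L, 256L),
                             spacing = c(0.2, 0.1, 0.1),
                             n_nuclei = 2L,
                             nucleus_radii = list(axial = c(1.9, 2.2),
                                                  lateral = c(4.6, 5.6)),
                             n_puncta = 50L,
                             territory_radius = 0.1,
                             dispersed_fraction = 0.05,
                             psf_sigma = c(lateral = 0.15, axial = 0.4),
                             photon_scale = 160,
                             dapi_scale = 100,
                             background = 4,
                             read_noise_sd = 2,
                             max_intensity = 255,
                             include_edge_nucleus = FALSE) {
  stopifnot(length(stack_shape) == 3L, all(stack_shape >= 1),
            length(spacing) == 3L, all(spacing > 0),
            n_nuclei >= 0, n_puncta >= 0,
            territory_radius > 0,
            dispersed_fraction >= 0, dispersed_fraction <= 1,
            length(psf_sigma) == 2L, all(psf_sigma > 0),
            photon_scale >= 0, dapi_scale >= 0, background >= 0,
            read_noise_sd >= 0, max_intensity > 0)
  if (any(unlist(nucleus_radii) <= 0)) stop("nucleus radii must be > 0")
  structure(list(stack_shape = as.integer(stack_shape),
                 spacing = as.numeric(spacing),
                 n_nuclei = as.integer(n_nuclei),
                 nucleus_radii = nucleus_radii,
                 n_puncta = as.integer(n_puncta),
                 territory_radius = territory_radius,
                 dispersed_fraction = dispersed_fraction,
                 psf_sigma = c(lateral = unname(psf_sigma[1]),
                               axial = unname(psf_sigma[2])),
                 photon_scale = photon_scale, dapi_scale = dapi_scale,
                 background = background, read_noise_sd = read_noise_sd,
                 max_intensity = max_intensity,
                 include_edge_nucleus = include_edge_nucleus),
            class = "image_sim_params")
}

#' Shipped generator presets for the foci pipeline
#'
#' `"wt"` holds 5% of puncta outside the Xi territory; `"depleted"` uses a
#' dispersed fraction calibrated so that the expected ground-truth count of
#' resolvable foci per nucleus is twice the wt preset's, mirroring the
#' reported 2-fold increase on protein depletion.
#'
#' @param name `"wt"` or `"depleted"`.
#' @param ... overrides forwarded to [image_sim_params()].
#' @return an [image_sim_params()].
#' @export
foci_presets <- function(name = c("wt", "depleted"), ...) {
  name <- match.arg(name)
  df <- switch(name, wt = 0.05, depleted = .depleted_dispersed_fraction)
  image_sim_params(dispersed_fraction = df, ...)
}

# Calibrated against the wt preset: E[resolvable foci] doubles.
# See the methods vignette for the calibration procedure.
.depleted_dispersed_fraction <- 0.120

#' Number of resolvable foci from true punctum coordinates
#'
#' Ground-truth definition of a "resolvable focus": single-linkage merging
#' of puncta closer than `2 * psf_sigma_lateral` (a Rayleigh-type criterion
#' for what thresholding a PSF-blurred image can separate). Implemented as
#' union-find over all pairs.
#'
#' @param coords matrix of punctum coordinates (um), one row per punctum.
#' @param cutoff merge distance (um).
#' @return integer cluster count (0 for an empty coordinate set).
#' @export
resolvable_count <- function(coords, cutoff) {
  n <- nrow(coords)
  if (is.null(n) || n == 0L) return(0L)
  if (n == 1L) return(1L)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  d <- as.matrix(dist(coords))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      if (d[i, j] < cutoff) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

# Uniform point in the unit ball, scaled by r.
.runif_ball <- function(r) {
  v <- rnorm(3)
  v / sqrt(sum(v^2)) * r * runif(1)^(1 / 3)
}

# Voxel index (1-based) containing a physical coordinate.
.coord_to_voxel <- function(coord, spacing, dims) {
  pmax(1L, pmin(dims, as.integer(floor(coord / spacing)) + 1L))
}

#' Simulate a population of two-channel nucleus stacks with ground truth
#'
#' Channel 1 is the DAPI-like nuclear fill, channel 2 the RNA-FISH puncta
#' (Gaussian PSF, Poisson photon noise, Gaussian read noise, digitizer
#' clipping). Identical seeds give identical output.
#'
#' @param params an [image_sim_params()].
#' @param n_cells number of images to generate.
#' @param seed integer seed.
#' @return list with `stacks` (list of [image_stack()]) and `truth` (list,
#'   one entry per image, each a list of per-nucleus ground truths: `label`,
#'   `centroid_um`, `semiaxes_um`, `volume_vox`, `puncta_um` (matrix of
#'   punctum coordinates), `n_resolvable`, `edge` flag; plus the image's
#'   ground-truth `labels` array).
#' @export
sim_image_population <- function(params, n_cells, seed = 1L) {
  stopifnot(inherits(params, "image_sim_params"), n_cells >= 1)
  set.seed(seed)
  d <- params$stack_shape
  sp <- params$spacing
  fov <- d * sp  # physical field size (z, y, x)

  sig_vox <- c(params$psf_sigma[["axial"]] / sp[1],
               params$psf_sigma[["lateral"]] / sp[2],
               params$psf_sigma[["lateral"]] / sp[3])
  # peak factor of a voxel delta after normalized separable blur
  k0 <- prod(vapply(sig_vox, function(s)
    if (s <= 0) 1 else max(.gauss_kernel(s)), numeric(1)))
  cutoff <- 2 * params$psf_sigma[["lateral"]]

  ax_r <- params$nucleus_radii$axial
  lat_r <- params$nucleus_radii$lateral
  if (params$n_nuclei >= 1L && 2 * min(lat_r) >= min(fov[2], fov[3]))
    stop("placement failure: stack too small to hold one nucleus off the XY border")

  stacks <- vector("list", n_cells)
  truths <- vector("list", n_cells)

  for (cell in seq_len(n_cells)) {
    labels <- array(0L, d)
    n_total <- params$n_nuclei + as.integer(params$include_edge_nucleus)
    # an unlucky first placement can leave no room for the rest, so the
    # whole configuration is resampled when a nucleus cannot be placed
    place_all <- function() {
      centers <- matrix(NA_real_, n_total, 3)
      semis <- matrix(NA_real_, n_total, 3)
      placed <- 0L
      for (i in seq_len(params$n_nuclei)) {
        ok <- FALSE
        for (try in seq_len(100L)) {
          semi <- c(runif(1, ax_r[1], ax_r[2]),
                    runif(1, lat_r[1], lat_r[2]),
                    runif(1, lat_r[1], lat_r[2]))
          margin <- semi + sp  # one-voxel clearance from borders
          if (any(fov - 2 * margin <= 0)) next
          ctr <- c(runif(1, margin[1], fov[1] - margin[1]),
                   runif(1, margin[2], fov[2] - margin[2]),
                   runif(1, margin[3], fov[3] - margin[3]))
          if (placed > 0L) {
            sep <- sqrt(rowSums((centers[seq_len(placed), , drop = FALSE] -
                                   matrix(ctr, placed, 3, byrow = TRUE))^2))
            req <- apply(semis[seq_len(placed), , drop = FALSE], 1L,
                         function(s) max(s[2:3])) + max(semi[2:3]) + 1
            if (any(sep < req)) next
          }
          placed <- placed + 1L
          centers[placed, ] <- ctr
          semis[placed, ] <- semi
          ok <- TRUE
          break
        }
        if (!ok) return(NULL)
      }
      list(centers = centers, semis = semis, placed = placed)
    }
    cfg <- NULL
    for (restart in seq_len(60L)) {
      cfg <- place_all()
      if (!is.null(cfg)) break
    }
    if (is.null(cfg))
      stop("placement failure: could not place ", params$n_nuclei,
           " non-overlapping nuclei off the XY border")
    centers <- cfg$centers
    semis <- cfg$semis
    placed <- cfg$placed
    edge_flag <- rep(FALSE, n_total)
    if (params$include_edge_nucleus) {
      semi <- c(runif(1, ax_r[1], ax_r[2]),
                runif(1, lat_r[1], lat_r[2]),
                runif(1, lat_r[1], lat_r[2]))
      ctr <- c(runif(1, semi[1] + sp[1], fov[1] - semi[1] - sp[1]),
               runif(1, semi[2] + sp[2], fov[2] - semi[2] - sp[2]),
               semi[3] * 0.4)  # intersects the x = 0 plane
      placed <- placed + 1L
      centers[placed, ] <- ctr
      semis[placed, ] <- semi
      edge_flag[placed] <- TRUE
    }

    # rasterize nuclei into the label array (bounding-box local grids)
    for (i in seq_len(placed)) {
      lo <- pmax(1L, as.integer(floor((centers[i, ] - semis[i, ]) / sp)))
      hi <- pmin(d, as.integer(ceiling((centers[i, ] + semis[i, ]) / sp)) + 1L)
      zs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; xs <- lo[3]:hi[3]
      zc <- ((zs - 0.5) * sp[1] - centers[i, 1]) / semis[i, 1]
      yc <- ((ys - 0.5) * sp[2] - centers[i, 2]) / semis[i, 2]
      xc <- ((xs - 0.5) * sp[3] - centers[i, 3]) / semis[i, 3]
      inside <- outer(outer(zc^2, yc^2, `+`), xc^2, `+`) <= 1
      sub <- labels[zs, ys, xs]
      sub[inside] <- i
      labels[zs, ys, xs] <- sub
    }

    # puncta
    fish_ideal <- array(0, d)
    truth <- vector("list", placed)
    for (i in seq_len(placed)) {
      n_disp <- rbinom(1L, params$n_puncta, params$dispersed_fraction)
      n_terr <- params$n_puncta - n_disp
      shrink <- semis[i, ] - params$territory_radius
      if (any(shrink <= 0))
        stop("territory_radius exceeds a nucleus semi-axis")
      pts <- matrix(NA_real_, params$n_puncta, 3)
      npts <- 0L
      if (n_terr > 0L) {
        repeat {  # territory center inside the shrunken ellipsoid
          tc <- (runif(3) * 2 - 1) * shrink
          if (sum((tc / shrink)^2) <= 1) break
        }
        tc <- tc + centers[i, ]
        for (p in seq_len(n_terr)) {
          repeat {
            pt <- tc + .runif_ball(params$territory_radius)
            vox <- .coord_to_voxel(pt, sp, d)
            if (labels[vox[1], vox[2], vox[3]] == i) break
          }
          npts <- npts + 1L
          pts[npts, ] <- pt
        }
      }
      for (p in seq_len(n_disp)) {
        repeat {
          u <- (runif(3) * 2 - 1) * semis[i, ]
          if (sum((u / semis[i, ])^2) > 1) next
          pt <- u + centers[i, ]
          vox <- .coord_to_voxel(pt, sp, d)
          if (labels[vox[1], vox[2], vox[3]] == i) break
        }
        npts <- npts + 1L
        pts[npts, ] <- pt
      }
      pts <- pts[seq_len(npts), , drop = FALSE]
      if (npts > 0L && params$photon_scale > 0) {
        q <- params$photon_scale / k0
        for (p in seq_len(npts)) {
          vox <- .coord_to_voxel(pts[p, ], sp, d)
          fish_ideal[vox[1], vox[2], vox[3]] <-
            fish_ideal[vox[1], vox[2], vox[3]] + q
        }
      }
      truth[[i]] <- list(label = i,
                         centroid_um = centers[i, ],
                         semiaxes_um = semis[i, ],
                         volume_vox = sum(labels == i),
                         puncta_um = pts,
                         n_resolvable = resolvable_count(pts, cutoff),
                         edge = edge_flag[i])
    }

    dapi_ideal <- params$dapi_scale * (labels > 0L)
    if (any(sig_vox > 0)) {
      if (any(dapi_ideal > 0)) dapi_ideal <- blur3d(dapi_ideal, sig_vox)
      if (any(fish_ideal > 0)) fish_ideal <- blur3d(fish_ideal, sig_vox)
    }

    digitize <- function(ideal) {
      v <- rpois(length(ideal), ideal + params$background)
      if (params$read_noise_sd > 0)
        v <- v + rnorm(length(v), 0, params$read_noise_sd)
      v <- round(pmax(0, pmin(params$max_intensity, v)))
      array(v, d)
    }
    vox <- array(0, c(d, 2L))
    vox[, , , 1] <- digitize(dapi_ideal)
    vox[, , , 2] <- digitize(fish_ideal)
    stacks[[cell]] <- image_stack(vox, sp, c("dapi", "fish"))
    truths[[cell]] <- list(nuclei = truth, labels = labels)
  }
  list(stacks = stacks, truth = truths)
}
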