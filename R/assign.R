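#' Assign foci to nuclei by maximal voxel overlap
#'
#' Each focus is assigned to the nucleus with which it shares the most
#' voxels; zero overlap leaves the focus unassigned (`NA`); ties are broken
#' towards the smaller nucleus label. With
#' `params$assignment_rule == "centroid"` a focus is instead assigned to the
#' nucleus containing its centroid voxel.
#'
#' @param foci an `xi_foci` object from [segment_foci()].
#' @param nuclei an `xi_nuclei` object from [segment_nuclei()] of the same
#'   stack.
#' @param params a [seg_params()] (only `assignment_rule` is used).
#' @return `foci` with `table$assigned_nucleus` filled in.
#' @export
assign_foci <- function(foci, nuclei, params = seg_params()) {
  stopifnot(inherits(foci, "xi_foci"), inherits(nuclei, "xi_nuclei"))
  if (!identical(dim(foci$labels), dim(nuclei$labels)))
    stop("focus and nucleus segmentations come from different stack shapes")
  tab <- foci$table
  if (nrow(tab) == 0L) return(foci)
  tab$assigned_nucleus <- NA_integer_

  if (params$assignment_rule == "centroid") {
    sp <- foci$spacing
    for (i in seq_len(nrow(tab))) {
      vox <- pmax(1L, pmin(dim(nuclei$labels),
        ceiling(c(tab$centroid_z_um[i] / sp[1],
                  tab$centroid_y_um[i] / sp[2],
                  tab$centroid_x_um[i] / sp[3]))))
      nl <- nuclei$labels[vox[1], vox[2], vox[3]]
      if (nl > 0L) tab$assigned_nucleus[i] <- nl
    }
  } else {
    pos <- which(foci$labels > 0L & nuclei$labels > 0L)
    if (length(pos) > 0L) {
      fl <- foci$labels[pos]
      nl <- nuclei$labels[pos]
      ov <- as.data.frame(table(focus = fl, nucleus = nl),
                          stringsAsFactors = FALSE)
      ov <- ov[ov$Freq > 0, , drop = FALSE]
      ov$focus <- as.integer(ov$focus)
      ov$nucleus <- as.integer(ov$nucleus)
      # max overlap; ties -> smaller nucleus label
      ov <- ov[order(ov$focus, -ov$Freq, ov$nucleus), , drop = FALSE]
      best <- ov[!duplicated(ov$focus), , drop = FALSE]
      m <- match(tab$label, best$focus)
      tab$assigned_nucleus <- best$nucleus[m]
    }
  }
  foci$table <- tab
  foci
}

#' Pairwise physical distances between focus centroids
#'
#' Anisotropy-aware Euclidean distances in micrometres between focus
#' centroids; symmetric with a zero diagonal.
#'
#' @param foci an `xi_foci` object, or a data.frame with columns
#'   `centroid_z_um`, `centroid_y_um`, `centroid_x_um`.
#' @param spacing unused when centroids are already in micrometres; retained
#'   for voxel-coordinate input as a numeric length-3 `(dz, dy, dx)` with
#'   `coords_vox`.
#' @param coords_vox optional matrix of voxel coordinates `(z, y, x)`; when
#'   given, distances are computed from `coords_vox * spacing`.
#' @return a symmetric numeric matrix (micrometres).
#' @examples
#' pairwise_distances(coords_vox = rbind(c(0, 0, 0), c(5, 0, 0)),
#'                    spacing = c(0.2, 0.1, 0.1))
#' @export
pairwise_distances <- function(foci = NULL, spacing = c(0.2, 0.1, 0.1),
                               coords_vox = NULL) {
  if (!is.null(coords_vox)) {
    xyz <- sweep(coords_vox, 2L, spacing, `*`)
  } else {
    tab <- if (inherits(foci, "xi_foci")) foci$table else foci
    if (nrow(tab) < 1L) stop("at least one focus is required")
    xyz <- cbind(tab$centroid_z_um, tab$centroid_y_um, tab$centroid_x_um)
  }
  m <- as.matrix(dist(xyz))
  dimnames(m) <- NULL
  m
}

#' Per-nucleus summary of assigned foci
#'
#' For each retained nucleus: number of assigned foci, their total volume,
#' and the mean nearest-neighbour distance among them (`NA` when fewer than
#' two foci are assigned). Unassigned foci are reported in the
#' `"n_unassigned"` attribute; per-nucleus counts plus unassigned always sum
#' to the total number of segmented foci.
#'
#' @param nuclei an `xi_nuclei` object.
#' @param foci an `xi_foci` object after [assign_foci()].
#' @param distances optional matrix from [pairwise_distances()] (computed
#'   internally when omitted).
#' @return data.frame, one row per nucleus: `nucleus`, `n_foci`,
#'   `total_focus_volume_um3`, `mean_nn_um`.
#' @export
summarize_nuclei <- function(nuclei, foci, distances = NULL) {
  stopifnot(inherits(nuclei, "xi_nuclei"), inherits(foci, "xi_foci"))
  ft <- foci$table
  if (nrow(ft) > 0L && is.null(distances))
    distances <- pairwise_distances(foci)
  out <- data.frame(nucleus = nuclei$table$label,
                    n_foci = 0L,
                    total_focus_volume_um3 = 0,
                    mean_nn_um = NA_real_)
  for (i in seq_len(nrow(out))) {
    idx <- which(!is.na(ft$assigned_nucleus) &
                   ft$assigned_nucleus == out$nucleus[i])
    out$n_foci[i] <- length(idx)
    out$total_focus_volume_um3[i] <- sum(ft$volume_um3[idx])
    if (length(idx) >= 2L) {
      sub <- distances[idx, idx, drop = FALSE]
      diag(sub) <- Inf
      out$mean_nn_um[i] <- mean(apply(sub, 1L, min))
    }
  }
  attr(out, "n_unassigned") <- sum(is.na(ft$assigned_nucleus))
  out
}

#' Batch foci counting over a manifest of images
#'
#' Runs the full pipeline (nucleus segmentation, focus segmentation,
#' assignment, per-nucleus summary) over a set of stacks and pools the
#' per-nucleus rows, tagged with image id, genotype and replicate. Images
#' that fail to load or process are logged and skipped.
#'
#' @param manifest data.frame with columns `image_id`, `genotype`,
#'   `replicate`, `dapi_channel`, `fish_channel`, and either `path` (TIFF
#'   written by [write_image_stack()]) or a list column `stack` of
#'   [image_stack()] objects.
#' @param params a [seg_params()].
#' @return data.frame with one row per retained nucleus (`image_id`,
#'   `nucleus_id`, `n_foci`, `volume_um3`, `mean_nn_um`, `genotype`,
#'   `replicate`), ordered by manifest row then nucleus label. The
#'   processing log (one row per image: status, message, counts) is attached
#'   as attribute `"log"`.
#' @export
batch_process <- function(manifest, params = seg_params()) {
  need <- c("image_id", "genotype", "replicate", "dapi_channel",
            "fish_channel")
  if (nrow(manifest) == 0L) {
    warning("empty manifest: no images to process")
    out <- data.frame(image_id = character(), nucleus_id = integer(),
                      n_foci = integer(), volume_um3 = numeric(),
                      mean_nn_um = numeric(), genotype = character(),
                      replicate = character())
    attr(out, "log") <- data.frame(image_id = character(),
                                   status = character(),
                                   message = character(),
                                   n_nuclei = integer(), n_foci = integer())
    return(out)
  }
  if (!all(need %in% names(manifest)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  rows <- vector("list", nrow(manifest))
  log <- data.frame(image_id = as.character(manifest$image_id),
                    status = "ok", message = "",
                    n_nuclei = 0L, n_foci = 0L,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(manifest))) {
    res <- tryCatch({
      stack <- if (!is.null(manifest$stack))
        manifest$stack[[i]]
      else
        read_image_stack(manifest$path[i])
      nuc <- segment_nuclei(stack, manifest$dapi_channel[i], params)
      foc <- segment_foci(stack, manifest$fish_channel[i], params)
      foc <- assign_foci(foc, nuc, params)
      sm <- summarize_nuclei(nuc, foc)
      log$n_nuclei[i] <- nrow(sm)
      log$n_foci[i] <- nrow(foc$table)
      if (nrow(sm) == 0L) NULL else
        data.frame(image_id = as.character(manifest$image_id[i]),
                   nucleus_id = sm$nucleus, n_foci = sm$n_foci,
                   volume_um3 = nuc$table$volume_um3[
                     match(sm$nucleus, nuc$table$label)],
                   mean_nn_um = sm$mean_nn_um,
                   genotype = as.character(manifest$genotype[i]),
                   replicate = as.character(manifest$replicate[i]),
                   stringsAsFactors = FALSE)
    }, error = function(e) {
      log$status[i] <<- "error"
      log$message[i] <<- conditionMessage(e)
      NULL
    })
    rows[[i]] <- res
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(image_id = character(), nucleus_id = integer(),
                      n_foci = integer(), volume_um3 = numeric(),
                      mean_nn_um = numeric(), genotype = character(),
                      replicate = character())
  rownames(out) <- NULL
  if (any(log$status == "error"))
    warning(sum(log$status == "error"), " image(s) failed and were skipped")
  attr(out, "log") <- log
  out
}
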