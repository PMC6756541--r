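#' Geometric features per labelled object
#'
#' For each label: pixel area (and um^2 area), outer-boundary perimeter
#' ([boundary_perimeter()]), form factor `4 * pi * area / perimeter^2`
#' (1 for a circle, tending to 0 for a line), second-moment ellipse axes,
#' and the 0-based centroid. Single-pixel objects get form factor 1.0 and
#' a `tiny_object` QC flag; discretization can push the raw ratio above 1
#' for small round objects, so values are capped at 1.0 (gross overshoots
#' additionally get an `ff_degenerate` flag).
#'
#' @param labels Integer label matrix (contiguous labels from 1).
#' @param um_per_px Pixel size in micrometres.
#' @return Tibble, one row per label: `label`, `centroid_x`, `centroid_y`
#'   (0-based, x = column), `area_px`, `area_um2`, `perimeter_px`,
#'   `form_factor`, `major_axis_px`, `minor_axis_px`, `qc_flags`.
#' @export
measure_geometry <- function(labels, um_per_px = 0.065) {
  n <- max(labels)
  if (n == 0) {
    return(tibble::tibble(label = integer(0), centroid_x = numeric(0),
                          centroid_y = numeric(0), area_px = integer(0),
                          area_um2 = numeric(0), perimeter_px = numeric(0),
                          form_factor = numeric(0), major_axis_px = numeric(0),
                          minor_axis_px = numeric(0), qc_flags = character(0)))
  }
  idx <- which(labels > 0L, arr.ind = TRUE)
  lab_v <- labels[labels > 0L]
  rows <- split(idx[, 1], lab_v)
  cols <- split(idx[, 2], lab_v)
  out <- lapply(seq_len(n), function(l) {
    r <- rows[[as.character(l)]]; cc <- cols[[as.character(l)]]
    area <- length(r)
    qc <- character(0)
    if (area == 1) {
      per <- 0; ff <- 1.0; qc <- "tiny_object"
      maj <- um <- 0
      axes <- c(1, 1)
    } else {
      r0 <- min(r); c0 <- min(cc)
      m <- matrix(FALSE, max(r) - r0 + 1L, max(cc) - c0 + 1L)
      m[cbind(r - r0 + 1L, cc - c0 + 1L)] <- TRUE
      per <- boundary_perimeter(m)
      raw_ff <- if (per > 0) 4 * pi * area / per^2 else 1.0
      ff <- min(raw_ff, 1.0)  # >1 is perimeter-discretization overshoot
      if (raw_ff > 1.5) qc <- "ff_degenerate"
      if (area <= 4) qc <- c(qc, "tiny_object")
      cen <- c(mean(r), mean(cc))
      cov <- stats::cov(cbind(r, cc)) * (area - 1) / area  # population moments
      ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
      ev <- pmax(ev, 0)
      axes <- 4 * sqrt(ev)  # skimage-style axis lengths
    }
    tibble::tibble(
      label = l,
      centroid_x = mean(cc) - 1, centroid_y = mean(r) - 1,
      area_px = area, area_um2 = area * um_per_px^2,
      perimeter_px = per, form_factor = ff,
      major_axis_px = if (area == 1) 1 else axes[1],
      minor_axis_px = if (area == 1) 1 else axes[2],
      qc_flags = paste(qc, collapse = ";"))
  })
  dplyr::bind_rows(out)
}

#' Skeleton end-node count of one object mask
#'
#' Thins the mask ([skeletonize()]) and counts skeleton pixels with exactly
#' one 8-connected skeleton neighbour. A straight rod has 2 end nodes, a
#' branched (Y-shaped) object 3, a compact blob 0 or 1 (its skeleton
#' degenerates to a point); counts above 3 indicate clumps or debris.
#'
#' @param mask Logical or 0/1 matrix of one connected object.
#' @return Integer end-node count.
#' @export
skeleton_end_nodes <- function(mask) {
  sk <- skeletonize(mask)
  if (!any(sk)) return(0L)
  s <- pad_zero(matrix(as.integer(sk), nrow(sk), ncol(sk)))
  nr <- nrow(s); nc <- ncol(s)
  nb <- s[c(1, 1:(nr - 1)), ] + s[c(2:nr, nr), ] +
    s[, c(1, 1:(nc - 1))] + s[, c(2:nc, nc)] +
    s[c(1, 1:(nr - 1)), c(1, 1:(nc - 1))] + s[c(1, 1:(nr - 1)), c(2:nc, nc)] +
    s[c(2:nr, nr), c(1, 1:(nc - 1))] + s[c(2:nr, nr), c(2:nc, nc)]
  sum(s == 1L & nb == 1L)
}

#' Per-object channel intensities
#'
#' For every label and channel role: arithmetic mean and total intensity
#' over the mask, the mode density (most frequent raw 16-bit value within
#' the mask, histogram bin width 1, ties broken toward the lower bin), and
#' a background-subtracted mode density (mode minus the median intensity of
#' unlabelled pixels, floored at 0).
#'
#' @param labels Integer label matrix.
#' @param image A `field_image` of the same shape.
#' @param which_labels Labels to measure (default all); an absent label is
#'   an error.
#' @return Tibble, one row per label, columns `mean_<role>`,
#'   `total_<role>`, `mode_density_<role>`, `mode_density_bgsub_<role>`.
#' @export
measure_intensity <- function(labels, image, which_labels = NULL) {
  stopifnot(inherits(image, "field_image"))
  if (!all(dim(labels) == dim(image$channels[[1]])))
    stop_hca("label mask and image must have the same shape")
  n <- max(labels)
  if (is.null(which_labels)) which_labels <- seq_len(n)
  present <- unique(labels[labels > 0L])
  missing_l <- setdiff(which_labels, present)
  if (length(missing_l))
    stop_hca("label(s) absent from mask: %s", paste(missing_l, collapse = ", "))
  if (length(which_labels) == 0) {
    out <- tibble::tibble(label = integer(0))
    for (role in names(image$channels)) {
      out[[paste0("mean_", role)]] <- numeric(0)
      out[[paste0("total_", role)]] <- numeric(0)
      out[[paste0("mode_density_", role)]] <- numeric(0)
      out[[paste0("mode_density_bgsub_", role)]] <- numeric(0)
    }
    return(out)
  }
  fg <- labels > 0L
  lab_v <- labels[fg]
  out <- tibble::tibble(label = as.integer(which_labels))
  for (role in names(image$channels)) {
    g <- image$channels[[role]]
    bg_med <- median(g[!fg])
    vals <- split(g[fg], lab_v)
    mode1 <- function(v) {
      tb <- table(v)
      as.numeric(names(tb)[which.max(tb)])  # which.max takes the first (lowest) tie
    }
    means <- vapply(as.character(which_labels), function(l) mean(vals[[l]]), 0)
    totals <- vapply(as.character(which_labels), function(l) sum(vals[[l]]), 0)
    modes <- vapply(as.character(which_labels), function(l) mode1(vals[[l]]), 0)
    out[[paste0("mean_", role)]] <- unname(means)
    out[[paste0("total_", role)]] <- unname(totals)
    out[[paste0("mode_density_", role)]] <- unname(modes)
    out[[paste0("mode_density_bgsub_", role)]] <- pmax(0, unname(modes) - bg_med)
  }
  out
}

#' Full per-object feature table for one field
#'
#' Combines [measure_geometry()], [skeleton_end_nodes()] per object, and
#' [measure_intensity()] into the interchange feature table consumed by
#' gating, enumeration and classification.
#'
#' @param seg A `segmentation` (or a bare label matrix).
#' @param image The `field_image` the segmentation came from.
#' @return Tibble, one row per object, keyed by `plate`, `well`, `field`,
#'   `label`.
#' @export
measure_objects <- function(seg, image) {
  labels <- if (inherits(seg, "segmentation")) seg$labels else seg
  geom <- measure_geometry(labels, image$um_per_px)
  n <- max(labels)
  ends <- integer(n)
  if (n > 0) {
    idx <- which(labels > 0L, arr.ind = TRUE)
    lab_v <- labels[labels > 0L]
    rows <- split(idx[, 1], lab_v); cols <- split(idx[, 2], lab_v)
    for (l in seq_len(n)) {
      r <- rows[[as.character(l)]]; cc <- cols[[as.character(l)]]
      m <- matrix(FALSE, max(r) - min(r) + 1L, max(cc) - min(cc) + 1L)
      m[cbind(r - min(r) + 1L, cc - min(cc) + 1L)] <- TRUE
      ends[l] <- skeleton_end_nodes(m)
    }
  }
  geom$end_nodes <- ends
  inten <- measure_intensity(labels, image)
  out <- dplyr::left_join(geom, inten, by = "label")
  dplyr::bind_cols(
    tibble::tibble(plate = rep(image$plate, nrow(out)),
                   well = rep(image$well, nrow(out)),
                   field = rep(image$field, nrow(out))),
    out)
}
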