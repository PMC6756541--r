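#' Segmentation parameters
#'
#' @param detection_roles Channel roles combined for object detection
#'   (default DAPI + FITC, so dye-resistant cells visible only in DAPI are
#'   still detected).
#' @param background_radius Radius (px) of the local-median background
#'   filter; should be well above the cell width.
#' @param threshold_k Multiplier on the robust background spread (MAD):
#'   pixels above `background + k * MAD` are foreground (default 5).
#' @param min_area_px Minimum object area; default is the pixel area of a
#'   0.5 um-diameter coccus at `um_per_px`, rejecting sub-bacterial debris.
#' @param max_area_px Maximum object area (default 20000).
#' @param split_touching Separate touching convex cells by
#'   distance-transform watershed?
#' @param um_per_px Pixel size used to derive the default `min_area_px`.
#' @return A `segmentation_params` list.
#' @export
segmentation_params <- function(detection_roles = c("DAPI", "FITC"),
                                background_radius = 15L,
                                threshold_k = 5,
                                min_area_px = NULL,
                                max_area_px = 20000L,
                                split_touching = FALSE,
                                um_per_px = 0.065) {
  if (is.null(min_area_px))
    min_area_px <- max(4L, as.integer(round(pi * (0.25 / um_per_px)^2)))
  if (min_area_px >= max_area_px) stop_hca("min_area_px must be < max_area_px")
  if (threshold_k <= 0) stop_hca("threshold_k must be > 0")
  structure(list(detection_roles = detection_roles,
                 background_radius = as.integer(background_radius),
                 threshold_k = threshold_k,
                 min_area_px = as.integer(min_area_px),
                 max_area_px = as.integer(max_area_px),
                 split_touching = isTRUE(split_touching)),
            class = "segmentation_params")
}

# local-median background of one channel (EBImage constant-time median)
estimate_background <- function(grid, radius = 15L) {
  img <- EBImage::Image(grid / 65535)
  bg <- EBImage::medianFilter(img, radius)
  EBImage::imageData(bg) * 65535
}

#' Combine detection channels into one grid
#'
#' Each requested channel is background-normalized to a robust z-score,
#' `(I - local median background) / MAD(residual)`, and the combined
#' detection grid is the per-pixel maximum across channels. This matches
#' detection on the combined DAPI + FITC signal: a cell visible in either
#' channel is visible in the combination. With `normalize = FALSE` the raw
#' per-pixel maximum is returned.
#'
#' @param image A `field_image`.
#' @param roles Channel roles to combine (must exist in the image).
#' @param background_radius Radius for the local-median background.
#' @param normalize Background-normalize before combining (default TRUE).
#' @return Numeric matrix, the detection grid.
#' @export
combine_detection_channels <- function(image, roles,
                                       background_radius = 15L,
                                       normalize = TRUE) {
  stopifnot(inherits(image, "field_image"))
  missing_roles <- setdiff(roles, names(image$channels))
  if (length(missing_roles))
    stop_hca("channel role(s) missing from image: %s",
             paste(missing_roles, collapse = ", "))
  grids <- lapply(roles, function(r) {
    g <- image$channels[[r]]
    if (!normalize) return(g + 0)  # numeric copy
    res <- g - estimate_background(g, background_radius)
    s <- stats::mad(res, center = 0)
    if (s <= 0) s <- 1
    res / s
  })
  Reduce(pmax, grids)
}

#' Detect objects in a field
#'
#' Thresholds the combined, background-normalized detection grid at
#' `threshold_k` robust SDs above background, labels 8-connected
#' components, optionally splits touching cells with a distance-transform
#' watershed, and filters components to `[min_area_px, max_area_px]`.
#'
#' @param image A `field_image`.
#' @param params A [segmentation_params()].
#' @return A `segmentation` list: `labels` (integer matrix, contiguous
#'   labels from 1, background 0), `n_objects`, and `qc` (character vector
#'   of field-level flags; `"saturated"` when more than half of a detection
#'   channel sits at the 16-bit ceiling).
#' @export
detect_objects <- function(image, params = segmentation_params()) {
  stopifnot(inherits(image, "field_image"), inherits(params, "segmentation_params"))
  qc <- character(0)
  for (r in params$detection_roles) {
    if (r %in% names(image$channels) &&
        mean(image$channels[[r]] >= 65535L) > 0.5) {
      qc <- c(qc, "saturated")
      warn(sprintf("detection channel %s is >50%% saturated in well %s field %d",
                   r, image$well, image$field))
    }
  }
  det <- combine_detection_channels(image, params$detection_roles,
                                    params$background_radius)
  mask <- det > params$threshold_k
  lab <- label_components(mask, connectivity = 8)
  if (params$split_touching && max(lab) > 0) {
    dm <- EBImage::distmap(EBImage::Image(mask * 1))
    ws <- EBImage::watershed(dm, tolerance = 1, ext = 1)
    ws <- matrix(as.integer(EBImage::imageData(ws)), nrow(mask), ncol(mask))
    # watershed regions refine the 8-connected components
    lab <- relabel_contiguous(ws)
  }
  if (max(lab) > 0) {
    areas <- tabulate(lab[lab > 0L], nbins = max(lab))
    drop <- which(areas < params$min_area_px | areas > params$max_area_px)
    if (length(drop)) lab[lab %in% drop] <- 0L
    lab <- relabel_contiguous(lab)
  }
  structure(list(labels = lab, n_objects = max(lab), qc = qc,
                 params = params, well = image$well, field = image$field,
                 plate = image$plate),
            class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("<segmentation> well %s field %d: %d objects%s\n",
              x$well, x$field, x$n_objects,
              if (length(x$qc)) paste0(" [", paste(x$qc, collapse = ","), "]") else ""))
  invisible(x)
}

#' Filter objects on the skeleton end-node criterion
#'
#' Objects with more than `max_end_nodes` skeleton endpoints tend to be
#' undifferentiated clumps or debris and are excluded (default threshold 3).
#'
#' @param records Per-object feature tibble with an `end_nodes` column.
#' @param max_end_nodes Maximum allowed end-node count; `Inf` keeps all.
#' @return List with `records` (the kept rows) and `exclusions` (the
#'   removed rows plus a `reason` column).
#' @export
filter_objects <- function(records, max_end_nodes = 3) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0)
    return(list(records = records,
                exclusions = dplyr::mutate(records, reason = character(0))))
  if (!"end_nodes" %in% names(records))
    stop_hca("records must carry an 'end_nodes' column (run measure_objects first)")
  keep <- records$end_nodes <= max_end_nodes
  excl <- records[!keep, , drop = FALSE]
  if (nrow(excl)) {
    excl$reason <- sprintf("end_nodes %d > %s", excl$end_nodes,
                           format(max_end_nodes))
  } else {
    excl$reason <- character(0)
  }
  list(records = records[keep, , drop = FALSE], exclusions = excl)
}

#' Match detected objects to ground truth
#'
#' Greedy one-to-one matching by intersection-over-union between detected
#' and true label masks; a pair is a match when IoU exceeds `min_iou`.
#' Precision = matches / detected, recall = matches / truth.
#'
#' @param labels Detected integer label matrix.
#' @param truth_labels Ground-truth label matrix of the same shape.
#' @param min_iou Minimum intersection-over-union (default 0.5).
#' @return Tibble with one row: `n_detected`, `n_truth`, `n_matched`,
#'   `precision`, `recall`.
#' @export
match_objects <- function(labels, truth_labels, min_iou = 0.5) {
  stopifnot(all(dim(labels) == dim(truth_labels)))
  nd <- max(labels); nt <- max(truth_labels)
  if (nd == 0 || nt == 0) {
    return(tibble::tibble(n_detected = nd, n_truth = nt, n_matched = 0L,
                          precision = ifelse(nd == 0, NA_real_, 0),
                          recall = ifelse(nt == 0, NA_real_, 0)))
  }
  both <- labels > 0L & truth_labels > 0L
  inter <- table(factor(labels[both], levels = seq_len(nd)),
                 factor(truth_labels[both], levels = seq_len(nt)))
  area_d <- tabulate(labels[labels > 0L], nd)
  area_t <- tabulate(truth_labels[truth_labels > 0L], nt)
  iou <- as.matrix(inter) / (outer(area_d, area_t, `+`) - as.matrix(inter))
  matched <- 0L
  used_d <- logical(nd); used_t <- logical(nt)
  repeat {
    iou[used_d, ] <- -1; iou[, used_t] <- -1
    m <- which(iou == max(iou), arr.ind = TRUE)[1, , drop = TRUE]
    if (iou[m[1], m[2]] < min_iou) break
    used_d[m[1]] <- TRUE; used_t[m[2]] <- TRUE
    matched <- matched + 1L
    if (all(used_d) || all(used_t)) break
  }
  tibble::tibble(n_detected = nd, n_truth = nt, n_matched = matched,
                 precision = matched / nd, recall = matched / nt)
}
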