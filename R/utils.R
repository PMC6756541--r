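#' @importFrom rlang %||% abort warn
#' @importFrom stats median mad quantile rpois rnorm rbinom runif sd lm coef predict setNames
#' @importFrom utils head tail
NULL

# Diagonal step weight for outer-boundary perimeter. Chosen so the chain-code
# length of a digitized circle is unbiased in expectation over orientations:
# E[cos(t) + (w - 1) sin(t)] = 1 for t uniform on [0, 45 deg]
# => w = 1 + (pi/4 - sin(pi/4)) / (1 - cos(pi/4)).
DIAG_WEIGHT <- 1 + (pi / 4 - sin(pi / 4)) / (1 - cos(pi / 4))

stop_hca <- function(...) stop(sprintf(...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)

#' Label connected components of a binary mask
#'
#' 8-connected labelling built on [EBImage::bwlabel()] (4-connected) with
#' diagonal adjacencies merged by union-find. Labels are contiguous from 1
#' in raster-scan order of first appearance; background is 0.
#'
#' @param mask Logical or 0/1 integer matrix.
#' @param connectivity 4 or 8 (default 8, the convention for convex
#'   bacterial shapes).
#' @return Integer matrix of labels, same shape as `mask`.
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask), connectivity %in% c(4, 8))
  m <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  lab <- EBImage::imageData(EBImage::bwlabel(m))
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  if (connectivity == 8 && max(lab) > 1L) {
    nr <- nrow(lab); nc <- ncol(lab)
    a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]    # down-right diagonal
    a2 <- lab[-nr, -1]; b2 <- lab[-1, -nc]    # down-left diagonal
    pick <- function(a, b) {
      k <- a > 0L & b > 0L & a != b
      cbind(a[k], b[k])
    }
    pairs <- unique(rbind(pick(a1, b1), pick(a2, b2)))
    if (nrow(pairs) > 0) {
      parent <- seq_len(max(lab))
      find <- function(i) {
        while (parent[i] != i) {
          parent[i] <<- parent[parent[i]]
          i <- parent[i]
        }
        i
      }
      for (r in seq_len(nrow(pairs))) {
        ra <- find(pairs[r, 1]); rb <- find(pairs[r, 2])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
      root <- vapply(seq_along(parent), find, integer(1))
      lab[lab > 0L] <- root[lab[lab > 0L]]
    }
  }
  relabel_contiguous(lab)
}

# Renumber nonzero labels contiguously from 1, ordered by first appearance
# in column-major scan (stable across platforms).
relabel_contiguous <- function(lab) {
  ids <- unique(lab[lab > 0L])
  if (length(ids) == 0) return(lab)
  map <- integer(max(ids))
  map[ids] <- seq_along(ids)
  lab[lab > 0L] <- map[lab[lab > 0L]]
  lab
}

# Pad a matrix with a border of zeros.
pad_zero <- function(m, k = 1L) {
  out <- matrix(0L, nrow(m) + 2L * k, ncol(m) + 2L * k)
  out[(k + 1L):(k + nrow(m)), (k + 1L):(k + ncol(m))] <- m
  out
}

#' Topological skeleton of a binary mask (Zhang-Suen thinning)
#'
#' Iterative thinning preserving 8-connectivity; compact blobs shrink to
#' a point, elongated shapes to their medial line.
#'
#' @param mask Logical or 0/1 matrix (one object).
#' @return Logical matrix of skeleton pixels.
#' @export
skeletonize <- function(mask) {
  m <- pad_zero(matrix(as.integer(mask != 0), nrow(mask), ncol(mask)))
  nr <- nrow(m); nc <- ncol(m)
  shift <- function(x, dr, dc) {
    out <- matrix(0L, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs, cs] <- x[rs - dr, cs - dc]
    out
  }
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      # neighbours clockwise from north: P2..P9
      p2 <- shift(m, 1, 0);  p3 <- shift(m, 1, -1)
      p4 <- shift(m, 0, -1); p5 <- shift(m, -1, -1)
      p6 <- shift(m, -1, 0); p7 <- shift(m, -1, 1)
      p8 <- shift(m, 0, 1);  p9 <- shift(m, 1, 1)
      bsum <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (p2 == 0L & p3 == 1L) + (p3 == 0L & p4 == 1L) +
        (p4 == 0L & p5 == 1L) + (p5 == 0L & p6 == 1L) +
        (p6 == 0L & p7 == 1L) + (p7 == 0L & p8 == 1L) +
        (p8 == 0L & p9 == 1L) + (p9 == 0L & p2 == 1L)
      cond <- m == 1L & bsum >= 2L & bsum <= 6L & a == 1L
      if (step == 1) {
        cond <- cond & (p2 * p4 * p6 == 0L) & (p4 * p6 * p8 == 0L)
      } else {
        cond <- cond & (p2 * p4 * p8 == 0L) & (p2 * p6 * p8 == 0L)
      }
      if (any(cond)) {
        m[cond] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  nr0 <- nrow(mask); nc0 <- ncol(mask)
  m[2:(nr0 + 1L), 2:(nc0 + 1L)] == 1L
}

# Moore-neighbour outer-boundary trace of a single connected mask.
# Returns an n x 2 matrix of (row, col) boundary pixel coordinates in order;
# single-pixel objects return one row.
trace_boundary <- function(mask) {
  m <- pad_zero(matrix(as.integer(mask != 0), nrow(mask), ncol(mask)))
  idx <- which(m == 1L, arr.ind = TRUE)
  if (nrow(idx) == 0) return(matrix(integer(0), 0, 2))
  # topmost-leftmost in (col, row) order => first by column then row
  start <- idx[order(idx[, 2], idx[, 1])[1], ]
  if (nrow(idx) == 1) return(matrix(start - 1L, 1, 2))
  # clockwise Moore neighbourhood starting from west
  dirs <- rbind(c(0, -1), c(-1, -1), c(-1, 0), c(-1, 1),
                c(0, 1), c(1, 1), c(1, 0), c(1, -1))
  path <- matrix(0L, 4L * sum(m) + 8L, 2L)
  np <- 0L
  cur <- start
  backtrack <- 1L  # came from the west (scan direction guarantees west is 0)
  first_next <- NULL
  repeat {
    np <- np + 1L
    path[np, ] <- cur
    found <- FALSE
    k <- backtrack
    for (s in 0:7) {
      kk <- ((k - 1L + s) %% 8L) + 1L
      nb <- cur + dirs[kk, ]
      if (m[nb[1], nb[2]] == 1L) {
        # next backtrack: direction pointing to the previous (background-side)
        # neighbour examined just before kk
        prev <- ((kk - 2L) %% 8L) + 1L
        bt_cell <- cur + dirs[prev, ]
        cur <- nb
        rel <- bt_cell - cur
        backtrack <- which(dirs[, 1] == rel[1] & dirs[, 2] == rel[2])
        found <- TRUE
        break
      }
    }
    if (!found) break  # isolated pixel
    if (all(cur == start) && np > 1L) {
      if (is.null(first_next)) {
        # Jacob's criterion: stop when start re-entered the same way
      }
      break
    }
    if (np > 4L * sum(m)) break
  }
  path[seq_len(np), , drop = FALSE] - 1L  # unpad
}

#' Outer-boundary perimeter of a connected mask
#'
#' Chain length of the Moore outer boundary traced through border-pixel
#' centres: straight steps count 1, diagonal steps are weighted so that
#' rasterized discs have unbiased perimeter (weight 1.2674).
#' Single-pixel objects return 0.
#'
#' @param mask Logical or 0/1 matrix containing one connected object.
#' @return Perimeter in pixel units.
#' @export
boundary_perimeter <- function(mask) {
  path <- trace_boundary(mask)
  n <- nrow(path)
  if (n <= 1) return(0)
  steps <- rbind(diff(path), path[1, ] - path[n, ])
  diag_step <- steps[, 1] != 0 & steps[, 2] != 0
  sum(ifelse(diag_step, DIAG_WEIGHT, 1))
}

# deterministic 31-bit stream seed from a master seed and string parts
derive_seed <- function(seed, ...) {
  parts <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(parts)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

iso_now <- function() format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

log_stage <- function(stage, msg) {
  message(sprintf("[%s] %s: %s", iso_now(), stage, msg))
}
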