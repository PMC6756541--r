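# Geometric fixtures and brute-force oracles used across tests.

disc_mask <- function(r, n = 2 * r + 5) {
  cc <- (n + 1) / 2
  outer(seq_len(n), seq_len(n), function(i, j) (i - cc)^2 + (j - cc)^2 <= r^2)
}

rect_mask <- function(h, w, pad = 2) {
  m <- matrix(FALSE, h + 2 * pad, w + 2 * pad)
  m[pad + seq_len(h), pad + seq_len(w)] <- TRUE
  m
}

# Y-shaped mask: three straight 1-px arms meeting at a junction
y_mask <- function(arm = 8) {
  n <- 2 * arm + 5
  m <- matrix(FALSE, n, n)
  cx <- arm + 3
  m[(cx - arm):cx, cx] <- TRUE                        # vertical arm up
  for (k in 0:arm) {
    m[cx + k, cx - k] <- TRUE                         # lower-left arm
    m[cx + k, cx + k] <- TRUE                         # lower-right arm
  }
  m
}

# one-channel field_image wrapper around a plain matrix
matrix_image <- function(..., well = "A01", field = 0L, um_per_px = 0.065) {
  field_image(list(...), well = well, field = field, um_per_px = um_per_px)
}

# brute-force per-pixel intensity oracle for a label mask
oracle_intensity <- function(labels, grid, lab) {
  v <- numeric(0)
  for (i in seq_len(nrow(labels)))
    for (j in seq_len(ncol(labels)))
      if (labels[i, j] == lab) v <- c(v, grid[i, j])
  counts <- table(v)
  mode_v <- as.numeric(names(counts)[which.max(counts)])
  list(mean = mean(v), total = sum(v), mode = mode_v, area = length(v))
}

# brute-force skeleton endpoint count: pixels of `sk` with exactly one
# 8-neighbour, counted with explicit loops
oracle_end_nodes <- function(sk) {
  n <- 0L
  for (i in seq_len(nrow(sk))) {
    for (j in seq_len(ncol(sk))) {
      if (!sk[i, j]) next
      nb <- 0L
      for (di in -1:1) for (dj in -1:1) {
        if (di == 0 && dj == 0) next
        ii <- i + di; jj <- j + dj
        if (ii >= 1 && ii <= nrow(sk) && jj >= 1 && jj <= ncol(sk) && sk[ii, jj])
          nb <- nb + 1L
      }
      if (nb == 1L) n <- n + 1L
    }
  }
  n
}

# noiseless one-object field: mask rendered at `amp` over a flat background
flat_field <- function(mask, amp = 3000, bg = 100, role = "FITC") {
  g <- matrix(bg, nrow(mask), ncol(mask))
  g[mask] <- bg + amp
  args <- list(g)
  names(args) <- role
  do.call(matrix_image, args)
}

# per-morphotype feature-table simulator for classifier tests that do not
# need rendered pixels: Gaussian feature clusters keyed by strain
simulate_feature_table <- function(n_per_strain, seed = 1L,
                                   strains = c("coccus", "short_rod", "filament"),
                                   separation = 6) {
  set.seed(seed)
  centers <- seq_along(strains) * separation
  purrr::map_dfr(seq_along(strains), function(k) {
    n <- n_per_strain
    tibble::tibble(
      strain = strains[k],
      area_px = rnorm(n, 150 + centers[k] * 30, 20),
      form_factor = pmin(1, pmax(0.01, rnorm(n, 0.9 - 0.12 * k, 0.05))),
      major_axis_px = rnorm(n, 10 + centers[k], 2),
      minor_axis_px = rnorm(n, 8, 1),
      mean_FITC = rnorm(n, 3000 + 100 * k, 300))
  })
}
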