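#' Morphotype specification
#'
#' Describes one bacterial morphotype for the field simulator: shape family,
#' physical size with lognormal dispersion, per-channel staining intensity,
#' and the fraction of cells that actually take up each stain
#' (`stain_coverage`), which models dye-resistant subpopulations such as
#' cells that stain with DAPI but not with a SYTO-family dye.
#'
#' @param name Text label (becomes the `morphotype`/`strain` column).
#' @param shape_family One of `"coccus"`, `"rod"`, `"curved_rod"`,
#'   `"filament"`.
#' @param length_um,width_um Cell length and width in micrometres
#'   (`length_um >= width_um`; for cocci the diameter is `width_um`).
#' @param length_cv,width_cv Lognormal coefficients of variation (>= 0).
#' @param base_intensity Named numeric vector of mean photon signal per
#'   channel role (over background), e.g. `c(DAPI = 3000, FITC = 4000)`.
#' @param intensity_cv Lognormal CV of per-cell intensity (>= 0).
#' @param stain_coverage Named vector in \[0, 1\]: fraction of cells of this
#'   morphotype emitting in each channel role. Roles not listed default to 1.
#' @return A `morphotype_spec` object (a list).
#' @export
morphotype_spec <- function(name,
                            shape_family = c("coccus", "rod", "curved_rod", "filament"),
                            length_um, width_um,
                            length_cv = 0.10, width_cv = 0.08,
                            base_intensity = c(DAPI = 3000, FITC = 4000),
                            intensity_cv = 0.20,
                            stain_coverage = numeric(0)) {
  shape_family <- match.arg(shape_family)
  if (!is.numeric(length_um) || length_um <= 0 || !is.numeric(width_um) || width_um <= 0)
    stop_hca("length_um and width_um must be positive")
  if (length_um < width_um)
    stop_hca("morphotype '%s': length_um (%.3g) must be >= width_um (%.3g)",
             name, length_um, width_um)
  if (length_cv < 0 || width_cv < 0 || intensity_cv < 0)
    stop_hca("dispersions must be >= 0")
  if (length(stain_coverage) && (any(stain_coverage < 0) || any(stain_coverage > 1)))
    stop_hca("stain_coverage values must lie in [0, 1]")
  structure(list(
    name = name, shape_family = shape_family,
    length_um = length_um, width_um = width_um,
    length_cv = length_cv, width_cv = width_cv,
    base_intensity = base_intensity, intensity_cv = intensity_cv,
    stain_coverage = stain_coverage
  ), class = "morphotype_spec")
}

#' Reference morphotype panel
#'
#' Three well-separated morphotypes (coccus, short rod, filament) plus a
#' curved rod, spanning the morphology range of common test organisms.
#'
#' @return Named list of [morphotype_spec()] objects.
#' @export
default_morphotypes <- function() {
  list(
    coccus = morphotype_spec("coccus", "coccus", length_um = 1.0, width_um = 1.0),
    short_rod = morphotype_spec("short_rod", "rod", length_um = 2.5, width_um = 0.8),
    curved_rod = morphotype_spec("curved_rod", "curved_rod", length_um = 3.0, width_um = 0.6),
    filament = morphotype_spec("filament", "filament", length_um = 8.0, width_um = 0.6)
  )
}

#' Field acquisition specification
#'
#' Imaging/simulation parameters for one field: geometry, expected cell
#' density, viability mixture, background and camera noise, and the channel
#' roles acquired. Dead cells emit in the exclusion-dye channel
#' (`dye_role`); live cells show only autofluorescence there.
#'
#' @param image_shape_px Integer (rows, cols) of the field.
#' @param um_per_px Pixel size in micrometres (default 0.065, a 6.5 um
#'   camera pixel behind a 100x objective).
#' @param cell_density Expected number of cells per field (Poisson mean).
#' @param viable_fraction Probability a placed cell is viable, in \[0, 1\].
#' @param overlap_allowed If `FALSE` (default) cells are placed with
#'   disjoint masks by rejection sampling.
#' @param background_level Mean background signal (camera counts).
#' @param shot_noise Apply Poisson noise to signal + background?
#' @param read_noise_sd Additive Gaussian read noise SD (counts).
#' @param channel_roles Ordered subset of `c("DAPI", "FITC", "Cy3")`.
#' @param dye_role Channel role of the exclusion dye (dead-cell reporter).
#' @param dead_dye_intensity,live_dye_intensity Mean exclusion-dye signal of
#'   dead cells and autofluorescence of live cells in `dye_role`.
#' @return A `field_spec` object (a list).
#' @export
field_spec <- function(image_shape_px = c(256L, 256L),
                       um_per_px = 0.065,
                       cell_density = 25,
                       viable_fraction = 1,
                       overlap_allowed = FALSE,
                       background_level = 100,
                       shot_noise = TRUE,
                       read_noise_sd = 3,
                       channel_roles = c("DAPI", "FITC", "Cy3"),
                       dye_role = "Cy3",
                       dead_dye_intensity = 2500,
                       live_dye_intensity = 40) {
  if (length(image_shape_px) != 2 || any(image_shape_px < 8))
    stop_hca("image_shape_px must be two integers >= 8")
  if (cell_density < 0) stop_hca("cell_density must be >= 0")
  if (viable_fraction < 0 || viable_fraction > 1)
    stop_hca("viable_fraction must lie in [0, 1]")
  if (background_level < 0 || read_noise_sd < 0)
    stop_hca("background_level and read_noise_sd must be >= 0")
  if (!all(channel_roles %in% c("DAPI", "FITC", "Cy3")))
    stop_hca("channel_roles must be a subset of DAPI, FITC, Cy3")
  structure(list(
    image_shape_px = as.integer(image_shape_px), um_per_px = um_per_px,
    cell_density = cell_density, viable_fraction = viable_fraction,
    overlap_allowed = isTRUE(overlap_allowed),
    background_level = background_level, shot_noise = isTRUE(shot_noise),
    read_noise_sd = read_noise_sd, channel_roles = channel_roles,
    dye_role = dye_role, dead_dye_intensity = dead_dye_intensity,
    live_dye_intensity = live_dye_intensity
  ), class = "field_spec")
}

#' Construct a field image container
#'
#' @param channels Named list of integer matrices (one per channel role),
#'   all the same shape, values within the 16-bit range.
#' @param well Well id in letter-number form (e.g. "B07").
#' @param field 0-based field index.
#' @param plate Plate id.
#' @param um_per_px Pixel size in micrometres.
#' @return A `field_image` object.
#' @export
field_image <- function(channels, well = "A01", field = 0L, plate = "plate1",
                        um_per_px = 0.065) {
  if (!length(channels) || is.null(names(channels)))
    stop_hca("channels must be a non-empty named list of matrices")
  dims <- unique(lapply(channels, dim))
  if (length(dims) != 1) stop_hca("all channel grids must share one shape")
  rng <- range(unlist(lapply(channels, range)))
  if (rng[1] < 0 || rng[2] > 65535)
    stop_hca("channel intensities must lie within the 16-bit range")
  structure(list(channels = channels, well = well, field = as.integer(field),
                 plate = plate, um_per_px = um_per_px),
            class = "field_image")
}

#' @export
print.field_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<field_image> plate %s well %s field %d: %dx%d px, channels %s\n",
              x$plate, x$well, x$field, d[1], d[2],
              paste(names(x$channels), collapse = "/")))
  invisible(x)
}

# sample a backbone polyline (n x 2, pixel units, centred on origin) and
# radius for one cell of the given morphotype
sample_cell_shape <- function(mt, um_per_px) {
  rln <- function(mean, cv) {
    if (cv <= 0) return(mean)
    s <- sqrt(log(1 + cv^2))
    stats::rlnorm(1, log(mean) - s^2 / 2, s)
  }
  L <- rln(mt$length_um, mt$length_cv) / um_per_px
  W <- rln(mt$width_um, mt$width_cv) / um_per_px
  W <- min(W, L)
  r <- W / 2
  theta <- runif(1, 0, pi)
  u <- c(cos(theta), sin(theta))
  if (mt$shape_family == "coccus") {
    pts <- matrix(0, 1, 2)
    r <- W / 2
  } else if (mt$shape_family == "rod") {
    h <- max(L - W, 0) / 2
    t <- seq(-h, h, length.out = max(2, ceiling(2 * h / 0.5) + 1))
    pts <- cbind(t * u[1], t * u[2])
  } else if (mt$shape_family == "curved_rod") {
    h <- max(L - W, 0) / 2
    bend <- 0.25 * (2 * h) * sample(c(-1, 1), 1)
    v <- c(-u[2], u[1])
    s <- seq(0, 1, length.out = max(8, ceiling(2 * h / 0.5) + 1))
    p0 <- -h * u; p2 <- h * u; p1 <- bend * v
    pts <- outer((1 - s)^2, p0) + outer(2 * s * (1 - s), p1) + outer(s^2, p2)
    pts <- matrix(pts, ncol = 2)
  } else { # filament: random-walk tube
    total <- max(L - W, W)
    step <- max(W, 1)
    nst <- max(2, ceiling(total / step))
    ang <- cumsum(c(theta, rnorm(nst - 1, 0, 0.35)))
    dx <- step * cos(ang); dy <- step * sin(ang)
    pts <- cbind(cumsum(c(0, dx))[-1], cumsum(c(0, dy))[-1])
    pts <- rbind(c(0, 0), pts)
    pts <- sweep(pts, 2, colMeans(pts))
    # densify for accurate distance field
    dense <- lapply(seq_len(nrow(pts) - 1), function(i) {
      k <- max(2, ceiling(step / 0.5))
      s <- seq(0, 1, length.out = k)
      cbind(pts[i, 1] + s * (pts[i + 1, 1] - pts[i, 1]),
            pts[i, 2] + s * (pts[i + 1, 2] - pts[i, 2]))
    })
    pts <- do.call(rbind, dense)
  }
  list(points = pts, radius = r, length_px = L, width_px = W)
}

# anti-aliased coverage of one cell in a local window around its own
# centroid (computed once per cell; placement then just translates it by
# integer offsets). `support` is the coverage footprint grown by `margin`
# px, used to keep non-overlapping cells separated so thresholded masks do
# not fuse.
render_coverage <- function(shape, margin = 2.5, subpx = c(0, 0)) {
  pts <- sweep(shape$points, 2, -subpx)  # + subpixel offset
  r <- shape$radius
  pad <- r + margin + 1
  r0 <- floor(min(pts[, 1]) - pad); r1 <- ceiling(max(pts[, 1]) + pad)
  c0 <- floor(min(pts[, 2]) - pad); c1 <- ceiling(max(pts[, 2]) + pad)
  rows <- r0:r1; cols <- c0:c1
  px_r <- rep(rows, times = length(cols))
  px_c <- rep(cols, each = length(rows))
  # min distance from each pixel centre to the backbone point set
  d2 <- rep(Inf, length(px_r))
  for (i in seq_len(nrow(pts))) {
    dd <- (px_r - pts[i, 1])^2 + (px_c - pts[i, 2])^2
    d2 <- pmin(d2, dd)
  }
  d <- sqrt(d2)
  cov <- pmin(1, pmax(0, r + 0.5 - d))
  list(nrow = length(rows), ncol = length(cols),
       cov = matrix(cov, length(rows), length(cols)),
       support = matrix(d <= r + 0.5 + margin, length(rows), length(cols)))
}

#' Generate one synthetic multi-channel fluorescence field
#'
#' Places cells of the given morphotypes at random positions, renders each
#' as an anti-aliased filled shape in every channel role it stains for,
#' applies the viability rules (dead cells emit in the exclusion-dye
#' channel, live cells only autofluorescence there), then adds background,
#' Poisson shot noise and Gaussian read noise, clipped to 16 bits.
#' Identical `(spec, morphotypes, seed)` give bit-identical output.
#'
#' @param spec A [field_spec()].
#' @param morphotypes List of [morphotype_spec()]s.
#' @param proportions Mixing proportions (sum to 1); default uniform.
#' @param seed Integer seed for this field's RNG stream.
#' @param n_cells Exact cell count; if `NULL` (default) drawn from
#'   Poisson(`cell_density`).
#' @param hpg HPG incubation status of the well: `"plus"`, `"minus"` or
#'   `NA`. Used only to set the per-object `hpg_positive` truth flag.
#' @param well,field,plate Identity stamped on the output.
#' @return List with elements `image` (a `field_image`) and `truth`
#'   (list: `objects` tibble with per-object label, morphotype, viable and
#'   HPG flags and centroid; `label_image` matrix; `n_objects`).
#' @export
generate_field <- function(spec, morphotypes = default_morphotypes(),
                           proportions = NULL, seed = 1L, n_cells = NULL,
                           hpg = NA_character_,
                           well = "A01", field = 0L, plate = "plate1") {
  stopifnot(inherits(spec, "field_spec"))
  if (inherits(morphotypes, "morphotype_spec")) morphotypes <- list(morphotypes)
  k <- length(morphotypes)
  if (is.null(proportions)) proportions <- rep(1 / k, k)
  if (abs(sum(proportions) - 1) > 1e-9)
    stop_hca("mixing proportions must sum to 1 (got %.6g)", sum(proportions))
  shp <- spec$image_shape_px
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)

  n <- if (is.null(n_cells)) rpois(1, spec$cell_density) else as.integer(n_cells)
  label_img <- matrix(0L, shp[1], shp[2])
  reserved <- matrix(FALSE, shp[1], shp[2])
  signal <- lapply(spec$channel_roles, function(r) matrix(0, shp[1], shp[2]))
  names(signal) <- spec$channel_roles
  objects <- vector("list", n)
  placed <- 0L
  mt_names <- vapply(morphotypes, `[[`, "", "name")

  for (i in seq_len(n)) {
    mi <- sample.int(k, 1, prob = proportions)
    mt <- morphotypes[[mi]]
    viable <- runif(1) < spec$viable_fraction
    shape <- sample_cell_shape(mt, spec$um_per_px)
    cv0 <- render_coverage(shape, subpx = runif(2) - 0.5)
    if (cv0$nrow > shp[1] || cv0$ncol > shp[2])
      stop_hca("image (%d x %d px) too small to place morphotype '%s' (needs ~%d px)",
               shp[1], shp[2], mt$name, max(cv0$nrow, cv0$ncol))
    core <- cv0$cov >= 0.5
    if (!any(core)) core[which.max(cv0$cov)] <- TRUE
    ok <- FALSE
    for (try in seq_len(250)) {
      top <- sample.int(shp[1] - cv0$nrow + 1L, 1)
      left <- sample.int(shp[2] - cv0$ncol + 1L, 1)
      cv <- list(rows = top:(top + cv0$nrow - 1L),
                 cols = left:(left + cv0$ncol - 1L),
                 cov = cv0$cov, support = cv0$support)
      if (!spec$overlap_allowed &&
          any(reserved[cv$rows, cv$cols] & cv$support)) next
      ok <- TRUE
      break
    }
    if (!ok) {
      if (!is.null(n_cells))
        stop_hca("could not place %d non-overlapping cells of morphotype '%s'",
                 n, mt$name)
      next
    }
    placed <- placed + 1L
    sub <- label_img[cv$rows, cv$cols]
    sub[core & sub == 0L] <- placed
    label_img[cv$rows, cv$cols] <- sub
    reserved[cv$rows, cv$cols] <- reserved[cv$rows, cv$cols] | cv$support

    rln1 <- function(mean, cvr) {
      if (cvr <= 0 || mean <= 0) return(mean)
      s <- sqrt(log(1 + cvr^2))
      stats::rlnorm(1, log(mean) - s^2 / 2, s)
    }
    for (role in spec$channel_roles) {
      if (role == spec$dye_role) {
        amp <- if (viable) rln1(spec$live_dye_intensity, mt$intensity_cv)
               else rln1(spec$dead_dye_intensity, mt$intensity_cv)
      } else {
        base <- mt$base_intensity[role]
        if (is.na(base) || base <= 0) next
        covg <- mt$stain_coverage[role]
        if (!is.na(covg) && runif(1) >= covg) next  # stain-resistant cell
        amp <- rln1(base, mt$intensity_cv)
      }
      if (amp <= 0) next
      signal[[role]][cv$rows, cv$cols] <-
        signal[[role]][cv$rows, cv$cols] + amp * cv$cov
    }
    ctr <- colMeans(which(label_img == placed, arr.ind = TRUE))
    objects[[placed]] <- tibble::tibble(
      label = placed, morphotype = mt$name, viable = viable,
      hpg_positive = if (identical(hpg, "plus")) viable else FALSE,
      centroid_y = ctr[1] - 1, centroid_x = ctr[2] - 1,
      area_px = sum(label_img == placed))
  }
  channels <- lapply(signal, function(s) {
    img <- s + spec$background_level
    if (spec$shot_noise) img <- rpois(length(img), pmax(img, 0))
    img <- img + rnorm(length(img), 0, spec$read_noise_sd)
    matrix(as.integer(pmin(65535, pmax(0, round(img)))), shp[1], shp[2])
  })
  truth_tbl <- if (placed > 0) dplyr::bind_rows(objects[seq_len(placed)])
               else tibble::tibble(label = integer(0), morphotype = character(0),
                                   viable = logical(0), hpg_positive = logical(0),
                                   centroid_y = numeric(0), centroid_x = numeric(0),
                                   area_px = integer(0))
  list(
    image = field_image(channels, well = well, field = field, plate = plate,
                        um_per_px = spec$um_per_px),
    truth = list(objects = truth_tbl, label_image = label_img,
                 n_objects = placed)
  )
}

#' Generate a seeded serial-dilution plate
#'
#' Emulates the enumeration layout: a stock at `stock_density` cells/mL,
#' serially diluted (factors strictly increasing, e.g. 50, 250, 1250, 6250
#' for a 1:5 series), a fixed sample volume per well, and a fixed number of
#' imaged fields per well out of `total_possible_fields` covering the well
#' bottom. The expected cells per field is
#' `stock_density / dilution * well_volume_mL / total_possible_fields`, so
#' expected counts scale as 1/dilution. Each field draws its own RNG stream
#' from `(seed, well, field)` so wells reproduce independently.
#'
#' @param stock_density Stock concentration, cells/mL.
#' @param dilution_factors Strictly increasing positive dilution factors.
#' @param fields_per_well Number of imaged fields per well (default 9).
#' @param seed Master seed.
#' @param spec [field_spec()] used for rendered fields.
#' @param morphotypes,proportions Passed to [generate_field()].
#' @param replicates Wells per dilution (default 3).
#' @param well_volume_uL Sample volume per well (default 50).
#' @param total_possible_fields Fields covering the whole well (default 650).
#' @param render If `FALSE`, skip pixel rendering and return ground-truth
#'   counts only (the Poisson draw is identical either way).
#' @return A list with `plate`, a tibble of one row per field (well,
#'   dilution_factor, replicate, field, true_count and, when rendered,
#'   a list-column `field_data` of [generate_field()] outputs), and the
#'   generating parameters (`stock_density`, etc.) as attributes-free
#'   elements for recovery tests.
#' @export
generate_dilution_series <- function(stock_density, dilution_factors,
                                     fields_per_well = 9L, seed = 1L,
                                     spec = field_spec(),
                                     morphotypes = default_morphotypes(),
                                     proportions = NULL,
                                     replicates = 3L,
                                     well_volume_uL = 50,
                                     total_possible_fields = 650L,
                                     render = TRUE) {
  if (any(diff(dilution_factors) <= 0))
    stop_hca("dilution_factors must be strictly increasing")
  if (any(dilution_factors <= 0)) stop_hca("dilution_factors must be positive")
  rows <- list()
  for (di in seq_along(dilution_factors)) {
    dil <- dilution_factors[di]
    lambda <- stock_density / dil * (well_volume_uL / 1000) / total_possible_fields
    for (rep_i in seq_len(replicates)) {
      well <- sprintf("%s%02d", LETTERS[di], rep_i)
      for (f in seq_len(fields_per_well) - 1L) {
        fseed <- derive_seed(seed, well, f)
        if (render) {
          fspec <- spec
          fspec$cell_density <- lambda
          fd <- generate_field(fspec, morphotypes, proportions, seed = fseed,
                               well = well, field = f)
          rows[[length(rows) + 1L]] <- tibble::tibble(
            well = well, dilution_factor = dil, replicate = rep_i, field = f,
            true_count = fd$truth$n_objects, field_data = list(fd))
        } else {
          old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
          set.seed(fseed)
          cnt <- rpois(1, lambda)
          if (!is.null(old)) assign(".Random.seed", old, globalenv())
          rows[[length(rows) + 1L]] <- tibble::tibble(
            well = well, dilution_factor = dil, replicate = rep_i, field = f,
            true_count = cnt)
        }
      }
    }
  }
  list(plate = dplyr::bind_rows(rows),
       stock_density = stock_density,
       fields_per_well = as.integer(fields_per_well),
       well_volume_uL = well_volume_uL,
       total_possible_fields = as.integer(total_possible_fields))
}

#' Generate a paired +HPG / -HPG object-feature sample
#'
#' Simulates the protein-synthesis viability readout at the feature-table
#' level: the -HPG sample's reporter-channel mode densities are drawn from
#' the autofluorescence distribution alone; in the +HPG sample, viable
#' (actively translating) cells are shifted up by `effect_size` SDs while
#' non-viable cells remain at autofluorescence.
#'
#' @param n_cells Objects in the +HPG sample (a warning is raised below 10,
#'   where a percentile cutoff is unstable).
#' @param viable_fraction True fraction of viable cells in \[0, 1\].
#' @param effect_size Separation of the viable +HPG intensity from
#'   autofluorescence, in autofluorescence SD units (> 0).
#' @param seed Integer seed.
#' @param autofluor_mean,autofluor_sd Autofluorescence mode-density
#'   distribution (normal).
#' @param n_minus Objects in the -HPG sample (default `n_cells`).
#' @return An `hpg_pair` list: `plus` and `minus` tibbles with
#'   `mode_density_Cy3` (plus carries the `true_viable` flag) and
#'   `viable_fraction` (the truth).
#' @export
generate_hpg_pair <- function(n_cells, viable_fraction, effect_size, seed = 1L,
                              autofluor_mean = 300, autofluor_sd = 60,
                              n_minus = n_cells) {
  if (viable_fraction < 0 || viable_fraction > 1)
    stop_hca("viable_fraction must lie in [0, 1]")
  if (effect_size <= 0)
    stop_hca("effect_size must be > 0 for a detectable signal")
  if (n_cells < 10)
    warn(sprintf("n_cells = %d < 10: percentile cutoff will be unstable", n_cells))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  minus <- tibble::tibble(
    object_id = seq_len(n_minus),
    mode_density_Cy3 = pmax(0, rnorm(n_minus, autofluor_mean, autofluor_sd)))
  viable <- runif(n_cells) < viable_fraction
  mu <- ifelse(viable, autofluor_mean + effect_size * autofluor_sd, autofluor_mean)
  plus <- tibble::tibble(
    object_id = seq_len(n_cells),
    true_viable = viable,
    mode_density_Cy3 = pmax(0, rnorm(n_cells, mu, autofluor_sd)))
  structure(list(plus = plus, minus = minus,
                 viable_fraction = viable_fraction,
                 effect_size = effect_size, seed = seed),
            class = "hpg_pair")
}

#' Simulate measured object features through the full imaging pipeline
#'
#' Renders seeded fields of the given morphotypes, segments and measures
#' them with the standard pipeline, and attaches the true morphotype of
#' each detected object (majority overlap with the ground-truth mask) as a
#' `strain` column. This is the end-to-end source of labelled per-object
#' feature tables for classifier training and evaluation.
#'
#' @param morphotypes List of [morphotype_spec()]s.
#' @param proportions Mixing proportions (default uniform).
#' @param n_fields Fields to render.
#' @param spec A [field_spec()] (default 320x320 px, 50 cells/field).
#' @param seed Master seed; each field uses its own derived stream.
#' @param params [segmentation_params()] used for detection.
#' @return Feature tibble (one row per detected object) with a `strain`
#'   column naming the majority-overlap true morphotype.
#' @export
simulate_object_features <- function(morphotypes, proportions = NULL,
                                     n_fields = 3,
                                     spec = field_spec(
                                       image_shape_px = c(320L, 320L),
                                       cell_density = 50),
                                     seed = 1L,
                                     params = segmentation_params()) {
  purrr::map_dfr(seq_len(n_fields), function(f) {
    fd <- generate_field(spec, morphotypes, proportions,
                         seed = derive_seed(seed, "features", f),
                         well = "A01", field = f - 1L)
    seg <- detect_objects(fd$image, params)
    feat <- measure_objects(seg, fd$image)
    if (nrow(feat) == 0) {
      feat$strain <- character(0)
      return(feat)
    }
    feat$strain <- vapply(feat$label, function(l) {
      tl <- fd$truth$label_image[seg$labels == l]
      tl <- tl[tl > 0]
      if (!length(tl)) return(NA_character_)
      winner <- as.integer(names(which.max(table(tl))))
      fd$truth$objects$morphotype[winner]
    }, "")
    feat[!is.na(feat$strain), , drop = FALSE]
  })
}
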