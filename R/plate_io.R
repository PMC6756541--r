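KNOWN_STAINS <- c("SytoBC", "DAPI", "PI", "SYTOX_Orange", "SYTOX_Green",
                  "HPG_AF594")

#' Read and validate a plate map
#'
#' The plate map is a CSV with one row per well and columns `well`,
#' `sample`, `strain`, `dilution_factor`, `stain_set` (stains separated by
#' `+`), `hpg` (`plus` / `minus` / `na`), `treatment`, `dose`,
#' `replicate`, `well_volume_uL`. Validation enforces: dilution factors
#' >= 1, known stain names, unique replicate indices per (sample,
#' dilution, treatment, hpg), and that every +HPG well has a -HPG partner
#' for the same sample, dilution, treatment and replicate.
#'
#' @param path CSV file path.
#' @return A `plate_map` tibble.
#' @export
read_plate_map <- function(path) {
  if (!file.exists(path)) stop_hca("plate map not found: %s", path)
  pm <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  validate_plate_map(pm)
}

#' @rdname read_plate_map
#' @param pm A data frame holding the plate-map columns.
#' @export
validate_plate_map <- function(pm) {
  required <- c("well", "sample", "dilution_factor", "stain_set", "hpg",
                "replicate")
  miss <- setdiff(required, names(pm))
  if (length(miss))
    stop_hca("plate map missing column(s): %s", paste(miss, collapse = ", "))
  if (!"strain" %in% names(pm)) pm$strain <- NA_character_
  if (!"treatment" %in% names(pm)) pm$treatment <- "none"
  if (!"dose" %in% names(pm)) pm$dose <- 0
  if (!"well_volume_uL" %in% names(pm)) pm$well_volume_uL <- 50
  if (any(pm$dilution_factor < 1))
    stop_hca("dilution_factor must be >= 1 for all wells")
  if (!all(pm$hpg %in% c("plus", "minus", "na")))
    stop_hca("hpg must be one of plus/minus/na")
  stains <- unique(unlist(strsplit(pm$stain_set, "\\+")))
  stains <- trimws(stains[nzchar(stains)])
  bad <- setdiff(stains, KNOWN_STAINS)
  if (length(bad))
    stop_hca("unknown stain(s): %s (known: %s)",
             paste(bad, collapse = ", "), paste(KNOWN_STAINS, collapse = ", "))
  dup <- pm |>
    dplyr::count(.data$sample, .data$dilution_factor, .data$treatment,
                 .data$hpg, .data$replicate) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup))
    stop_hca("replicate indices not unique per (sample, dilution, treatment, hpg)")
  plus <- pm[pm$hpg == "plus", , drop = FALSE]
  if (nrow(plus)) {
    minus <- pm[pm$hpg == "minus", , drop = FALSE]
    key <- function(d) paste(d$sample, d$dilution_factor, d$treatment, d$replicate)
    orphan <- !key(plus) %in% key(minus)
    if (any(orphan))
      stop_hca("+HPG well(s) without a paired -HPG well: %s",
               paste(plus$well[orphan], collapse = ", "))
  }
  class(pm) <- c("plate_map", class(pm))
  pm
}

field_file_name <- function(plate, well, field, role) {
  sprintf("%s_%s_f%d_%s.tif", plate, well, field, role)
}

#' Write / read a field image as per-channel 16-bit TIFFs
#'
#' One grayscale TIFF per channel, named
#' `<plate>_<well>_f<field>_<channelrole>.tif`.
#'
#' @param image A `field_image`.
#' @param dir Output directory (created if needed).
#' @return `write_field_image()` returns the written paths invisibly;
#'   `read_field_image()` returns a `field_image`.
#' @export
write_field_image <- function(image, dir) {
  stopifnot(inherits(image, "field_image"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (role in names(image$channels)) {
    p <- file.path(dir, field_file_name(image$plate, image$well, image$field, role))
    tiff::writeTIFF(image$channels[[role]] / 65535, p, bits.per.sample = 16,
                    compression = "none")
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' @rdname write_field_image
#' @param plate,well,field Identity of the field to read.
#' @param roles Channel roles to read.
#' @param um_per_px Pixel size to stamp on the result.
#' @export
read_field_image <- function(dir, plate, well, field,
                             roles = c("DAPI", "FITC", "Cy3"),
                             um_per_px = 0.065) {
  channels <- list()
  for (role in roles) {
    p <- file.path(dir, field_file_name(plate, well, field, role))
    if (!file.exists(p)) stop_hca("channel file not found: %s", p)
    m <- tiff::readTIFF(p)
    channels[[role]] <- matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
  }
  field_image(channels, well = well, field = field, plate = plate,
              um_per_px = um_per_px)
}

#' Write / read a label mask as 16-bit TIFF
#'
#' Labels are stored as raw 16-bit values (label 1 = pixel value 1).
#'
#' @param labels Integer label matrix (max label 65535).
#' @param path Output TIFF path.
#' @return `read_label_mask()` returns the integer label matrix.
#' @export
write_label_mask <- function(labels, path) {
  if (max(labels) > 65535) stop_hca("too many labels for a 16-bit mask")
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16,
                  compression = "none")
  invisible(path)
}

#' @rdname write_label_mask
#' @export
read_label_mask <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}

#' Read a run configuration
#'
#' YAML with sections `segmentation`, `enumeration`, `cutoffs`,
#' `classifier`, plus `seed` and `output_dir`; every section is optional
#' and falls back to package defaults, but present values are validated
#' before any stage runs.
#'
#' @param path YAML file path.
#' @return A `run_config` list with materialized parameter objects and a
#'   `config_hash` stamp.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_hca("config file not found: %s", path)
  raw <- yaml::read_yaml(path)
  build_run_config(raw)
}

#' @rdname read_run_config
#' @param raw A named list with the configuration sections.
#' @export
build_run_config <- function(raw = list()) {
  seg <- do.call(segmentation_params, raw$segmentation %||% list())
  enum_args <- raw$enumeration %||% list()
  if (is.null(enum_args$field_factor) && !is.null(raw$simulation)) {
    # extrapolation factor follows the simulated acquisition geometry
    enum_args$field_factor <- field_factor(
      raw$simulation$total_possible_fields %||% 650,
      raw$simulation$fields_per_well %||% 9)
  }
  enum <- do.call(enumeration_config, enum_args)
  cls <- raw$classifier %||% list()
  sim <- raw$simulation %||% list()
  cfg <- list(
    segmentation = seg,
    enumeration = enum,
    classifier = list(ntree = cls$ntree %||% 100,
                      mtry = cls$mtry,
                      exclude_roles = cls$exclude_roles %||% character(0)),
    simulation = sim,
    cutoffs = raw$cutoffs %||% list(),
    seed = as.integer(raw$seed %||% 1L),
    output_dir = raw$output_dir %||% "microhca-out")
  cfg$config_hash <- config_hash(cfg)
  class(cfg) <- "run_config"
  cfg
}

# md5 of the canonical JSON serialization (stable key order)
config_hash <- function(cfg) {
  cfg$config_hash <- NULL
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

#' Write ground truth to plain-text artifacts
#'
#' The per-object table goes to CSV; the label image to a 16-bit TIFF.
#'
#' @param truth A ground-truth list from [generate_field()].
#' @param dir Output directory.
#' @param stem File stem, e.g. `"plate1_A01_f0"`.
#' @return Written paths, invisibly.
#' @export
write_ground_truth <- function(truth, dir, stem) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, paste0(stem, "_truth.csv"))
  utils::write.csv(truth$objects, csv, row.names = FALSE)
  tif <- file.path(dir, paste0(stem, "_truth_labels.tif"))
  write_label_mask(truth$label_image, tif)
  invisible(c(csv, tif))
}
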