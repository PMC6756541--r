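read_stage_csv <- function(path) {
  if (!file.exists(path)) stop_hca("required input not found: %s", path)
  tibble::as_tibble(utils::read.csv(path))
}

stamp_artifact <- function(out, stage, cfg, extra = list()) {
  meta <- c(list(stage = stage, config_hash = cfg$config_hash,
                 seed = cfg$seed, written = iso_now()), extra)
  p <- file.path(out, sprintf("%s_meta.json", stage))
  jsonlite::write_json(meta, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(p)
}

sim_spec_from_config <- function(cfg) {
  sim <- cfg$simulation
  spec_args <- sim[names(sim) %in% names(formals(field_spec))]
  do.call(field_spec, spec_args)
}

#' Run one pipeline stage
#'
#' Thin orchestration over the package functions, tying the stages into the
#' two workflows (enumeration/viability and mixture classification). Each
#' subcommand is idempotent, reads its inputs from `out`, stamps every
#' artifact with the config hash and seed, and logs stage boundaries.
#'
#' Subcommands: `simulate` (synthetic dilution plate: channel TIFFs +
#' ground truth), `segment` (label masks + per-field counts),
#' `measure` (per-object feature CSV), `enumerate` (per-sample cells/mL
#' with linearity QC), `viability` (dye-exclusion gated viable counts),
#' `classify` (random-forest strain identification; pure wells train,
#' mixed wells are deconvolved), `report` (replicate mean/SD/%CV summary).
#'
#' @param command Subcommand name.
#' @param config A `run_config` (see [read_run_config()]) or a raw list.
#' @param out Output directory (default `config$output_dir`).
#' @return The stage's main result, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(command = c("simulate", "segment", "measure",
                                     "enumerate", "viability", "classify",
                                     "report"),
                         config = build_run_config(), out = NULL) {
  command <- match.arg(command)
  if (!inherits(config, "run_config")) config <- build_run_config(config)
  out <- out %||% config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_stage(command, sprintf("start (out = %s, seed = %d)", out, config$seed))
  res <- switch(command,
    simulate = stage_simulate(config, out),
    segment = stage_segment(config, out),
    measure = stage_measure(config, out),
    enumerate = stage_enumerate(config, out),
    viability = stage_viability(config, out),
    classify = stage_classify(config, out),
    report = stage_report(config, out))
  log_stage(command, "done")
  invisible(res)
}

stage_simulate <- function(cfg, out) {
  sim <- cfg$simulation
  spec <- sim_spec_from_config(cfg)
  series <- generate_dilution_series(
    stock_density = sim$stock_density %||% 1e9,
    dilution_factors = sim$dilution_factors %||% c(50, 250, 1250, 6250),
    fields_per_well = sim$fields_per_well %||% 9L,
    seed = cfg$seed, spec = spec,
    replicates = sim$replicates %||% 3L,
    well_volume_uL = sim$well_volume_uL %||% 50,
    total_possible_fields = sim$total_possible_fields %||% 650L,
    render = TRUE)
  img_dir <- file.path(out, "images")
  truth_dir <- file.path(out, "truth")
  for (i in seq_len(nrow(series$plate))) {
    fd <- series$plate$field_data[[i]]
    write_field_image(fd$image, img_dir)
    write_ground_truth(fd$truth, truth_dir,
                       sprintf("%s_%s_f%d", fd$image$plate, fd$image$well,
                               fd$image$field))
  }
  plate_tbl <- series$plate[c("well", "dilution_factor", "replicate", "field",
                              "true_count")]
  utils::write.csv(plate_tbl, file.path(out, "plate_fields.csv"),
                   row.names = FALSE)
  stamp_artifact(out, "simulate", cfg,
                 list(stock_density = series$stock_density,
                      n_fields = nrow(plate_tbl)))
  plate_tbl
}

stage_segment <- function(cfg, out) {
  plate <- read_stage_csv(file.path(out, "plate_fields.csv"))
  if (!nrow(plate)) stop_hca("no fields listed in %s/plate_fields.csv", out)
  spec <- sim_spec_from_config(cfg)
  mask_dir <- file.path(out, "masks")
  rows <- purrr::pmap(plate, function(well, dilution_factor, replicate, field,
                                      ...) {
    img <- read_field_image(file.path(out, "images"), "plate1", well, field,
                            roles = spec$channel_roles,
                            um_per_px = spec$um_per_px)
    seg <- detect_objects(img, cfg$segmentation)
    write_label_mask(seg$labels,
                     file.path(mask_dir,
                               sprintf("plate1_%s_f%d_labels.tif", well, field)))
    tibble::tibble(well = well, dilution_factor = dilution_factor,
                   replicate = replicate, field = field,
                   n_objects = seg$n_objects,
                   qc = paste(seg$qc, collapse = ";"))
  })
  counts <- dplyr::bind_rows(rows)
  utils::write.csv(counts, file.path(out, "field_counts.csv"), row.names = FALSE)
  stamp_artifact(out, "segment", cfg, list(n_fields = nrow(counts)))
  counts
}

stage_measure <- function(cfg, out) {
  plate <- read_stage_csv(file.path(out, "plate_fields.csv"))
  spec <- sim_spec_from_config(cfg)
  rows <- purrr::pmap(plate, function(well, dilution_factor, replicate, field,
                                      ...) {
    img <- read_field_image(file.path(out, "images"), "plate1", well, field,
                            roles = spec$channel_roles,
                            um_per_px = spec$um_per_px)
    labels <- read_label_mask(file.path(out, "masks",
                                        sprintf("plate1_%s_f%d_labels.tif",
                                                well, field)))
    measure_objects(labels_as_segmentation(labels, img), img)
  })
  features <- dplyr::bind_rows(rows)
  utils::write.csv(features, file.path(out, "features.csv"), row.names = FALSE)
  stamp_artifact(out, "measure", cfg, list(n_objects = nrow(features)))
  features
}

labels_as_segmentation <- function(labels, img) {
  structure(list(labels = labels, n_objects = max(labels), qc = character(0),
                 well = img$well, field = img$field, plate = img$plate),
            class = "segmentation")
}

stage_enumerate <- function(cfg, out) {
  counts <- read_stage_csv(file.path(out, "field_counts.csv"))
  per_well <- counts |>
    dplyr::group_by(.data$well, .data$dilution_factor, .data$replicate) |>
    dplyr::summarise(count = sum(.data$n_objects), .groups = "drop")
  series <- per_well[c("dilution_factor", "count")]
  est <- estimate_stock_density(series, cfg$enumeration)
  result <- tibble::tibble(
    sample = "sample1",
    cells_per_ml = est$cells_per_ml,
    r_squared = est$r_squared,
    linearity_pass = est$pass,
    dilutions_used = paste(est$accepted, collapse = ";"))
  utils::write.csv(est$per_well, file.path(out, "enumeration_wells.csv"),
                   row.names = FALSE)
  utils::write.csv(result, file.path(out, "enumeration.csv"), row.names = FALSE)
  jsonlite::write_json(as.list(result), file.path(out, "enumeration.json"),
                       auto_unbox = TRUE, digits = NA)
  stamp_artifact(out, "enumerate", cfg)
  result
}

stage_viability <- function(cfg, out) {
  features <- read_stage_csv(file.path(out, "features.csv"))
  cuts <- cfg$cutoffs
  cutoff <- cuts$dye_exclusion %||% default_cutoffs()$cutoff[1]
  counts <- read_stage_csv(file.path(out, "plate_fields.csv"))
  per_well <- features |>
    dplyr::group_by(.data$well) |>
    dplyr::group_modify(function(df, key) {
      # manual dye cutoffs refer to stain signal over background, so gate
      # on the background-subtracted mode density
      g <- gate_viable(df, cutoff, mode = "dye_exclusion",
                       channel_col = "mode_density_bgsub_Cy3")
      tibble::tibble(n_total = nrow(df), n_viable = g$n_viable)
    }) |>
    dplyr::ungroup() |>
    dplyr::left_join(dplyr::distinct(counts[c("well", "dilution_factor",
                                              "replicate")]),
                     by = "well") |>
    dplyr::mutate(
      total_cells_per_ml = enumerate_cells(.data$n_total,
                                           .data$dilution_factor,
                                           cfg$enumeration),
      viable_cells_per_ml = enumerate_cells(.data$n_viable,
                                            .data$dilution_factor,
                                            cfg$enumeration))
  utils::write.csv(per_well, file.path(out, "viability.csv"), row.names = FALSE)
  stamp_artifact(out, "viability", cfg, list(cutoff = cutoff))
  per_well
}

stage_classify <- function(cfg, out) {
  features <- read_stage_csv(file.path(out, "features.csv"))
  if (!"strain" %in% names(features))
    stop_hca("features.csv lacks a 'strain' column; classification needs pure-culture labels")
  pure <- features[!is.na(features$strain) & features$strain != "mixed", ]
  mixed <- features[is.na(features$strain) | features$strain == "mixed", ]
  parts <- partition_objects(pure, seed = cfg$seed)
  model <- train_strain_forest(parts[parts$partition == "train", ],
                               exclude_roles = cfg$classifier$exclude_roles,
                               seed = cfg$seed,
                               ntree = cfg$classifier$ntree,
                               mtry = cfg$classifier$mtry)
  confusion <- evaluate_per_strain(model, pure)
  utils::write.csv(confusion, file.path(out, "confusion.csv"), row.names = FALSE)
  report <- list(confusion = confusion, seed = cfg$seed,
                 partition_sizes = as.list(table(parts$partition)))
  if (nrow(mixed)) {
    mix <- classify_mixture(model, mixed)
    utils::write.csv(mix$composition, file.path(out, "mixture_composition.csv"),
                     row.names = FALSE)
    report$composition <- mix$composition
  }
  jsonlite::write_json(report, file.path(out, "classifier_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  stamp_artifact(out, "classify", cfg)
  report
}

stage_report <- function(cfg, out) {
  path <- file.path(out, "viability.csv")
  src <- if (file.exists(path)) {
    tibble::as_tibble(utils::read.csv(path))
  } else {
    tibble::as_tibble(utils::read.csv(file.path(out, "enumeration_wells.csv")))
  }
  summarize_col <- function(col) {
    dplyr::bind_cols(tibble::tibble(measure = col),
                     summarize_replicates(src[[col]]))
  }
  cols <- intersect(c("total_cells_per_ml", "viable_cells_per_ml",
                      "cells_per_ml"), names(src))
  summary <- dplyr::bind_rows(lapply(cols, summarize_col))
  utils::write.csv(summary, file.path(out, "summary.csv"), row.names = FALSE)
  stamp_artifact(out, "report", cfg)
  summary
}
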