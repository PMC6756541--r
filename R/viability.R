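#' Field extrapolation factor
#'
#' Ratio of the total possible fields covering a well bottom to the fields
#' actually imaged, used to extrapolate per-well object counts to the
#' whole well. With the 384-well defaults (650 possible fields, 9 imaged)
#' this is 650/9 = 72.22, printed as 72.2 at one decimal.
#'
#' @param total_possible_fields Total fields covering the well (default 650).
#' @param imaged_fields Fields imaged (default 9); must be positive and at
#'   most `total_possible_fields`.
#' @return The extrapolation factor, a positive real.
#' @export
field_factor <- function(total_possible_fields = 650, imaged_fields = 9) {
  if (imaged_fields <= 0) stop_hca("imaged_fields must be > 0")
  if (imaged_fields > total_possible_fields)
    stop_hca("imaged_fields (%s) exceeds total_possible_fields (%s)",
             imaged_fields, total_possible_fields)
  total_possible_fields / imaged_fields
}

#' Enumeration configuration
#'
#' @param field_factor Whole-well extrapolation factor (default 650/9).
#' @param sampling_factor Volume correction to cells/mL (default 20 for a
#'   50 uL well sample).
#' @param linearity_r2_min Minimum dilution-linearity R^2 (default 0.95).
#' @param min_dilutions Minimum dilutions for linearity QC (default 3).
#' @param hpg_rule Correction rule for the P90 HPG gate; see
#'   [hpg_viable_count()].
#' @return An `enumeration_config` list.
#' @export
enumeration_config <- function(field_factor = 650 / 9,
                               sampling_factor = 20,
                               linearity_r2_min = 0.95,
                               min_dilutions = 3L,
                               hpg_rule = c("p90_correction", "alternative")) {
  if (field_factor <= 0 || sampling_factor <= 0 || linearity_r2_min <= 0 ||
      min_dilutions <= 0)
    stop_hca("all enumeration_config values must be positive")
  structure(list(field_factor = field_factor, sampling_factor = sampling_factor,
                 linearity_r2_min = linearity_r2_min,
                 min_dilutions = as.integer(min_dilutions),
                 hpg_rule = match.arg(hpg_rule)),
            class = "enumeration_config")
}

#' Dead-control (heat-kill) intensity cutoff
#'
#' The autofluorescence/dead-stain cutoff is taken as a high percentile
#' (default 99.5) of the exclusion-dye intensity distribution measured on a
#' heat-killed control of the same strain; cutoffs are derived per strain.
#' Percentiles use the linear-interpolation convention (R type 7).
#'
#' @param dead_intensities Per-object intensities from the heat-killed
#'   control (at least 10 values).
#' @param percentile Percentile in (0, 100\]; default 99.5.
#' @return The cutoff intensity.
#' @export
heat_kill_cutoff <- function(dead_intensities, percentile = 99.5) {
  dead_intensities <- dead_intensities[!is.na(dead_intensities)]
  if (length(dead_intensities) < 10)
    stop_hca("need >= 10 dead-control intensities (got %d); set a manual cutoff instead",
             length(dead_intensities))
  unname(quantile(dead_intensities, percentile / 100, type = 7))
}

#' 90th-percentile cutoff from a -HPG sample
#'
#' Cutoff for the protein-synthesis (HPG/CLICK) gate: the 90th percentile
#' of the -HPG sample's reporter-channel mode densities, so ~10% of pure
#' autofluorescence objects (debris and outliers) exceed it by
#' construction. Linear-interpolation percentile convention (R type 7).
#'
#' @param minus_hpg_mode_densities Mode densities from the paired -HPG
#'   sample (at least 10 values).
#' @return The cutoff `x`.
#' @export
p90_cutoff <- function(minus_hpg_mode_densities) {
  v <- minus_hpg_mode_densities[!is.na(minus_hpg_mode_densities)]
  if (length(v) == 0) stop_hca("empty -HPG sample: cannot derive a P90 cutoff")
  if (length(v) < 10)
    stop_hca("need >= 10 -HPG values for a stable P90 cutoff (got %d)", length(v))
  unname(quantile(v, 0.90, type = 7))
}

#' Build a cutoff table entry
#'
#' Cutoffs are persisted with their provenance: `heat_kill` (derived from a
#' dead control), `p90_minus_hpg` (derived from a paired -HPG sample) or
#' `manual` (e.g. the fixed 100 for PI or 1000 for SYTOX Orange).
#'
#' @param sample Sample or strain the cutoff applies to.
#' @param channel_role Channel gated on.
#' @param stain Stain name.
#' @param cutoff Cutoff intensity (>= 0).
#' @param provenance One of `"heat_kill"`, `"p90_minus_hpg"`, `"manual"`.
#' @param parameters Optional text describing derivation parameters.
#' @return One-row tibble; bind rows to build the full table.
#' @export
cutoff_entry <- function(sample, channel_role, stain, cutoff,
                         provenance = c("manual", "heat_kill", "p90_minus_hpg"),
                         parameters = NA_character_) {
  provenance <- match.arg(provenance)
  if (cutoff < 0) stop_hca("cutoff must be >= 0")
  tibble::tibble(sample = sample, channel_role = channel_role, stain = stain,
                 cutoff = cutoff, provenance = provenance,
                 parameters = parameters)
}

#' Default manual stain cutoffs
#'
#' The fixed intensity cutoffs used when no strain-specific control is
#' available: 100 for PI and 1000 for SYTOX Orange.
#'
#' @return Tibble of manual cutoff entries (sample `"*"` = any).
#' @export
default_cutoffs <- function() {
  dplyr::bind_rows(
    cutoff_entry("*", "Cy3", "PI", 100, "manual"),
    cutoff_entry("*", "Cy3", "SYTOX_Orange", 1000, "manual"))
}

#' Gate objects into viable / non-viable
#'
#' Two gating modes: `dye_exclusion` (membrane-impermeant DNA dyes such as
#' PI or SYTOX Orange stain only dead cells, so viable objects have
#' intensity at or below the cutoff) and `incorporation` (HPG/CLICK signal
#' marks active protein synthesis, so viable objects lie strictly above
#' the cutoff).
#'
#' @param records Per-object feature tibble.
#' @param cutoff Intensity cutoff `x`.
#' @param mode `"dye_exclusion"` or `"incorporation"`.
#' @param channel_col Feature column gated on (default
#'   `"mode_density_Cy3"`).
#' @return List: `n_viable` and `viable` (the viable subset of `records`).
#' @export
gate_viable <- function(records, cutoff,
                        mode = c("dye_exclusion", "incorporation"),
                        channel_col = "mode_density_Cy3") {
  mode <- match.arg(mode)
  if (nrow(records) == 0) return(list(n_viable = 0L, viable = records))
  if (!channel_col %in% names(records))
    stop_hca("gating column '%s' not present in records", channel_col)
  v <- records[[channel_col]]
  keep <- if (mode == "dye_exclusion") v <= cutoff else v > cutoff
  list(n_viable = sum(keep), viable = records[keep, , drop = FALSE])
}

#' Corrected viable count under the P90 HPG gate
#'
#' With the cutoff at the 90th percentile of the -HPG distribution, 10% of
#' +HPG objects are expected above it by chance even with no protein
#' synthesis; the corrected viable count subtracts that allowance:
#' `n_A_v - 0.1 * n_A`, clamped to `[0, n_A]`. `rule = "alternative"`
#' preserves the other grouping of the correction,
#' `n_A - (n_A_v - 0.1 * n_A)`, for auditability.
#'
#' @param n_A Objects in the +HPG sample.
#' @param n_A_v Objects in the +HPG sample with mode density above the
#'   cutoff.
#' @param rule Correction rule (default `"p90_correction"`).
#' @return Corrected viable count (real, clamped to `[0, n_A]`).
#' @export
hpg_viable_count <- function(n_A, n_A_v,
                             rule = c("p90_correction", "alternative")) {
  rule <- match.arg(rule)
  if (n_A_v < 0 || n_A_v > n_A) stop_hca("need 0 <= n_A_v <= n_A")
  raw <- if (rule == "p90_correction") n_A_v - 0.1 * n_A
         else n_A - (n_A_v - 0.1 * n_A)
  min(max(raw, 0), n_A)
}

#' Analyze a paired +HPG / -HPG sample
#'
#' Derives the P90 cutoff from the -HPG sample, counts +HPG objects above
#' it, applies the 10% correction, and reports the debiased viable
#' fraction: since non-viable objects exceed a P90 cutoff at rate 0.1 and
#' strongly translating cells at ~1, `E[n_A_v/n_A] = f + 0.1(1 - f)`, so
#' `f` is estimated by `(n_A_v/n_A - 0.1) / 0.9` (equivalently
#' `corrected_viable / (0.9 n_A)`), clamped to `[0, 1]`.
#'
#' @param pair An `hpg_pair` (see [generate_hpg_pair()]) or a list with
#'   `plus` and `minus` feature tibbles.
#' @param channel_col Mode-density column gated on.
#' @param rule Correction rule, see [hpg_viable_count()].
#' @return An `hpg_result` list: `cutoff`, `n_A`, `n_A_v`,
#'   `corrected_viable`, `viable_fraction_estimate`.
#' @export
hpg_pair_result <- function(pair, channel_col = "mode_density_Cy3",
                            rule = c("p90_correction", "alternative")) {
  rule <- match.arg(rule)
  x <- p90_cutoff(pair$minus[[channel_col]])
  n_A <- nrow(pair$plus)
  n_A_v <- sum(pair$plus[[channel_col]] > x)
  corrected <- hpg_viable_count(n_A, n_A_v, rule)
  est <- if (n_A > 0) min(max((n_A_v / n_A - 0.1) / 0.9, 0), 1) else NA_real_
  structure(list(cutoff = x, n_A = n_A, n_A_v = n_A_v,
                 corrected_viable = corrected,
                 viable_fraction_estimate = est, rule = rule),
            class = "hpg_result")
}

#' @export
print.hpg_result <- function(x, ...) {
  cat(sprintf("<hpg_result> cutoff %.1f; n(A) = %d, n(A)v = %d; corrected viable %.1f; viable fraction %.3f\n",
              x$cutoff, x$n_A, x$n_A_v, x$corrected_viable,
              x$viable_fraction_estimate))
  invisible(x)
}

#' Extrapolate imaged counts to cells per mL
#'
#' `cells/mL = counts * field_factor * dilution_factor * sampling_factor`:
#' counts over the imaged fields of a well are scaled to the whole well,
#' undiluted, and corrected for the sampled volume.
#'
#' @param counts Object count(s) over the imaged fields of a well.
#' @param dilution_factor Final dilution of the imaged sample (>= 1).
#' @param cfg An [enumeration_config()].
#' @return Cells per mL (vectorized over `counts`).
#' @export
enumerate_cells <- function(counts, dilution_factor,
                            cfg = enumeration_config()) {
  if (any(counts < 0)) stop_hca("counts must be >= 0")
  if (any(dilution_factor < 1)) stop_hca("dilution_factor must be >= 1")
  counts * cfg$field_factor * dilution_factor * cfg$sampling_factor
}

#' Dilution-linearity quality control
#'
#' Counts from a valid serial dilution must scale as 1/dilution. The mean
#' count per dilution is regressed on 1/dilution_factor by least squares
#' and the series passes when R^2 exceeds `linearity_r2_min` with at least
#' `min_dilutions` dilutions. If the full series fails, the dilution with
#' the largest standardized residual is dropped and the fit repeated while
#' at least `min_dilutions` remain; enumeration uses only the accepted
#' dilutions.
#'
#' @param series Tibble with `dilution_factor` and `count` (one row per
#'   well; replicates share a dilution_factor).
#' @param cfg An [enumeration_config()].
#' @return List: `r_squared`, `accepted` (dilution factors), `pass`.
#' @export
linearity_qc <- function(series, cfg = enumeration_config()) {
  stopifnot(is.data.frame(series),
            all(c("dilution_factor", "count") %in% names(series)))
  means <- series |>
    dplyr::group_by(.data$dilution_factor) |>
    dplyr::summarise(mean_count = mean(.data$count), .groups = "drop")
  if (nrow(means) < cfg$min_dilutions)
    stop_hca("linearity QC needs >= %d dilutions (got %d)",
             cfg$min_dilutions, nrow(means))
  fit_r2 <- function(df) {
    fit <- lm(mean_count ~ I(1 / dilution_factor), data = df)
    ss_tot <- sum((df$mean_count - mean(df$mean_count))^2)
    r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 0
    list(r2 = r2, fit = fit)
  }
  cur <- means
  repeat {
    f <- fit_r2(cur)
    if (f$r2 > cfg$linearity_r2_min)
      return(list(r_squared = f$r2, accepted = sort(cur$dilution_factor),
                  pass = TRUE))
    if (nrow(cur) - 1 < cfg$min_dilutions) break
    res <- abs(stats::residuals(f$fit))
    cur <- cur[-which.max(res), , drop = FALSE]
  }
  f <- fit_r2(means)
  list(r_squared = f$r2, accepted = numeric(0), pass = FALSE)
}

#' Estimate stock density from a dilution series
#'
#' Runs [linearity_qc()], converts per-well counts of accepted dilutions
#' to cells/mL with [enumerate_cells()], and averages.
#'
#' @param series Tibble with `dilution_factor` and `count` per well.
#' @param cfg An [enumeration_config()].
#' @return List: `cells_per_ml` (NA when QC fails), `r_squared`, `pass`,
#'   `accepted`, `per_well` tibble of well-level estimates.
#' @export
estimate_stock_density <- function(series, cfg = enumeration_config()) {
  qc <- linearity_qc(series, cfg)
  per_well <- series |>
    dplyr::mutate(cells_per_ml = enumerate_cells(.data$count,
                                                 .data$dilution_factor, cfg))
  est <- if (qc$pass) {
    acc <- per_well |> dplyr::filter(.data$dilution_factor %in% qc$accepted)
    mean(acc$cells_per_ml)
  } else NA_real_
  list(cells_per_ml = est, r_squared = qc$r_squared, pass = qc$pass,
       accepted = qc$accepted, per_well = per_well)
}

#' Replicate summary (mean, SD, %CV)
#'
#' Sample standard deviation; percent coefficient of variation
#' `100 * SD / mean`. A zero mean leaves %CV undefined (NA, flagged).
#'
#' @param values Per-replicate cells/mL (>= 2 values).
#' @return One-row tibble: `n`, `mean`, `sd`, `cv_percent`, `qc_flags`.
#' @export
summarize_replicates <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) stop_hca("need >= 2 replicates (got %d)", length(values))
  m <- mean(values); s <- sd(values)
  cv <- if (m == 0) NA_real_ else 100 * s / m
  tibble::tibble(n = length(values), mean = m, sd = s, cv_percent = cv,
                 qc_flags = if (m == 0) "zero_mean" else "")
}
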