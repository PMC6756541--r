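# Synthetic field generator: determinism, ground-truth contracts, and the
# statistical properties downstream recovery tests rely on.

test_that("zero-density field has no objects and only background + noise", {
  fs <- field_spec(image_shape_px = c(64, 64), cell_density = 0,
                   background_level = 100, read_noise_sd = 3)
  fd <- generate_field(fs, seed = 11)
  expect_equal(fd$truth$n_objects, 0)
  expect_equal(nrow(fd$truth$objects), 0)
  expect_true(all(fd$truth$label_image == 0L))
  for (g in fd$image$channels) {
    expect_lt(abs(mean(g) - 100), 5)        # background level
    expect_lt(max(g), 100 + 8 * sqrt(100) + 30)  # no signal spikes
  }
})

test_that("exact-count mode places the requested number of disjoint cells", {
  fs <- field_spec(image_shape_px = c(200, 200), cell_density = 0)
  fd <- generate_field(fs, morphotypes = list(default_morphotypes()$coccus),
                       seed = 7, n_cells = 12)
  expect_equal(fd$truth$n_objects, 12)
  expect_setequal(unique(as.vector(fd$truth$label_image)), 0:12)
  # disjoint by construction: every pixel carries at most one label
  areas <- tabulate(fd$truth$label_image[fd$truth$label_image > 0], 12)
  expect_equal(sum(areas), sum(fd$truth$label_image > 0))
  expect_true(all(areas > 0))
})

test_that("identical seed gives bit-identical image and truth", {
  fs <- field_spec(image_shape_px = c(160, 160), cell_density = 8)
  a <- generate_field(fs, seed = 42)
  b <- generate_field(fs, seed = 42)
  expect_identical(a$image$channels, b$image$channels)
  expect_identical(a$truth$objects, b$truth$objects)
  c <- generate_field(fs, seed = 43)
  expect_false(identical(a$image$channels, c$image$channels))
})

test_that("viable flag fraction converges to viable_fraction", {
  fs <- field_spec(image_shape_px = c(128, 128), cell_density = 0,
                   viable_fraction = 0.6, overlap_allowed = TRUE)
  mt <- list(default_morphotypes()$coccus)
  flags <- unlist(lapply(1:50, function(s) {
    generate_field(fs, morphotypes = mt, seed = s, n_cells = 20)$truth$objects$viable
  }))
  expect_length(flags, 1000)
  expect_lt(abs(mean(flags) - 0.6), 0.05)
})

test_that("image too small for the morphotype fails naming it", {
  fs <- field_spec(image_shape_px = c(32, 32), cell_density = 0)
  expect_error(
    generate_field(fs, morphotypes = list(default_morphotypes()$filament),
                   seed = 1, n_cells = 2),
    "filament")
})

test_that("truth mask pixels carry signal above background in a stained channel", {
  fs <- field_spec(image_shape_px = c(200, 200), cell_density = 15,
                   background_level = 100)
  fd <- generate_field(fs, seed = 5)
  on_cell <- fd$truth$label_image > 0
  dapi <- fd$image$channels$DAPI
  expect_true(all(dapi[on_cell] >= 100))
})

test_that("dilution series: expected counts scale as 1/dilution (slope -1)", {
  factors <- c(50, 250, 1250, 6250)
  means <- sapply(1:20, function(s) {
    ser <- generate_dilution_series(2e9, factors, fields_per_well = 3,
                                    seed = s, replicates = 1, render = FALSE)
    tapply(ser$plate$true_count, ser$plate$dilution_factor, mean)
  })
  mean_counts <- rowMeans(means)[as.character(factors)]
  fit <- lm(log(mean_counts) ~ log(factors))
  expect_lt(abs(coef(fit)[2] + 1), 0.05)
})

test_that("dilution series matches the Poisson closed form", {
  # stock 1e9 at 1:250 in a 50 uL well, 9 of 650 fields imaged
  lambda <- 1e9 / 250 * 0.05 / 650          # expected objects per field
  ser <- generate_dilution_series(1e9, c(50, 250, 1250, 6250),
                                  fields_per_well = 9, seed = 2,
                                  replicates = 3, render = FALSE)
  cnt <- ser$plate$true_count[ser$plate$dilution_factor == 250]
  se <- sqrt(lambda / length(cnt))
  expect_lt(abs(mean(cnt) - lambda), 3 * se)
  # single factor gives a single well
  one <- generate_dilution_series(1e8, 50, fields_per_well = 2, seed = 1,
                                  replicates = 1, render = FALSE)
  expect_equal(unique(one$plate$well), "A01")
  expect_error(generate_dilution_series(1e8, c(250, 50), seed = 1),
               "strictly increasing")
})

test_that("adjacent 1:5 dilutions have expected count ratio 5", {
  factors <- c(50, 250, 1250, 6250)
  ser <- generate_dilution_series(5e9, factors, fields_per_well = 9,
                                  seed = 3, replicates = 3, render = FALSE)
  m <- tapply(ser$plate$true_count, ser$plate$dilution_factor, mean)
  m <- m[as.character(factors)]
  ratios <- m[-length(m)] / m[-1]
  expect_true(all(abs(ratios - 5) < 0.8))
})

test_that("hpg pair: null and saturated limits behave", {
  # viable_fraction 0: both samples from the same distribution
  p0 <- generate_hpg_pair(2000, 0, effect_size = 6, seed = 4)
  expect_lt(abs(mean(p0$plus$mode_density_Cy3) - mean(p0$minus$mode_density_Cy3)),
            3 * 60 / sqrt(1000))
  expect_false(any(p0$plus$true_viable))
  # viable_fraction 1, large effect: essentially all plus objects above P90
  p1 <- generate_hpg_pair(2000, 1, effect_size = 6, seed = 4)
  x <- p90_cutoff(p1$minus$mode_density_Cy3)
  expect_gt(mean(p1$plus$mode_density_Cy3 > x), 0.99)
  expect_warning(generate_hpg_pair(5, 0.5, 6, seed = 1), "unstable")
  expect_error(generate_hpg_pair(100, 0.5, effect_size = 0, seed = 1), "effect_size")
})

test_that("field RNG streams are independent per (seed, well, field)", {
  s1 <- derive_seed(1, "A01", 0)
  expect_identical(s1, derive_seed(1, "A01", 0))
  expect_false(s1 == derive_seed(1, "A01", 1))
  expect_false(s1 == derive_seed(1, "B01", 0))
  expect_false(s1 == derive_seed(2, "A01", 0))
  expect_true(s1 >= 0 && s1 < 2^31)
})

test_that("morphotype invariants are enforced", {
  expect_error(morphotype_spec("bad", "rod", length_um = 0.5, width_um = 1),
               "length_um")
  expect_error(morphotype_spec("bad", "rod", length_um = 2, width_um = 1,
                               stain_coverage = c(FITC = 1.4)),
               "stain_coverage")
  expect_error(field_spec(viable_fraction = 1.2), "viable_fraction")
  expect_error(generate_field(field_spec(), proportions = c(0.5, 0.2), seed = 1),
               "sum to 1")
})
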