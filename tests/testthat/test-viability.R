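# Cutoffs, gating, enumeration arithmetic, linearity QC and replicate
# summaries.

test_that("field factor arithmetic", {
  expect_equal(round(field_factor(650, 9), 1), 72.2)
  expect_equal(field_factor(650, 9), 650 / 9)
  expect_equal(field_factor(400, 400), 1.0)
  expect_equal(field_factor(100, 4), 25.0)
  expect_error(field_factor(650, 0), "imaged_fields")
  expect_error(field_factor(10, 20), "exceeds")
})

test_that("heat-kill cutoff is the stated percentile of the dead control", {
  expect_equal(heat_kill_cutoff(rep(42, 20)), 42)
  v <- seq(0, 1000, by = 1)   # uniform grid: order-statistics oracle
  expect_equal(heat_kill_cutoff(v, 99.5), quantile(v, 0.995, type = 7),
               ignore_attr = TRUE)
  expect_lt(abs(heat_kill_cutoff(v, 99.5) - 995), 1)
  expect_error(heat_kill_cutoff(c(1, 2, 3)), ">= 10")
})

test_that("manual stain cutoffs are honored verbatim", {
  tab <- default_cutoffs()
  expect_equal(tab$cutoff[tab$stain == "PI"], 100)
  expect_equal(tab$cutoff[tab$stain == "SYTOX_Orange"], 1000)
  expect_true(all(tab$provenance == "manual"))
  rec <- tibble::tibble(mode_density_Cy3 = c(50, 150))
  g <- gate_viable(rec, tab$cutoff[tab$stain == "PI"], "dye_exclusion")
  expect_equal(g$n_viable, 1)
})

test_that("P90 cutoff leaves exactly 10% of distinct values strictly above", {
  x <- p90_cutoff(1:100)
  expect_equal(sum(1:100 > x), 10)
  # all-equal values: cutoff equals the value, none strictly above
  xx <- p90_cutoff(rep(7, 50))
  expect_equal(xx, 7)
  expect_equal(sum(rep(7, 50) > xx), 0)
  # normal quantile oracle
  set.seed(2)
  z <- rnorm(10000)
  expect_lt(abs(p90_cutoff(z) - qnorm(0.9)), 0.05)
  expect_error(p90_cutoff(numeric(0)), "empty")
})

test_that("P90 exceedance is floor(0.1 n) within 1 for distinct samples", {
  set.seed(5)
  for (n in c(10, 15, 20, 37, 100, 253, 1000)) {
    v <- sample(seq_len(10 * n), n)   # distinct
    x <- p90_cutoff(v)
    expect_lte(abs(sum(v > x) - floor(0.1 * n)), 1)
  }
})

test_that("gating modes select opposite sides of the cutoff", {
  rec <- tibble::tibble(mode_density_Cy3 = c(50, 150))
  de <- gate_viable(rec, 100, "dye_exclusion")
  expect_equal(de$n_viable, 1)
  expect_equal(de$viable$mode_density_Cy3, 50)
  inc <- gate_viable(rec, 100, "incorporation")
  expect_equal(inc$n_viable, 1)
  expect_equal(inc$viable$mode_density_Cy3, 150)
  expect_equal(gate_viable(rec[0, ], 100, "dye_exclusion")$n_viable, 0)
  expect_error(gate_viable(rec, 100, "nonsense"))
})

test_that("raising a dye-exclusion cutoff never decreases the viable count", {
  set.seed(9)
  rec <- tibble::tibble(mode_density_Cy3 = rlnorm(500, 5, 1))
  counts <- sapply(c(50, 100, 200, 500, 1000),
                   function(x) gate_viable(rec, x, "dye_exclusion")$n_viable)
  expect_true(all(diff(counts) >= 0))
})

test_that("HPG viable-count correction subtracts the 10% allowance", {
  expect_equal(hpg_viable_count(200, 60), 40)
  expect_equal(hpg_viable_count(200, 20), 0)    # n_A_v = 0.1 n_A exactly
  expect_equal(hpg_viable_count(100, 5), 0)     # clamped at zero
  expect_equal(hpg_viable_count(100, 100, rule = "alternative"),
               100 - (100 - 0.1 * 100))
  expect_error(hpg_viable_count(10, 11), "n_A_v")
})

test_that("HPG pair analysis recovers a 50% viable fraction", {
  res <- lapply(1:20, function(s) {
    pair <- generate_hpg_pair(2000, 0.5, effect_size = 6, seed = s)
    tidy(hpg_pair_result(pair))
  })
  res <- dplyr::bind_rows(res)
  # the raw P90-corrected count estimates 0.9 f (closed form)
  expect_lt(abs(mean(res$corrected_viable / res$n_A) - 0.45), 0.02)
  # the debiased fraction estimates f itself
  expect_lt(abs(mean(res$viable_fraction_estimate) - 0.5), 0.05)
})

test_that("enumeration formula: counts x 72.2 x dilution x sampling", {
  expect_equal(enumerate_cells(100, 250), 100 * (650 / 9) * 250 * 20)
  expect_equal(round(enumerate_cells(100, 250) / 1e7, 3), 3.611)
  expect_equal(enumerate_cells(0, 6250), 0)
  unit <- enumeration_config(field_factor = 1, sampling_factor = 1)
  expect_equal(enumerate_cells(37, 1, unit), 37)
  # linear in counts and in each factor
  expect_equal(enumerate_cells(2 * 50, 250), 2 * enumerate_cells(50, 250))
  expect_equal(enumerate_cells(50, 2 * 250), 2 * enumerate_cells(50, 250))
})

test_that("linearity QC passes exact series and fails flat ones", {
  dil <- c(50, 250, 1250, 6250)
  exact <- tibble::tibble(dilution_factor = dil, count = 1e5 / dil)
  qc <- linearity_qc(exact)
  expect_equal(qc$r_squared, 1.0)
  expect_true(qc$pass)
  expect_setequal(qc$accepted, dil)

  set.seed(3)
  flat <- tibble::tibble(dilution_factor = dil, count = 100 + rnorm(4))
  qc2 <- linearity_qc(flat)
  expect_lt(qc2$r_squared, 0.5)
  expect_false(qc2$pass)

  expect_error(linearity_qc(exact[1:2, ]), "dilutions")
})

test_that("noisy 1:5 series passes linearity QC in nearly all trials", {
  dil <- c(50, 250, 1250, 6250)
  passes <- sapply(1:40, function(s) {
    set.seed(s)
    counts <- rpois(12, rep(5e4 / dil, each = 3))
    ser <- tibble::tibble(dilution_factor = rep(dil, each = 3), count = counts)
    linearity_qc(ser)$pass
  })
  expect_gte(mean(passes), 0.95)
})

test_that("stock density is recovered from ground-truth dilution counts", {
  ser <- generate_dilution_series(1e9, c(50, 250, 1250, 6250),
                                  fields_per_well = 9, seed = 6,
                                  replicates = 3, render = FALSE)
  per_well <- dplyr::summarise(
    dplyr::group_by(ser$plate, .data$well, .data$dilution_factor),
    count = sum(.data$true_count), .groups = "drop")
  est <- estimate_stock_density(per_well[c("dilution_factor", "count")])
  expect_true(est$pass)
  expect_lt(abs(est$cells_per_ml / 1e9 - 1), 0.1)
})

test_that("replicate summary reproduces the reported %CV layout", {
  # replicate vector constructed to have mean 4.1e9 and sample SD 3.7e8
  x <- as.numeric(scale(1:6))
  reps <- 4.1e9 + 3.7e8 * x
  s <- summarize_replicates(reps)
  expect_equal(s$mean, 4.1e9)
  expect_equal(s$sd, 3.7e8)
  expect_equal(round(s$cv_percent, 1), 9.0)

  same <- summarize_replicates(rep(2.5e9, 4))
  expect_equal(same$sd, 0)
  expect_equal(same$cv_percent, 0)

  s3 <- summarize_replicates(c(1, 2, 3))
  expect_equal(s3$mean, 2)
  expect_equal(s3$sd, 1)
  expect_equal(s3$cv_percent, 50)

  zero <- summarize_replicates(c(-1, 1))
  expect_true(is.na(zero$cv_percent))
  expect_equal(zero$qc_flags, "zero_mean")
  expect_error(summarize_replicates(5), ">= 2")
})
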