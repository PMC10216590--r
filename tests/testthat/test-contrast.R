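# thick strongly absorbing sections are optically semi-infinite, so the two
# stacks reduce to bare Fresnel interfaces with known reflectances:
# (n, k) = (2, 1) -> R = 0.2 ; (1.468..., 0.3) -> R = 0.05
opaque_pair_library <- function() {
  n_surr <- (2.1 + sqrt(2.1^2 - 4 * 0.95 * 1.0355)) / (2 * 0.95)
  flat_library(
    c(air = 1, cellm = 2, surrm = n_surr, polycarbonate_tape = 1.59,
      carbon_tape = 2.2, silicon = 4),
    c(cellm = 1, surrm = 0.3, carbon_tape = 0.75, silicon = 0.03))
}

test_that("build_stacks assembles the imaging stack in order", {
  cfg0 <- omlit_config(section_thickness_nm = 60)
  st0 <- build_stacks(cfg0)
  expect_equal(nrow(st0$cell$layers), 3)
  expect_equal(st0$cell$layers$material,
               c("stained_cell", "polycarbonate_tape", "carbon_tape"))
  expect_equal(st0$surround$layers$material[[1]], "stained_tissue")
  expect_equal(st0$cell$layers$thickness_nm[-1], st0$surround$layers$thickness_nm[-1])

  cfg_ag <- omlit_config(coating = list(material = "silver", thickness_nm = 70))
  st_ag <- build_stacks(cfg_ag)
  expect_equal(nrow(st_ag$cell$layers), 4)
  expect_equal(st_ag$cell$layers$material[[2]], "silver")
  expect_equal(st_ag$cell$layers$thickness_nm[[2]], 70)

  cfg_same <- omlit_config(cell_material = "stained_tissue",
                           surround_material = "stained_tissue")
  st_same <- build_stacks(cfg_same)
  expect_identical(st_same$cell, st_same$surround)

  expect_error(omlit_contrast(omlit_config(cell_material = "unobtainium"),
                              illumination(470), omlit_materials()),
               "unknown material")
})

test_that("contrast is the max/min reflectance ratio, symmetric, and 1 for identical materials", {
  lib <- opaque_pair_library()
  cfg <- omlit_config(section_thickness_nm = 3000, cell_material = "cellm",
                      surround_material = "surrm")
  res <- omlit_contrast(cfg, illumination(470), lib)
  expect_equal(res$R_cell, 0.2, tolerance = 1e-6)
  expect_equal(res$R_surround, 0.05, tolerance = 1e-6)
  expect_equal(res$contrast, 4, tolerance = 1e-5)
  expect_gte(res$contrast, 1)

  # swapping the cell and surround roles leaves the contrast unchanged
  cfg_sw <- omlit_config(section_thickness_nm = 3000, cell_material = "surrm",
                         surround_material = "cellm")
  expect_equal(omlit_contrast(cfg_sw, illumination(470), lib)$contrast,
               res$contrast, tolerance = 1e-12)

  # Michelson alternative: (0.2 - 0.05) / (0.2 + 0.05) = 0.6
  expect_equal(omlit_contrast(cfg, illumination(470), lib, mode = "michelson")$contrast,
               0.6, tolerance = 1e-5)

  same <- omlit_config(cell_material = "stained_cell", surround_material = "stained_cell")
  expect_equal(omlit_contrast(same, illumination(470), omlit_materials())$contrast, 1)
})

test_that("sweep grid equals pointwise contrast calls and annotates its optimum", {
  lib <- omlit_materials()
  cfg <- omlit_config(coating = list(material = "silver", thickness_nm = 10))

  # degenerate 1x1x1 grid reduces to a single contrast call
  sw1 <- contrast_sweep(cfg, lib, section_grid = 60, coating_grid = 70,
                        wavelengths = 470)
  c1 <- omlit_contrast(omlit_config(section_thickness_nm = 60,
                                    coating = list(material = "silver", thickness_nm = 70)),
                       illumination(470), lib)
  expect_equal(nrow(sw1), 1)
  expect_equal(sw1$contrast, c1$contrast, tolerance = 1e-12)

  sw <- contrast_sweep(cfg, lib, section_grid = c(40, 60, 90),
                       coating_grid = c(30, 70, 150), wavelengths = c(470, 630))
  expect_equal(nrow(sw), 3 * 3 * 2)
  for (i in c(1, 5, 11, 18)) {
    ci <- omlit_contrast(
      omlit_config(section_thickness_nm = sw$section_nm[i],
                   coating = list(material = "silver", thickness_nm = sw$coating_nm[i])),
      illumination(sw$wavelength_nm[i]), lib)
    expect_equal(sw$contrast[i], ci$contrast, tolerance = 1e-9)
    expect_equal(sw$R_cell[i], ci$R_cell, tolerance = 1e-9)
  }

  # argmax equals the grid maximum; fraction thickness never exceeds it
  am <- attr(sw, "argmax")
  expect_equal(am$best_contrast, max(sw$contrast))
  opt <- sweep_optima(sw)
  expect_true(all(opt$fraction_thickness_nm <= opt$coating_nm))
  expect_error(contrast_sweep(cfg, lib, section_grid = numeric(0)), "non-empty")
})

test_that("contrast fluctuation period scales with wavelength as lambda/(2 n)", {
  # cell and surround differ only in section-layer extinction; opaque substrate
  lib <- flat_library(c(air = 1, cellm = 1.5, surrm = 1.5, metal = 0.9),
                      c(cellm = 0.02, surrm = 0, metal = 5.5))
  cfg <- omlit_config(tape_thickness_nm = 0, carbon_tape_thickness_nm = 0,
                      substrate = "metal", cell_material = "cellm",
                      surround_material = "surrm")
  periods <- vapply(c(390, 630), function(lambda) {
    sw <- contrast_sweep(cfg, lib, section_grid = seq(10, 900, 2),
                         coating_grid = 0, wavelengths = lambda)
    estimate_period(sw$section_nm, sw$contrast)$period_nm
  }, numeric(1))
  expect_lt(abs(periods[[1]] - 390 / 3), 2 + 1e-9)
  expect_lt(abs(periods[[2]] - 630 / 3), 2 + 1e-9)
  expect_lt(abs(periods[[2]] / periods[[1]] - 630 / 390), 0.1 * 630 / 390)
})

test_that("optimum report mirrors the per-wavelength optima and their reduced thicknesses", {
  lib <- omlit_materials()
  cfg <- omlit_config(coating = list(material = "silver", thickness_nm = 10))

  # single-point sweep: the row reproduces that point
  sw1 <- contrast_sweep(cfg, lib, section_grid = 60, coating_grid = 70,
                        wavelengths = 470)
  rep1 <- optimum_report(list(silver = sw1))
  expect_equal(nrow(rep1), 1)
  expect_equal(rep1$coating_nm, 70)
  expect_equal(rep1$coating_nm_fraction, 70)
  expect_equal(rep1$best_contrast, max(sw1$contrast))

  # saturating contrast: a half-wave absorbing section over an increasingly
  # opaque mirror gives contrast rising monotonically to the coating-opacity
  # plateau; optimum pinned at the grid end, reduced thickness below it
  lib_sat <- flat_library(
    c(air = 1, cellm = 1.56, surrm = 1.56, mirror = 0.06,
      polycarbonate_tape = 1.59, carbon_tape = 2.2, black = 1.59),
    c(cellm = 0.1, carbon_tape = 0.75, black = 0.4))
  cfg_sat <- omlit_config(section_thickness_nm = 150,
                          coating = list(material = "mirror", thickness_nm = 10),
                          substrate = "black",
                          cell_material = "cellm", surround_material = "surrm")
  sw_sat <- contrast_sweep(cfg_sat, lib_sat, section_grid = 150,
                           coating_grid = seq(2, 60, 2), wavelengths = 470)
  by_coat <- dplyr::arrange(sw_sat, coating_nm)
  expect_true(all(diff(by_coat$contrast) > -1e-12))
  rep_sat <- optimum_report(list(mirror = sw_sat))
  expect_equal(rep_sat$coating_nm, 60)
  expect_equal(rep_sat$section_nm, 150)
  expect_true(rep_sat$at_grid_max)
  expect_lt(rep_sat$coating_nm_fraction, rep_sat$coating_nm)

  # multi-material report: stable (material, wavelength) ordering
  sw_cu <- contrast_sweep(omlit_config(coating = list(material = "copper", thickness_nm = 10)),
                          lib, section_grid = c(40, 60), coating_grid = c(30, 70),
                          wavelengths = c(470, 630))
  sw_ag <- contrast_sweep(cfg, lib, section_grid = c(40, 60),
                          coating_grid = c(30, 70), wavelengths = c(470, 630))
  rep2 <- optimum_report(list(silver = sw_ag, copper = sw_cu))
  expect_equal(rep2$coating_material, c("copper", "copper", "silver", "silver"))
  expect_equal(rep2$wavelength_nm, c(470, 630, 470, 630))
  expect_error(optimum_report(list()), "empty")
})

test_that("period estimation handles clean, noisy, and degenerate traces", {
  x <- seq(0, 500, by = 1)
  clean <- cos(2 * pi * x / 100)
  est <- estimate_period(x, clean)
  expect_lt(abs(est$period_nm - 100), 1 + 1e-9)
  expect_gte(est$n_peaks, 2)

  set.seed(501)
  noisy <- clean + rnorm(length(x), sd = 0.01)
  expect_lt(abs(estimate_period(x, noisy)$period_nm - 100), 2)

  expect_error(estimate_period(x, rep(1, length(x))), "insufficient oscillation")
  expect_error(estimate_period(x[1:80], clean[1:80]), "insufficient oscillation")
})
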