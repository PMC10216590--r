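test_that("normalization is affine-invariant and rejects constant images", {
  set.seed(41)
  img <- matrix(runif(10000), 100, 100)
  img[1:20] <- 0
  img[101:120] <- 1  # >= 0.1% mass at both ends, so the percentiles hit 0 and 1
  norm <- normalize_image(img)
  expect_equal(norm, img, tolerance = 1e-12)

  expect_equal(normalize_image(3.7 * img + 0.4), norm, tolerance = 1e-12)
  expect_equal(normalize_image(img, mode = "minmax"), img, tolerance = 1e-12)
  expect_error(normalize_image(matrix(0.3, 10, 10)), "constant")
})

test_that("ROI pair sampling yields valid, deterministic, well-separated pairs", {
  ph <- roi_test_phantom(seed = 11)
  lm <- slice_phantom(ph, 1000, 5)
  pairs <- sample_roi_pairs(lm, n = 50, roi_size = 11, seed = 4)

  expect_equal(length(unique(pairs$pair_id)), 50)
  cell_mask <- lm$labels >= 2L
  for (p in unique(pairs$pair_id)) {
    cp <- pairs[pairs$pair_id == p & pairs$role == "cell", ]
    sp <- pairs[pairs$pair_id == p & pairs$role == "surround", ]
    # equivalent areas, every pixel in its designated tissue class
    expect_equal(nrow(cp), 121)
    expect_equal(nrow(sp), 121)
    expect_true(all(cell_mask[cbind(cp$y, cp$x)]))
    expect_true(all(lm$labels[cbind(sp$y, sp$x)] == 0L))
    # disjoint regions
    expect_equal(nrow(dplyr::inner_join(cp[, c("x", "y")], sp[, c("x", "y")],
                                        by = c("x", "y"))), 0)
  }
  # cell ROI centres respect the minimum separation
  centres <- pairs |>
    dplyr::filter(role == "cell") |>
    dplyr::summarise(cx = mean(x), cy = mean(y), .by = pair_id)
  dmat <- as.matrix(dist(centres[, c("cx", "cy")]))
  expect_true(all(dmat[upper.tri(dmat)] >= 22))

  expect_identical(sample_roi_pairs(lm, n = 50, seed = 4), pairs)
  expect_false(identical(sample_roi_pairs(lm, n = 50, seed = 5), pairs))
  expect_equal(nrow(sample_roi_pairs(lm, n = 0, seed = 1)), 0)
  expect_error(sample_roi_pairs(lm, n = 5000, seed = 1),
               "insufficient eligible regions")

  # 0-based CSV round trip
  csv <- tempfile(fileext = ".csv")
  write_roi_pairs(pairs, csv)
  back <- read_roi_pairs(csv)
  expect_equal(back$x, pairs$x)
  expect_equal(back$y, pairs$y)
  raw <- utils::read.csv(csv)
  expect_equal(min(raw$x), min(pairs$x) - 1L)
})

test_that("contrast measurement matches constructions and the optical model", {
  ph <- roi_test_phantom(seed = 11)
  lm <- slice_phantom(ph, 1000, 5)
  pairs <- sample_roi_pairs(lm, n = 50, roi_size = 11, seed = 4)

  # uniform image: every pair contrast 1, sd 0
  uni <- measure_contrast(matrix(0.6, 320, 320), pairs)
  expect_equal(uni$mean_contrast, 1)
  expect_equal(uni$sd_contrast, 0)
  expect_equal(uni$n, 50)

  # two-level synthetic image with means 0.8 / 0.2
  two <- matrix(0.8, 320, 320)
  two[lm$labels == 0L] <- 0.2
  est2 <- measure_contrast(two, pairs)
  expect_equal(est2$mean_contrast, 4)
  expect_equal(est2$sd_contrast, 0)
  expect_equal(measure_contrast(two, pairs, mode = "michelson")$mean_contrast, 0.6)

  # rendered noiseless section reproduces the model-predicted contrast
  lib <- omlit_materials()
  cfg <- omlit_config(section_thickness_nm = 1000)
  illum <- illumination(470)
  img <- render_section(lm, cfg, illum, lib)
  est <- measure_contrast(unclass(img), pairs)
  model <- omlit_contrast(cfg, illum, lib)
  expect_equal(est$mean_contrast, model$contrast, tolerance = 1e-9)
  expect_equal(est$sd_contrast, 0, tolerance = 1e-12)

  # ratio contrast is invariant under positive scaling (not offsets);
  # Michelson is invariant under neither scaling-with-offset asymmetry reversed:
  # it tolerates pure scaling too, but offsets shift it
  est_scaled <- measure_contrast(unclass(img) * 2.5, pairs)
  expect_equal(est_scaled$mean_contrast, est$mean_contrast, tolerance = 1e-12)
  est_offset <- measure_contrast(unclass(img) + 0.3, pairs)
  expect_false(isTRUE(all.equal(est_offset$mean_contrast, est$mean_contrast)))
  mich <- measure_contrast(unclass(img), pairs, mode = "michelson")
  mich_scaled <- measure_contrast(unclass(img) * 2.5, pairs, mode = "michelson")
  expect_equal(mich_scaled$mean_contrast, mich$mean_contrast, tolerance = 1e-12)

  expect_error(measure_contrast(matrix(1, 5, 5), pairs), "bounds")
})

test_that("noisy and defect-laden measurements behave statistically as expected", {
  ph <- roi_test_phantom(seed = 11)
  lm <- slice_phantom(ph, 1000, 5)
  pairs <- sample_roi_pairs(lm, n = 50, roi_size = 11, seed = 4)
  lib <- omlit_materials()
  cfg <- omlit_config(section_thickness_nm = 1000)
  illum <- illumination(470)

  clean <- render_section(lm, cfg, illum, lib)
  base <- measure_contrast(unclass(clean), pairs)

  # Gaussian noise: the 50-pair mean stays within 3 standard errors
  noisy <- render_section(lm, cfg, illum, lib, noise_sd = 0.005, seed = 77)
  est_n <- measure_contrast(unclass(noisy), pairs)
  se <- est_n$sd_contrast / sqrt(est_n$n)
  expect_lt(abs(est_n$mean_contrast - base$mean_contrast), 3 * se)

  # scratches crossing ROIs inflate the per-pair spread
  defected <- add_defects(unclass(clean), n_scratches = 12, seed = 13)
  roi_mask <- matrix(FALSE, 320, 320)
  roi_mask[cbind(pairs$y, pairs$x)] <- TRUE
  expect_gt(sum(attr(defected, "defect_mask") & roi_mask), 0)
  est_d <- measure_contrast(defected, pairs)
  expect_gt(est_d$sd_contrast, base$sd_contrast)

  # tidy/glance accessors
  expect_equal(nrow(tidy(base)), 50)
  expect_equal(glance(base)$n, 50)
})
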