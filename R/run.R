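#' Reproducible pipeline runs
#'
#' The `run_*()` functions tie the modules together behind a single YAML
#' configuration and a global seed, writing their outputs (JSON/CSV/TIFF) plus
#' the resolved configuration into an output directory so every run can be
#' reproduced from its own artifacts. The `inst/cli/omlit` script exposes them
#' from a shell. The global seed fans out to per-stage child seeds (documented
#' in [child_seed()]'s source) so stages can be re-run independently.
#'
#' @name run
NULL

.resolve_library <- function(cfg) {
  if (is.null(cfg$materials) || identical(cfg$materials, "bundled")) {
    omlit_materials()
  } else {
    read_material_library(cfg$materials)
  }
}

.resolve_omlit_config <- function(cfg) {
  oc <- cfg$stack %||% list()
  coating <- NULL
  if (!is.null(oc$coating) && !identical(oc$coating, "none")) {
    coating <- list(material = oc$coating$material,
                    thickness_nm = oc$coating$thickness_nm)
  }
  omlit_config(
    section_thickness_nm = oc$section_thickness_nm %||% 60,
    coating = coating,
    tape_material = oc$tape_material %||% "polycarbonate_tape",
    tape_thickness_nm = oc$tape_thickness_nm %||% 50000,
    carbon_tape_thickness_nm = oc$carbon_tape_thickness_nm %||% 100000,
    substrate = oc$substrate %||% "silicon",
    cell_material = oc$cell_material %||% "stained_cell",
    surround_material = oc$surround_material %||% "stained_tissue")
}

.resolve_illumination <- function(cfg, wavelength = NULL) {
  il <- cfg$illumination %||% list()
  illumination(
    wavelength_nm = wavelength %||% il$wavelength_nm %||% 470,
    angle_deg = il$angle_deg %||% 0,
    polarization = il$polarization %||% "unpolarized",
    fwhm_nm = il$fwhm_nm %||% 0,
    na = il$na %||% 0)
}

.prepare_outdir <- function(out_dir, force = FALSE) {
  if (dir.exists(out_dir)) {
    if (!force && length(list.files(out_dir)) > 0) {
      rlang::abort(sprintf(
        "output directory `%s` is not empty; use force = TRUE to overwrite", out_dir))
    }
  } else {
    dir.create(out_dir, recursive = TRUE)
  }
  invisible(out_dir)
}

.write_resolved <- function(cfg, out_dir) {
  yaml::write_yaml(cfg, file.path(out_dir, "resolved_config.yaml"))
}

#' Read a run configuration from YAML
#' @param path YAML file path (see `inst/extdata/example_config.yaml`).
#' @return A named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("config not found: %s", path))
  yaml::read_yaml(path)
}

#' @describeIn run Single-configuration reflectance and contrast; writes
#'   `simulate.json` with `R_cell`, `R_surround` and `contrast`.
#' @param cfg Run configuration list (from [read_run_config()]).
#' @param out_dir Output directory.
#' @param force Overwrite non-empty output directories.
#' @export
run_simulate <- function(cfg, out_dir, force = FALSE) {
  .prepare_outdir(out_dir, force)
  lib <- .resolve_library(cfg)
  config <- .resolve_omlit_config(cfg)
  illum <- .resolve_illumination(cfg)
  res <- omlit_contrast(config, illum, lib, mode = cfg$contrast_mode %||% "ratio")
  payload <- list(schema = "omlitr/simulate/1",
                  wavelength_nm = res$wavelength_nm,
                  section_nm = res$section_nm,
                  coating_material = res$coating_material,
                  coating_nm = res$coating_nm,
                  R_cell = res$R_cell, R_surround = res$R_surround,
                  contrast = res$contrast)
  jsonlite::write_json(payload, file.path(out_dir, "simulate.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  .write_resolved(cfg, out_dir)
  invisible(res)
}

#' @describeIn run Contrast sweep; writes `sweep.csv` (grid), `sweep.json`
#'   (argmax/fraction summary) and the resolved config.
#' @export
run_sweep <- function(cfg, out_dir, force = FALSE) {
  .prepare_outdir(out_dir, force)
  lib <- .resolve_library(cfg)
  config <- .resolve_omlit_config(cfg)
  sw <- cfg$sweep %||% list()
  grids <- list(
    section = if (!is.null(sw$section_nm)) unlist(sw$section_nm) else seq(10, 300, 5),
    coating = if (!is.null(sw$coating_nm)) unlist(sw$coating_nm) else seq(10, 400, 5),
    wavelengths = if (!is.null(sw$wavelengths_nm)) unlist(sw$wavelengths_nm) else
      c(390, 470, 555, 630))
  res <- contrast_sweep(config, lib,
                        section_grid = grids$section,
                        coating_grid = grids$coating,
                        wavelengths = grids$wavelengths,
                        mode = cfg$contrast_mode %||% "ratio",
                        fraction = sw$fraction %||% 0.95)
  write_contrast_csv(res, file.path(out_dir, "sweep.csv"))
  jsonlite::write_json(
    list(schema = "omlitr/sweep/1",
         argmax = as.list(attr(res, "argmax")),
         optimum = attr(res, "optimum")),
    file.path(out_dir, "sweep.json"), auto_unbox = TRUE, digits = NA, na = "null")
  .write_resolved(cfg, out_dir)
  invisible(res)
}

#' @describeIn run Per-material optimum report over the standard coating
#'   metals; writes `report.csv` and `report.txt`.
#' @export
run_report <- function(cfg, out_dir, force = FALSE) {
  .prepare_outdir(out_dir, force)
  lib <- .resolve_library(cfg)
  sw <- cfg$sweep %||% list()
  materials <- unlist(sw$materials %||% c("silver", "chromium", "copper"))
  grids <- list(
    section = if (!is.null(sw$section_nm)) unlist(sw$section_nm) else seq(10, 300, 5),
    coating = if (!is.null(sw$coating_nm)) unlist(sw$coating_nm) else seq(10, 400, 5),
    wavelengths = if (!is.null(sw$wavelengths_nm)) unlist(sw$wavelengths_nm) else
      c(390, 470, 555, 630))
  sweeps <- purrr::map(materials, function(m) {
    cfg_m <- .resolve_omlit_config(cfg)
    cfg_m$coating <- list(material = m, thickness_nm = grids$coating[[1]])
    contrast_sweep(cfg_m, lib, section_grid = grids$section,
                   coating_grid = grids$coating,
                   wavelengths = grids$wavelengths,
                   mode = cfg$contrast_mode %||% "ratio",
                   fraction = sw$fraction %||% 0.95)
  })
  names(sweeps) <- materials
  rep <- optimum_report(sweeps, fraction = sw$fraction %||% 0.95)
  write_contrast_csv(rep, file.path(out_dir, "report.csv"))
  writeLines(utils::capture.output(print(rep)), file.path(out_dir, "report.txt"))
  .write_resolved(cfg, out_dir)
  invisible(rep)
}

#' @describeIn run Phantom generation and section rendering; writes per-section
#'   intensity and label TIFFs plus a `metadata.json` sidecar.
#' @param seed Global seed; fans out to per-stage child seeds.
#' @export
run_render <- function(cfg, out_dir, seed, force = FALSE) {
  .prepare_outdir(out_dir, force)
  lib <- .resolve_library(cfg)
  config <- .resolve_omlit_config(cfg)
  ph_cfg <- cfg$phantom %||% list()
  n_sections <- ph_cfg$n_sections %||% 3
  thickness <- config$section_thickness_nm
  phantom <- generate_phantom(
    dim_vox = unlist(ph_cfg$dim_vox %||% c(192L, 192L, 24L)),
    voxel_size_nm = ph_cfg$voxel_size_nm %||% 500,
    n_somata = ph_cfg$n_somata %||% 25,
    n_vessels = ph_cfg$n_vessels %||% 2,
    processes_per_cell = ph_cfg$processes_per_cell %||% 2,
    seed = child_seed(seed, "phantom"))
  noise <- cfg$noise %||% list()
  defects <- cfg$defects %||% list()
  meta <- list(schema = "omlitr/render/1", seed = seed,
               n_sections = n_sections, section_thickness_nm = thickness)
  for (i in seq_len(n_sections)) {
    lm <- slice_phantom(phantom, thickness, i)
    img <- render_section(lm, config, .resolve_illumination(cfg), lib,
                          noise_sd = noise$gaussian_sd %||% 0,
                          poisson_scale = noise$poisson_scale %||% 0,
                          seed = child_seed(seed, "render") + i)
    if ((defects$n_scratches %||% 0) + (defects$n_cracks %||% 0) +
        (defects$n_specks %||% 0) > 0) {
      img <- add_defects(img,
                         n_scratches = defects$n_scratches %||% 0,
                         n_cracks = defects$n_cracks %||% 0,
                         n_specks = defects$n_specks %||% 0,
                         seed = child_seed(seed, "defects") + i)
    }
    write_section_tiff(img, file.path(out_dir, sprintf("section_%03d.tif", i)))
    write_section_tiff(lm$labels / max(PHANTOM_LABELS),
                       file.path(out_dir, sprintf("labels_%03d.tif", i)))
  }
  meta$label_codes <- as.list(PHANTOM_LABELS)
  jsonlite::write_json(meta, file.path(out_dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  .write_resolved(cfg, out_dir)
  invisible(phantom)
}

#' @describeIn run End-to-end demo: phantom, noiseless render, ROI-pair
#'   measurement, and comparison with the model-predicted contrast; writes
#'   `measure.json` and per-pair CSV.
#' @export
run_measure <- function(cfg, out_dir, seed, force = FALSE) {
  .prepare_outdir(out_dir, force)
  lib <- .resolve_library(cfg)
  config <- .resolve_omlit_config(cfg)
  illum <- .resolve_illumination(cfg)
  ph_cfg <- cfg$phantom %||% list()
  roi_cfg <- cfg$rois %||% list()
  noise <- cfg$noise %||% list()
  phantom <- generate_phantom(
    dim_vox = unlist(ph_cfg$dim_vox %||% c(320L, 320L, 10L)),
    voxel_size_nm = ph_cfg$voxel_size_nm %||% 1000,
    n_somata = ph_cfg$n_somata %||% 60,
    soma_radius_nm = unlist(ph_cfg$soma_radius_nm %||% c(10000, 13000)),
    n_vessels = ph_cfg$n_vessels %||% 2,
    processes_per_cell = ph_cfg$processes_per_cell %||% 0,
    seed = child_seed(seed, "phantom"))
  mid <- ceiling(dim(phantom$labels)[[3]] * phantom$voxel_size_nm /
                   (2 * config$section_thickness_nm))
  lm <- slice_phantom(phantom, config$section_thickness_nm, mid)
  img <- render_section(lm, config, illum, lib,
                        noise_sd = noise$gaussian_sd %||% 0,
                        poisson_scale = noise$poisson_scale %||% 0,
                        seed = child_seed(seed, "render"))
  pairs <- sample_roi_pairs(lm, n = roi_cfg$n_pairs %||% 50,
                            roi_size = roi_cfg$roi_size %||% 11,
                            seed = child_seed(seed, "rois"))
  est <- measure_contrast(img, pairs, mode = cfg$contrast_mode %||% "ratio")
  model <- omlit_contrast(config, illum, lib, mode = cfg$contrast_mode %||% "ratio")
  payload <- list(schema = "omlitr/measure/1",
                  n_pairs = est$n, mean_contrast = est$mean_contrast,
                  sd_contrast = est$sd_contrast,
                  model_contrast = model$contrast,
                  abs_error = abs(est$mean_contrast - model$contrast),
                  seed = seed)
  jsonlite::write_json(payload, file.path(out_dir, "measure.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(as.data.frame(tidy(est)),
                   file.path(out_dir, "pairs.csv"), row.names = FALSE)
  write_roi_pairs(pairs, file.path(out_dir, "rois.csv"))
  write_section_tiff(img, file.path(out_dir, "measured_section.tif"))
  .write_resolved(cfg, out_dir)
  invisible(list(estimate = est, model = model, image = img, pairs = pairs))
}
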