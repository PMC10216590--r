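#' OMLIT stack configuration
#'
#' Describes the imaging stack used in optical multilayer interference
#' tomography: an ultrathin stained section, an optional metal coating, the
#' collection tape, conductive carbon tape, and a silicon wafer substrate,
#' illuminated from air. The cell and surround materials occupy the section
#' layer in the two stacks compared for contrast. Tape and carbon tape default
#' to incoherent (both are far thicker than an LED coherence length); section
#' and coating default to coherent.
#'
#' @param section_thickness_nm Section thickness in nm (default 60, a typical
#'   ultramicrotome setting).
#' @param coating `NULL` for the coating-free scheme, or a
#'   `list(material =, thickness_nm =)` with material one of
#'   `"silver"`, `"chromium"`, `"copper"` (other library ids are permitted).
#' @param tape_material,tape_thickness_nm Collection tape (default 50-micron
#'   polycarbonate).
#' @param carbon_tape_thickness_nm Conductive carbon tape thickness (default
#'   100 um; it is optically opaque, so the exact value is immaterial).
#' @param substrate Substrate material id (default `"silicon"`).
#' @param cell_material,surround_material Section-layer material ids for the
#'   cell body and the surrounding neuropil.
#' @param incident Incident medium (default `"air"`).
#' @param tape_coherence,carbon_coherence Coherence flags for the thick layers.
#' @return An `omlit_config` object.
#' @export
omlit_config <- function(section_thickness_nm = 60,
                         coating = NULL,
                         tape_material = "polycarbonate_tape",
                         tape_thickness_nm = 50000,
                         carbon_tape_thickness_nm = 100000,
                         substrate = "silicon",
                         cell_material = "stained_cell",
                         surround_material = "stained_tissue",
                         incident = "air",
                         tape_coherence = "incoherent",
                         carbon_coherence = "incoherent") {
  check_number(section_thickness_nm, "section_thickness_nm", min = 0)
  check_number(tape_thickness_nm, "tape_thickness_nm", min = 0)
  check_number(carbon_tape_thickness_nm, "carbon_tape_thickness_nm", min = 0)
  if (!is.null(coating)) {
    if (!is.list(coating) || is.null(coating$material) || is.null(coating$thickness_nm)) {
      rlang::abort("`coating` must be NULL or list(material =, thickness_nm =)")
    }
    check_number(coating$thickness_nm, "coating$thickness_nm", min = 0)
  }
  structure(list(
    section_thickness_nm = section_thickness_nm,
    coating = coating,
    tape_material = tape_material,
    tape_thickness_nm = tape_thickness_nm,
    carbon_tape_thickness_nm = carbon_tape_thickness_nm,
    substrate = substrate,
    cell_material = cell_material,
    surround_material = surround_material,
    incident = incident,
    tape_coherence = tape_coherence,
    carbon_coherence = carbon_coherence
  ), class = "omlit_config")
}

#' @export
print.omlit_config <- function(x, ...) {
  coat <- if (is.null(x$coating)) "coating-free" else
    sprintf("%s %g nm", x$coating$material, x$coating$thickness_nm)
  cat(sprintf(
    "<omlit_config> section %g nm (%s vs %s), %s, tape %s %g nm, carbon %g nm, %s\n",
    x$section_thickness_nm, x$cell_material, x$surround_material, coat,
    x$tape_material, x$tape_thickness_nm, x$carbon_tape_thickness_nm, x$substrate))
  invisible(x)
}

#' Build the cell and surround layer stacks for a configuration
#'
#' The two stacks are identical except for the section layer's material.
#' Layer order, top to bottom: section, optional coating, tape, carbon tape,
#' over the substrate; incident medium air.
#'
#' @param config An [omlit_config()].
#' @param section_material Optional override of the section material for both
#'   stacks (used by the phantom renderer).
#' @return Named list with `layer_stack` elements `cell` and `surround`.
#' @export
build_stacks <- function(config, section_material = NULL) {
  stopifnot(inherits(config, "omlit_config"))
  base_layers <- function(section_mat) {
    lays <- list(layer(section_mat, config$section_thickness_nm, "coherent"))
    if (!is.null(config$coating)) {
      lays <- c(lays, list(layer(config$coating$material,
                                 config$coating$thickness_nm, "coherent")))
    }
    lays <- c(lays, list(
      layer(config$tape_material, config$tape_thickness_nm, config$tape_coherence),
      layer("carbon_tape", config$carbon_tape_thickness_nm, config$carbon_coherence)))
    # zero-thickness support layers are optical no-ops; drop them so their
    # materials need not exist in the library
    lays[c(TRUE, vapply(lays[-1], function(l) l$thickness_nm > 0, logical(1)))]
  }
  mk <- function(mat) layer_stack(config$incident, base_layers(mat), config$substrate)
  if (!is.null(section_material)) {
    return(list(cell = mk(section_material), surround = mk(section_material)))
  }
  list(cell = mk(config$cell_material), surround = mk(config$surround_material))
}

.pair_contrast <- function(R_cell, R_surround, mode) {
  hi <- pmax(R_cell, R_surround)
  lo <- pmin(R_cell, R_surround)
  if (mode == "ratio") {
    if (any(lo == 0)) rlang::abort("degenerate contrast: a reflectance is exactly 0")
    hi / lo
  } else {
    if (any(hi + lo == 0)) rlang::abort("degenerate contrast: both reflectances are 0")
    (hi - lo) / (hi + lo)
  }
}

#' Model-predicted cell/surround contrast of one configuration
#'
#' Computes reflectance for the cell and surround stacks via
#' [stack_reflectance()] and returns the contrast. The default contrast is the
#' ratio of the brighter to the darker reflectance (C >= 1, symmetric under
#' swapping the cell and surround roles); Michelson contrast
#' \eqn{(R_{hi} - R_{lo}) / (R_{hi} + R_{lo})} is available as an alternative.
#'
#' @param config An [omlit_config()].
#' @param illum An [illumination()].
#' @param lib A [material_library()].
#' @param mode `"ratio"` (default) or `"michelson"`.
#' @return One-row tibble with `wavelength_nm`, `section_nm`,
#'   `coating_material`, `coating_nm`, `R_cell`, `R_surround`, `contrast`.
#' @examples
#' lib <- omlit_materials()
#' omlit_contrast(omlit_config(section_thickness_nm = 60), illumination(470), lib)
#' @export
omlit_contrast <- function(config, illum, lib, mode = c("ratio", "michelson")) {
  mode <- match.arg(mode)
  stacks <- build_stacks(config)
  R_cell <- stack_reflectance(stacks$cell, illum, lib)$R
  R_surround <- stack_reflectance(stacks$surround, illum, lib)$R
  out <- tibble::tibble(
    wavelength_nm = illum$wavelength_nm,
    section_nm = config$section_thickness_nm,
    coating_material = if (is.null(config$coating)) NA_character_ else
      config$coating$material,
    coating_nm = if (is.null(config$coating)) 0 else config$coating$thickness_nm,
    R_cell = R_cell, R_surround = R_surround,
    contrast = .pair_contrast(R_cell, R_surround, mode))
  attr(out, "config") <- config
  attr(out, "illumination") <- illum
  attr(out, "mode") <- mode
  class(out) <- c("omlit_contrast", class(out))
  out
}

# expand a per-axis vector into a full array varying along dimension `dimidx`
.expand_dim <- function(v, dimidx, dims) {
  array(rep(v, each = prod(dims[seq_len(dimidx - 1L)])), dim = dims)
}

# Vectorized reflectance grid over (section thickness x coating thickness) at
# one wavelength, normal-or-oblique incidence, one polarization. Same
# characteristic-matrix arithmetic and phase sampling as .reflect_once, with
# the section and coating phase thicknesses broadcast over the grid.
.reflectance_grid <- function(config, section_material, section_grid,
                              coating_grid, wavelength_nm, lib,
                              theta0_rad, pol) {
  has_coating <- !is.null(config$coating)
  has_tape <- config$tape_thickness_nm > 0
  has_carbon <- config$carbon_tape_thickness_nm > 0
  mats <- c(section_material,
            if (has_coating) config$coating$material,
            if (has_tape) config$tape_material,
            if (has_carbon) "carbon_tape")
  d_fixed <- c(NA, if (has_coating) NA,
               if (has_tape) config$tape_thickness_nm,
               if (has_carbon) config$carbon_tape_thickness_nm)
  coh <- c("coherent", if (has_coating) "coherent",
           if (has_tape) config$tape_coherence,
           if (has_carbon) config$carbon_coherence)
  n_inc <- complex_index(lib, config$incident, wavelength_nm)
  if (abs(Im(n_inc)) > 1e-12) rlang::abort("incident medium must be lossless")
  n_lay <- vapply(mats, function(m) complex_index(lib, m, wavelength_nm),
                  complex(1), USE.NAMES = FALSE)
  n_sub <- complex_index(lib, config$substrate, wavelength_nm)
  s0 <- Re(n_inc) * sin(theta0_rad)
  cs <- .cos_in_medium(n_lay, s0)
  cs_sub <- .cos_in_medium(n_sub, s0)

  # opacity truncation on fixed-thickness layers
  kfix <- which(!is.na(d_fixed))
  im2 <- 2 * (2 * pi * Im(n_lay[kfix] * cs[kfix]) * d_fixed[kfix] / wavelength_nm)
  opaque <- kfix[im2 > .OPAQUE_2IM]
  if (length(opaque) > 0) {
    jcut <- opaque[[1]]
    n_sub <- n_lay[[jcut]]
    cs_sub <- cs[[jcut]]
    keep <- seq_len(jcut - 1L)
    mats <- mats[keep]; d_fixed <- d_fixed[keep]; coh <- coh[keep]
    n_lay <- n_lay[keep]; cs <- cs[keep]
  }

  ns <- length(section_grid)
  nc <- if (has_coating) length(coating_grid) else 1L
  incoh <- which(coh == "incoherent" & !is.na(d_fixed) & d_fixed > 0)
  dims <- c(ns, nc, rep(.N_PHASE, length(incoh)))
  # conjugated phase, matching the matrix formalism's time convention
  phase_of <- function(j, d)
    .cap_delta(Conj(2 * pi * n_lay[[j]] * d * cs[[j]] / wavelength_nm))

  deltas <- vector("list", length(mats))
  deltas[[1]] <- .expand_dim(phase_of(1L, section_grid), 1L, dims)
  nextdim <- 3L
  for (j in seq_along(mats)[-1]) {
    if (has_coating && j == 2L) {
      deltas[[j]] <- .expand_dim(phase_of(2L, coating_grid), 2L, dims)
    } else if (j %in% incoh) {
      phi <- pi * (seq_len(.N_PHASE) - 0.5) / .N_PHASE
      deltas[[j]] <- .expand_dim(phase_of(j, d_fixed[[j]]) + phi, nextdim, dims)
      nextdim <- nextdim + 1L
    } else {
      deltas[[j]] <- phase_of(j, d_fixed[[j]])
    }
  }
  eta0 <- Re(.eta_of(n_inc, cos(theta0_rad) + 0i, pol))
  eta_sub <- Conj(.eta_of(n_sub, cs_sub, pol))
  etas <- as.list(Conj(.eta_of(n_lay, cs, pol)))
  bc <- .chain_bc(deltas, etas, eta_sub)
  r <- (eta0 * bc$B - bc$C) / (eta0 * bc$B + bc$C)
  R <- Mod(r)^2
  if (length(incoh) > 0) {
    R <- rowMeans(matrix(R, nrow = ns * nc))
  }
  matrix(R, nrow = ns, ncol = nc)
}

#' Contrast sweep over section thickness, coating thickness and wavelength
#'
#' Evaluates the cell/surround contrast on a dense grid, the computational
#' counterpart of a coating-design heatmap. The default grids cover section
#' thicknesses 10-300 nm and coating thicknesses 10-400 nm in 5 nm steps at
#' the four LED lines 390/470/555/630 nm.
#'
#' @param config An [omlit_config()] used as template; its section and coating
#'   thicknesses are replaced by the grid values.
#' @param lib A [material_library()].
#' @param section_grid,coating_grid Sorted, non-empty thickness grids in nm
#'   (`coating_grid` is ignored for a coating-free config).
#' @param wavelengths Wavelength set in nm.
#' @param angle_deg,polarization Illumination geometry (strictly monochromatic,
#'   single angle; spectral/NA averaging is not applied inside sweeps).
#' @param mode Contrast definition, as in [omlit_contrast()].
#' @param fraction Fraction for the reduced-thickness annotation: per
#'   wavelength, the smallest grid coating thickness whose best-over-section
#'   contrast reaches `fraction` of that wavelength's optimum (default 0.95).
#' @return An `omlit_sweep` tibble with columns `wavelength_nm`, `section_nm`,
#'   `coating_nm`, `R_cell`, `R_surround`, `contrast`, carrying the
#'   per-wavelength optimum table and the overall argmax as attributes
#'   (`optimum`, `argmax`).
#' @export
contrast_sweep <- function(config, lib,
                           section_grid = seq(10, 300, by = 5),
                           coating_grid = seq(10, 400, by = 5),
                           wavelengths = c(390, 470, 555, 630),
                           angle_deg = 0,
                           polarization = c("unpolarized", "s", "p"),
                           mode = c("ratio", "michelson"),
                           fraction = 0.95) {
  polarization <- match.arg(polarization)
  mode <- match.arg(mode)
  stopifnot(inherits(config, "omlit_config"))
  for (g in list(section_grid, wavelengths)) {
    if (length(g) == 0 || is.unsorted(g, strictly = TRUE)) {
      rlang::abort("grids must be non-empty and strictly increasing")
    }
  }
  has_coating <- !is.null(config$coating)
  if (has_coating &&
      (length(coating_grid) == 0 || is.unsorted(coating_grid, strictly = TRUE))) {
    rlang::abort("grids must be non-empty and strictly increasing")
  }
  th <- deg2rad(angle_deg)
  pols <- if (polarization == "unpolarized") {
    if (angle_deg == 0) "s" else c("s", "p")
  } else polarization

  grid_R <- function(material, wl) {
    acc <- 0
    for (p in pols) {
      acc <- acc + .reflectance_grid(config, material, section_grid,
                                     coating_grid, wl, lib, th, p)
    }
    acc / length(pols)
  }
  coat_vals <- if (has_coating) coating_grid else 0
  res <- purrr::map_dfr(wavelengths, function(wl) {
    Rc <- grid_R(config$cell_material, wl)
    Rs <- grid_R(config$surround_material, wl)
    tibble::tibble(
      wavelength_nm = wl,
      section_nm = rep(section_grid, times = length(coat_vals)),
      coating_nm = rep(coat_vals, each = length(section_grid)),
      R_cell = as.vector(Rc),
      R_surround = as.vector(Rs),
      contrast = as.vector(.pair_contrast(Rc, Rs, mode)))
  })
  optimum <- res |>
    dplyr::group_by(.data$wavelength_nm) |>
    dplyr::group_modify(function(df, key) {
      best <- df |>
        dplyr::arrange(dplyr::desc(.data$contrast), .data$section_nm,
                       .data$coating_nm) |>
        dplyr::slice(1)
      by_coat <- df |>
        dplyr::summarise(best_c = max(.data$contrast), .by = "coating_nm") |>
        dplyr::arrange(.data$coating_nm)
      frac_nm <- by_coat$coating_nm[by_coat$best_c >= fraction * best$contrast][1]
      tibble::tibble(best_contrast = best$contrast,
                     section_nm = best$section_nm,
                     coating_nm = best$coating_nm,
                     fraction_thickness_nm = frac_nm)
    }) |>
    dplyr::ungroup()
  argmax <- optimum |>
    dplyr::arrange(dplyr::desc(.data$best_contrast)) |>
    dplyr::slice(1)
  attr(res, "optimum") <- optimum
  attr(res, "argmax") <- argmax
  attr(res, "fraction") <- fraction
  attr(res, "mode") <- mode
  attr(res, "config") <- config
  attr(res, "coating_material") <- if (has_coating) config$coating$material else NA_character_
  class(res) <- c("omlit_sweep", class(res))
  res
}

#' Per-material optimum report
#'
#' Summarises one sweep per coating material into a table with one row per
#' (material, wavelength): the best contrast, the section and coating
#' thicknesses attaining it, and the smallest coating thickness reaching
#' `fraction` of the row optimum (the parenthetical reduced-thickness
#' convention used when an optimum sits at the top of the coating grid).
#'
#' @param sweeps A named list of `omlit_sweep` objects (name = coating
#'   material), or a single sweep.
#' @param fraction Fraction of the row optimum for the reduced thickness
#'   (default 0.95).
#' @return An `omlit_report` tibble sorted by material then wavelength, with
#'   columns `coating_material`, `wavelength_nm`, `best_contrast`,
#'   `section_nm`, `coating_nm`, `coating_nm_fraction`, `at_grid_max`.
#' @export
optimum_report <- function(sweeps, fraction = 0.95) {
  if (inherits(sweeps, "omlit_sweep")) sweeps <- list(sweeps)
  if (length(sweeps) == 0) rlang::abort("empty sweep list")
  nm <- names(sweeps)
  rows <- purrr::imap_dfr(sweeps, function(sw, id) {
    if (nrow(sw) == 0) rlang::abort("empty sweep")
    mat <- if (is.character(id) && nzchar(id)) id else
      attr(sw, "coating_material")
    grid_max <- max(sw$coating_nm)
    sw |>
      dplyr::group_by(.data$wavelength_nm) |>
      dplyr::group_modify(function(df, key) {
        best <- df |>
          dplyr::arrange(dplyr::desc(.data$contrast), .data$section_nm,
                         .data$coating_nm) |>
          dplyr::slice(1)
        by_coat <- df |>
          dplyr::summarise(best_c = max(.data$contrast), .by = "coating_nm") |>
          dplyr::arrange(.data$coating_nm)
        frac_nm <- by_coat$coating_nm[by_coat$best_c >= fraction * best$contrast][1]
        tibble::tibble(
          coating_material = mat,
          best_contrast = best$contrast,
          section_nm = best$section_nm,
          coating_nm = best$coating_nm,
          coating_nm_fraction = frac_nm,
          at_grid_max = best$coating_nm == grid_max)
      }) |>
      dplyr::ungroup() |>
      dplyr::relocate("coating_material")
  })
  out <- dplyr::arrange(rows, .data$coating_material, .data$wavelength_nm)
  attr(out, "fraction") <- fraction
  class(out) <- c("omlit_report", class(out))
  out
}

#' @export
print.omlit_report <- function(x, ...) {
  cat(sprintf("Optimal contrast by coating material (reduced thickness at %.0f%% of optimum)\n",
              100 * attr(x, "fraction")))
  cat(sprintf("%-12s %13s %11s %11s %15s\n", "Material", "Best contrast",
              "Wavelength", "Section", "Coating"))
  for (i in seq_len(nrow(x))) {
    coat <- if (x$at_grid_max[i] && x$coating_nm_fraction[i] < x$coating_nm[i]) {
      sprintf("%g (%g) *", x$coating_nm[i], x$coating_nm_fraction[i])
    } else sprintf("%g", x$coating_nm[i])
    cat(sprintf("%-12s %13.4f %11g %11g %15s\n", x$coating_material[i],
                x$best_contrast[i], x$wavelength_nm[i], x$section_nm[i], coat))
  }
  cat("* optimum at the top of the coating grid; reduced thickness in parentheses\n")
  invisible(x)
}

#' Write a sweep or report to CSV
#' @param x An `omlit_sweep` or `omlit_report`.
#' @param path Destination CSV path.
#' @return `path`, invisibly.
#' @export
write_contrast_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Dominant fluctuation period of a contrast-versus-thickness trace
#'
#' Contrast versus section thickness oscillates with period
#' \eqn{\lambda / (2 n_{section})} at normal incidence (the thin-film
#' interference mechanism that makes the fluctuation period proportional to
#' the illumination wavelength). The period is estimated from the mean spacing
#' of trace peaks; peaks are located between successive rising crossings of a
#' hysteresis band (40%/60% of the trace range), which is robust to small
#' amounts of noise.
#'
#' @param thickness_nm Sorted thickness samples (nm).
#' @param values Trace values at `thickness_nm` (e.g. contrast).
#' @return List with `period_nm`, `peak_positions_nm`, `n_peaks`.
#' @export
estimate_period <- function(thickness_nm, values) {
  stopifnot(length(thickness_nm) == length(values), length(values) >= 4)
  rng <- max(values) - min(values)
  if (rng < 1e-12) {
    rlang::abort("insufficient oscillation: trace is constant")
  }
  lo <- min(values) + 0.4 * rng
  hi <- min(values) + 0.6 * rng
  events <- integer(0)
  armed <- values[[1]] < lo
  for (i in seq_along(values)) {
    if (!armed && values[[i]] < lo) armed <- TRUE
    if (armed && values[[i]] >= hi) {
      events <- c(events, i)
      armed <- FALSE
    }
  }
  # one peak per completed oscillation: argmax between successive rising
  # events; the stretch after the last event counts only if the trace falls
  # back below the band (a completed peak)
  peaks <- integer(0)
  if (length(events) >= 1) {
    bounds <- c(events, length(values) + 1L)
    for (e in seq_along(events)) {
      seg <- seq(bounds[[e]], bounds[[e + 1L]] - 1L)
      if (e == length(events) && !any(values[seg] < lo)) next
      peaks <- c(peaks, seg[[which.max(values[seg])]])
    }
  }
  if (length(peaks) < 2) {
    rlang::abort("insufficient oscillation: fewer than 2 complete peaks in trace")
  }
  pos <- thickness_nm[peaks]
  list(period_nm = mean(diff(pos)), peak_positions_nm = pos,
       n_peaks = length(peaks))
}
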