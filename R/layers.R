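#' Layers, stacks and illumination
#'
#' A `layer_stack` describes a planar multilayer as a semi-infinite incident
#' medium, an ordered top-to-bottom tibble of finite layers, and a semi-infinite
#' substrate. Each layer carries a coherence flag: `"coherent"` layers keep
#' optical phase (thin films), `"incoherent"` layers are thicker than the source
#' coherence length and are combined by intensity (phase-averaged).
#'
#' @name layer_stack
NULL

#' @param material Material id (must exist in the library used at evaluation).
#' @param thickness_nm Layer thickness in nm, finite and >= 0.
#' @param coherence `"coherent"` or `"incoherent"`.
#' @return `layer()` returns a one-row tibble.
#' @rdname layer_stack
#' @export
layer <- function(material, thickness_nm, coherence = c("coherent", "incoherent")) {
  coherence <- match.arg(coherence)
  check_number(thickness_nm, "thickness_nm", min = 0)
  tibble::tibble(material = as.character(material),
                 thickness_nm = as.numeric(thickness_nm),
                 coherence = coherence)
}

#' @param incident Material id of the semi-infinite incident medium. Must be
#'   lossless (k = 0) at the evaluation wavelength.
#' @param layers A list of [layer()] rows (or a tibble with the same columns),
#'   ordered top to bottom. May be empty.
#' @param substrate Material id of the semi-infinite exit medium; may be
#'   absorbing (e.g. silicon in the visible), in which case the transmitted
#'   wave's power is reported as absorptance.
#' @rdname layer_stack
#' @export
layer_stack <- function(incident = "air", layers = list(), substrate) {
  if (is.data.frame(layers)) {
    lay <- tibble::as_tibble(layers)
  } else {
    lay <- if (length(layers) == 0) layer("air", 0)[0, ] else dplyr::bind_rows(layers)
  }
  stopifnot(all(c("material", "thickness_nm", "coherence") %in% names(lay)))
  if (any(!is.finite(lay$thickness_nm)) || any(lay$thickness_nm < 0)) {
    rlang::abort("all layer thicknesses must be finite and >= 0")
  }
  if (!all(lay$coherence %in% c("coherent", "incoherent"))) {
    rlang::abort("layer coherence must be 'coherent' or 'incoherent'")
  }
  structure(list(incident = as.character(incident),
                 layers = lay,
                 substrate = as.character(substrate)),
            class = "layer_stack")
}

#' @export
print.layer_stack <- function(x, ...) {
  cat(sprintf("<layer_stack> %s | %d layer(s) | %s\n",
              x$incident, nrow(x$layers), x$substrate))
  if (nrow(x$layers) > 0) {
    cat(paste(sprintf("  %-22s %10.1f nm  %s", x$layers$material,
                      x$layers$thickness_nm, x$layers$coherence),
              collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Monochromatic (or narrow-band) illumination
#'
#' @param wavelength_nm Centre wavelength in nm.
#' @param angle_deg Angle of incidence in degrees, in \[0, 90).
#' @param polarization `"unpolarized"` (default), `"s"` or `"p"`. Unpolarized
#'   reflectance is the mean of the s and p results.
#' @param fwhm_nm Spectral full width at half maximum in nm; 0 means strictly
#'   monochromatic. When > 0, results are Gaussian-averaged over wavelength.
#' @param na Illumination numerical aperture in \[0, 1); 0 means a single
#'   incidence angle. When > 0, results are averaged over the illumination cone.
#' @return An `illumination` object.
#' @export
illumination <- function(wavelength_nm, angle_deg = 0,
                         polarization = c("unpolarized", "s", "p"),
                         fwhm_nm = 0, na = 0) {
  polarization <- match.arg(polarization)
  check_number(wavelength_nm, "wavelength_nm", min = 1e-6)
  check_number(angle_deg, "angle_deg", min = 0, max = 90 - 1e-9)
  check_number(fwhm_nm, "fwhm_nm", min = 0)
  if (!is.numeric(na) || length(na) != 1L || na < 0 || na >= 1) {
    rlang::abort("`na` must be in [0, 1)")
  }
  structure(list(wavelength_nm = wavelength_nm, angle_deg = angle_deg,
                 polarization = polarization, fwhm_nm = fwhm_nm, na = na),
            class = "illumination")
}

#' @export
print.illumination <- function(x, ...) {
  cat(sprintf("<illumination> %g nm, %g deg, %s, fwhm %g nm, NA %g\n",
              x$wavelength_nm, x$angle_deg, x$polarization, x$fwhm_nm, x$na))
  invisible(x)
}

#' Read a stack + illumination description from YAML
#'
#' Expected schema: an `incident:` material (default `"air"`), an ordered
#' `layers:` list with `material`, `thickness_nm` and optional `coherence`, a
#' `substrate:` material, and an `illumination:` block with `wavelength_nm` and
#' optional `angle_deg`, `polarization`, `fwhm_nm`, `na`.
#'
#' @param path YAML file path.
#' @return A list with elements `stack` and `illumination`.
#' @export
read_stack_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$layers) || is.null(cfg$substrate)) {
    rlang::abort(sprintf("%s: YAML must contain `layers:` and `substrate:`", path))
  }
  lay <- purrr::map(cfg$layers, function(l) {
    layer(l$material, l$thickness_nm,
          coherence = l$coherence %||% "coherent")
  })
  ill <- cfg$illumination %||% list()
  if (is.null(ill$wavelength_nm)) {
    rlang::abort(sprintf("%s: `illumination:` must contain `wavelength_nm`", path))
  }
  list(
    stack = layer_stack(incident = cfg$incident %||% "air",
                        layers = lay, substrate = cfg$substrate),
    illumination = illumination(
      wavelength_nm = ill$wavelength_nm,
      angle_deg = ill$angle_deg %||% 0,
      polarization = ill$polarization %||% "unpolarized",
      fwhm_nm = ill$fwhm_nm %||% 0,
      na = ill$na %||% 0)
  )
}
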