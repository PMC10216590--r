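#' Material dispersion libraries
#'
#' A material library is a tibble with columns `material_id`, `wavelength_nm`,
#' `n` (refractive index) and `k` (extinction coefficient), one row per sampled
#' wavelength, carrying per-material provenance notes as an attribute. The sign
#' convention is fixed package-wide: the complex refractive index is
#' \eqn{\tilde n = n + i k} with absorption meaning \eqn{k > 0}.
#'
#' @param samples Data frame with columns `material_id`, `wavelength_nm`, `n`, `k`.
#' @param provenance Optional named character vector of free-text source notes,
#'   one per material id.
#' @return A `material_library` tibble, sorted by material then wavelength.
#' @examples
#' lib <- material_library(tibble::tibble(
#'   material_id = "glass", wavelength_nm = c(400, 600), n = c(1.53, 1.51), k = 0
#' ))
#' complex_index(lib, "glass", 500)
#' @export
material_library <- function(samples, provenance = NULL) {
  required <- c("material_id", "wavelength_nm", "n", "k")
  missing <- setdiff(required, names(samples))
  if (length(missing) > 0) {
    rlang::abort(paste0("material library is missing column(s): ",
                        paste(missing, collapse = ", ")))
  }
  lib <- tibble::as_tibble(samples)[required]
  if (nrow(lib) == 0) rlang::abort("material library must contain at least one sample")
  lib$material_id <- as.character(lib$material_id)
  for (col in c("wavelength_nm", "n", "k")) {
    if (!is.numeric(lib[[col]]) || anyNA(lib[[col]]) || any(!is.finite(lib[[col]]))) {
      rlang::abort(sprintf("column `%s` must be finite numeric", col))
    }
    lib[[col]] <- as.double(lib[[col]])
  }
  if (any(lib$n <= 0)) rlang::abort("refractive index n must be > 0 for every sample")
  if (any(lib$k < 0)) rlang::abort("extinction coefficient k must be >= 0 for every sample")
  lib <- dplyr::arrange(lib, .data$material_id, .data$wavelength_nm)
  dup <- lib |>
    dplyr::summarise(n_rows = dplyr::n(),
                     .by = c("material_id", "wavelength_nm")) |>
    dplyr::filter(.data$n_rows > 1)
  if (nrow(dup) > 0) {
    rlang::abort(sprintf(
      "duplicated (material, wavelength) sample(s): %s",
      paste(sprintf("%s @ %g nm", dup$material_id, dup$wavelength_nm), collapse = "; ")))
  }
  # per-material strictly increasing wavelengths is implied by sort + no dups
  if (!is.null(provenance)) {
    if (is.null(names(provenance))) {
      rlang::abort("`provenance` must be a named character vector (material_id -> note)")
    }
    provenance <- provenance[names(provenance) %in% unique(lib$material_id)]
  }
  attr(lib, "provenance") <- provenance
  class(lib) <- c("material_library", class(tibble::tibble()))
  lib
}

#' @export
print.material_library <- function(x, ...) {
  mats <- unique(x$material_id)
  cat(sprintf("<material_library> %d material(s), %d samples\n",
              length(mats), nrow(x)))
  NextMethod()
}

#' Bundled default material library
#'
#' Dispersion data at the four LED lines (390, 470, 555, 630 nm) for every
#' material in the OMLIT stack: metals (Ag, Cr, Cu) and silicon from standard
#' published tabulations; polycarbonate from a Sellmeier fit; stained tissue,
#' stained cell, poststained variants, carbon tape and bare resin as documented
#' synthetic placeholders (the exact constants of heavy-metal-stained sections
#' are not published; see `material_provenance()`). All entries can be
#' overridden by loading a user library with [read_material_library()].
#'
#' @return A `material_library` tibble.
#' @export
omlit_materials <- function() {
  path <- system.file("extdata", "materials_default.csv", package = "omlitr")
  prov_path <- system.file("extdata", "materials_provenance.csv", package = "omlitr")
  lib <- read_material_library(path)
  prov <- utils::read.csv(prov_path, stringsAsFactors = FALSE)
  attr(lib, "provenance") <- stats::setNames(prov$provenance, prov$material_id)
  lib
}

#' Provenance notes of a material library
#' @param lib A `material_library`.
#' @return Named character vector of source notes (possibly `NULL`).
#' @export
material_provenance <- function(lib) attr(lib, "provenance")

#' Read a material library from CSV or JSON
#'
#' The CSV dialect is `material_id,wavelength_nm,n,k` (UTF-8, `.` decimal
#' separator); the JSON mirror is an array of objects with the same fields.
#' Parse errors name the offending line.
#'
#' @param path File path ending in `.csv` or `.json`.
#' @return A `material_library` tibble.
#' @export
read_material_library <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    recs <- jsonlite::fromJSON(path)
    return(material_library(tibble::as_tibble(recs)))
  }
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) rlang::abort(sprintf("%s: no data rows", path))
  header <- trimws(strsplit(lines[[1]], ",", fixed = TRUE)[[1]])
  expected <- c("material_id", "wavelength_nm", "n", "k")
  if (!identical(header, expected)) {
    rlang::abort(sprintf("%s line 1: header must be `%s`",
                         path, paste(expected, collapse = ",")))
  }
  parse_row <- function(i) {
    fields <- trimws(strsplit(lines[[i]], ",", fixed = TRUE)[[1]])
    if (length(fields) != 4) {
      rlang::abort(sprintf("%s line %d: expected 4 comma-separated fields, got %d",
                           path, i, length(fields)))
    }
    nums <- suppressWarnings(as.numeric(fields[2:4]))
    if (anyNA(nums)) {
      rlang::abort(sprintf("%s line %d: non-numeric value in wavelength_nm/n/k", path, i))
    }
    tibble::tibble(material_id = fields[[1]], wavelength_nm = nums[[1]],
                   n = nums[[2]], k = nums[[3]])
  }
  samples <- purrr::map_dfr(seq(2, length(lines)), parse_row)
  material_library(samples)
}

#' Write a material library to CSV or JSON
#'
#' Values are written at full double precision so that
#' `read_material_library(write_material_library(lib, p))` round-trips the
#' samples bit-for-bit.
#'
#' @param lib A `material_library`.
#' @param path Destination path ending in `.csv` or `.json`.
#' @return `path`, invisibly.
#' @export
write_material_library <- function(lib, path) {
  stopifnot(inherits(lib, "material_library"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(as.data.frame(lib), path, digits = NA, auto_unbox = TRUE)
  } else {
    num <- function(x) sprintf("%.17g", x)
    rows <- sprintf("%s,%s,%s,%s", lib$material_id, num(lib$wavelength_nm),
                    num(lib$n), num(lib$k))
    writeLines(c("material_id,wavelength_nm,n,k", rows), path, useBytes = TRUE)
  }
  invisible(path)
}

#' Complex refractive index of a material at a wavelength
#'
#' Returns \eqn{\tilde n = n + i k} at the queried wavelength(s). At a tabulated
#' wavelength the stored sample is returned exactly; between samples `n` and `k`
#' are each interpolated linearly in wavelength. Extrapolation outside a
#' material's sampled range is an error.
#'
#' @param lib A `material_library`.
#' @param material Material id.
#' @param wavelength_nm Numeric vector of query wavelengths (nm).
#' @return Complex vector, same length as `wavelength_nm`.
#' @examples
#' complex_index(omlit_materials(), "silver", 470)
#' @export
complex_index <- function(lib, material, wavelength_nm) {
  stopifnot(inherits(lib, "material_library"), length(material) == 1L)
  rows <- lib[lib$material_id == material, , drop = FALSE]
  if (nrow(rows) == 0) {
    rlang::abort(sprintf("unknown material id: `%s`", material))
  }
  wl <- rows$wavelength_nm
  if (any(wavelength_nm < wl[[1]] - 1e-9) || any(wavelength_nm > wl[[length(wl)]] + 1e-9)) {
    rlang::abort(sprintf(
      "wavelength outside sampled range for `%s` (%g-%g nm); extrapolation is not allowed",
      material, wl[[1]], wl[[length(wl)]]))
  }
  if (length(wl) == 1L) {
    return(complex(real = rep(rows$n, length(wavelength_nm)),
                   imaginary = rep(rows$k, length(wavelength_nm))))
  }
  n <- stats::approx(wl, rows$n, xout = wavelength_nm, rule = 1)$y
  k <- stats::approx(wl, rows$k, xout = wavelength_nm, rule = 1)$y
  complex(real = n, imaginary = pmax(k, 0))
}
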