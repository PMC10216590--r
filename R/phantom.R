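#' Synthetic tissue phantoms
#'
#' A `tissue_phantom` is a seeded 3D label volume emulating the content of a
#' resin-embedded cortex block at light-microscope scale: somata with nuclei
#' and nucleoli, non-branching vessels, and random-walk neurite processes in a
#' neuropil background. Labels (integer codes): neuropil = 0, vessel_lumen = 1,
#' cytoplasm = 2, nucleus = 3, nucleolus = 4. Regeneration from the same seed
#' and parameters is bit-identical.
#'
#' @name phantom
NULL

PHANTOM_LABELS <- c(neuropil = 0L, vessel_lumen = 1L, cytoplasm = 2L,
                    nucleus = 3L, nucleolus = 4L)

# stamp a ball of `code` into integer volume `vol` (dims nx, ny, nz)
.stamp_ball <- function(vol, center, radius, code) {
  dm <- dim(vol)
  lo <- pmax(ceiling(center - radius), 1L)
  hi <- pmin(floor(center + radius), dm)
  if (any(lo > hi)) return(vol)
  xr <- seq(lo[[1]], hi[[1]]); yr <- seq(lo[[2]], hi[[2]]); zr <- seq(lo[[3]], hi[[3]])
  dx2 <- (xr - center[[1]])^2
  dy2 <- (yr - center[[2]])^2
  dz2 <- (zr - center[[3]])^2
  mask <- outer(outer(dx2, dy2, "+"), dz2, "+") <= radius^2
  sub <- vol[xr, yr, zr, drop = FALSE]
  sub[mask] <- code
  vol[xr, yr, zr] <- sub
  vol
}

.stamp_tube <- function(vol, from, to, radius, code) {
  len <- sqrt(sum((to - from)^2))
  nstep <- max(2L, ceiling(len / (radius / 2)))
  for (t in seq(0, 1, length.out = nstep)) {
    vol <- .stamp_ball(vol, from + t * (to - from), radius, code)
  }
  vol
}

#' Generate a seeded 3D tissue phantom
#'
#' Somata are placed by rejection sampling without overlap (centres are kept
#' at least the sum of radii plus one voxel apart; full soma cross-sections in
#' XY, clipping allowed along z as in a thin imaged slab). Each soma contains a
#' concentric nucleus with 1-3 nucleoli; vessels are straight tubes crossing
#' the volume; processes are persistent-direction random-walk tubes leaving
#' the somata. Structures are stamped in the order vessels, cytoplasm,
#' processes, nuclei, nucleoli, so deeper structures take precedence.
#'
#' @param dim_vox Volume size in voxels, length-3 integer (x, y, z).
#' @param voxel_size_nm Voxel edge length in nm (isotropic).
#' @param n_somata Number of somata to place (equivalently a density times the
#'   volume; 0 gives a pure neuropil volume).
#' @param soma_radius_nm Length-2 range of soma radii (nm).
#' @param nucleus_fraction Nucleus radius as a fraction of its soma radius.
#' @param nucleolus_fraction Nucleolus radius as a fraction of the soma radius.
#' @param n_nucleoli_range Length-2 integer range; each nucleus receives a
#'   uniform draw from this range.
#' @param n_vessels Number of vessels.
#' @param vessel_radius_nm Length-2 range of vessel radii (nm).
#' @param processes_per_cell Random-walk processes leaving each soma.
#' @param process_radius_nm Process tube radius (nm).
#' @param seed Integer seed (required; determinism is part of the contract).
#' @param max_attempts_per_soma Rejection budget per soma.
#' @return A `tissue_phantom`: list with `labels` (integer 3D array),
#'   `voxel_size_nm`, `seed` and the full parameter snapshot.
#' @export
generate_phantom <- function(dim_vox = c(192L, 192L, 24L),
                             voxel_size_nm = 500,
                             n_somata = 25,
                             soma_radius_nm = c(2500, 7000),
                             nucleus_fraction = 0.6,
                             nucleolus_fraction = 0.12,
                             n_nucleoli_range = c(1L, 3L),
                             n_vessels = 2,
                             vessel_radius_nm = c(1500, 3000),
                             processes_per_cell = 2,
                             process_radius_nm = 600,
                             seed,
                             max_attempts_per_soma = 1000L) {
  stopifnot(length(dim_vox) == 3, all(dim_vox >= 1))
  check_number(voxel_size_nm, "voxel_size_nm", min = 1e-6)
  if (missing(seed)) rlang::abort("`seed` is required for reproducible phantoms")
  params <- list(dim_vox = as.integer(dim_vox), voxel_size_nm = voxel_size_nm,
                 n_somata = n_somata, soma_radius_nm = soma_radius_nm,
                 nucleus_fraction = nucleus_fraction,
                 nucleolus_fraction = nucleolus_fraction,
                 n_nucleoli_range = as.integer(n_nucleoli_range),
                 n_vessels = n_vessels, vessel_radius_nm = vessel_radius_nm,
                 processes_per_cell = processes_per_cell,
                 process_radius_nm = process_radius_nm,
                 max_attempts_per_soma = as.integer(max_attempts_per_soma))
  r_vox <- soma_radius_nm / voxel_size_nm
  if (2 * r_vox[[2]] > min(dim_vox[1:2])) {
    rlang::abort("soma diameter exceeds the XY extent of the volume")
  }
  vol <- with_seed(seed, {
    vol <- array(PHANTOM_LABELS[["neuropil"]], dim = dim_vox)
    dm <- dim_vox

    # vessels: straight tubes entering one face and exiting the opposite face
    for (v in seq_len(n_vessels)) {
      ax <- sample(1:2, 1)  # cross the volume in x or y
      rad <- stats::runif(1, vessel_radius_nm[[1]], vessel_radius_nm[[2]]) / voxel_size_nm
      from <- c(stats::runif(1, 1, dm[[1]]), stats::runif(1, 1, dm[[2]]),
                stats::runif(1, 1, dm[[3]]))
      to <- from + stats::rnorm(3, sd = dm / 8)
      from[[ax]] <- 1; to[[ax]] <- dm[[ax]]
      vol <- .stamp_tube(vol, from, to, rad, PHANTOM_LABELS[["vessel_lumen"]])
    }

    # somata by rejection sampling: disjoint spheres, full footprint in XY
    centers <- matrix(numeric(0), ncol = 3)
    radii <- numeric(0)
    attempts <- 0L
    budget <- max_attempts_per_soma * max(1L, n_somata)
    while (length(radii) < n_somata) {
      attempts <- attempts + 1L
      if (attempts > budget) {
        rlang::abort(sprintf(
          "soma placement rejection budget exhausted (%d attempts) after placing %d of %d somata; lower the density or enlarge the volume",
          budget, length(radii), n_somata))
      }
      r <- stats::runif(1, r_vox[[1]], r_vox[[2]])
      cen <- c(stats::runif(1, 1 + r, dm[[1]] - r),
               stats::runif(1, 1 + r, dm[[2]] - r),
               stats::runif(1, 1, dm[[3]]))
      if (length(radii) > 0) {
        d <- sqrt(colSums((t(centers) - cen)^2))
        if (any(d < radii + r + 1)) next
      }
      centers <- rbind(centers, cen)
      radii <- c(radii, r)
    }
    for (i in seq_along(radii)) {
      vol <- .stamp_ball(vol, centers[i, ], radii[[i]], PHANTOM_LABELS[["cytoplasm"]])
    }

    # processes: persistent random walks from the soma surface (cytoplasm)
    pr <- process_radius_nm / voxel_size_nm
    for (i in seq_along(radii)) {
      for (p in seq_len(processes_per_cell)) {
        dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
        pos <- centers[i, ] + dir * radii[[i]]
        nseg <- sample(10:25, 1)
        for (s in seq_len(nseg)) {
          dir <- dir + stats::rnorm(3, sd = 0.25)
          dir <- dir / sqrt(sum(dir^2))
          nxt <- pos + dir * 3
          vol <- .stamp_tube(vol, pos, nxt, max(pr, 1), PHANTOM_LABELS[["cytoplasm"]])
          pos <- nxt
          if (any(pos < -5) || any(pos > dm + 5)) break
        }
      }
    }

    # nuclei and nucleoli (stamped last: deeper structures take precedence)
    for (i in seq_along(radii)) {
      rnuc <- nucleus_fraction * radii[[i]]
      vol <- .stamp_ball(vol, centers[i, ], rnuc, PHANTOM_LABELS[["nucleus"]])
      n_nucl <- sample(seq(n_nucleoli_range[[1]], n_nucleoli_range[[2]]), 1)
      rno <- nucleolus_fraction * radii[[i]]
      for (q in seq_len(n_nucl)) {
        off <- stats::rnorm(3); off <- off / sqrt(sum(off^2))
        off <- off * stats::runif(1, 0, max(rnuc - rno, 0))
        vol <- .stamp_ball(vol, centers[i, ] + off, rno, PHANTOM_LABELS[["nucleolus"]])
      }
    }
    vol
  })
  structure(list(labels = vol, voxel_size_nm = voxel_size_nm,
                 seed = seed, params = params),
            class = "tissue_phantom")
}

#' @export
print.tissue_phantom <- function(x, ...) {
  dm <- dim(x$labels)
  counts <- tabulate(x$labels + 1L, nbins = 5L)
  cat(sprintf("<tissue_phantom> %d x %d x %d voxels @ %g nm, seed %s\n",
              dm[[1]], dm[[2]], dm[[3]], x$voxel_size_nm, format(x$seed)))
  cat(paste(sprintf("  %-12s %d", names(PHANTOM_LABELS), counts), collapse = "\n"), "\n")
  invisible(x)
}

#' Cut one serial section from a phantom
#'
#' The slab of voxel planes covered by section `index` (1-based) at the given
#' thickness is collapsed to a 2D label map by per-pixel majority vote across
#' the slab; ties go to the deeper structure (nucleolus > nucleus > cytoplasm >
#' vessel_lumen > neuropil).
#'
#' @param phantom A `tissue_phantom`.
#' @param section_thickness_nm Section thickness in nm.
#' @param index 1-based section index.
#' @return A `section_labelmap`: list with `labels` (integer matrix, x by y),
#'   `section_index`, `section_thickness_nm`, `pixel_size_nm`, and the voxel
#'   plane range `z_from`/`z_to`.
#' @export
slice_phantom <- function(phantom, section_thickness_nm, index) {
  stopifnot(inherits(phantom, "tissue_phantom"))
  check_number(section_thickness_nm, "section_thickness_nm", min = 1e-9)
  vz <- phantom$voxel_size_nm
  nz <- dim(phantom$labels)[[3]]
  z_from <- floor((index - 1) * section_thickness_nm / vz) + 1
  z_to <- max(z_from, ceiling(index * section_thickness_nm / vz - 1e-9))
  if (index < 1 || z_to > nz) {
    rlang::abort(sprintf("section index %s out of range (volume has %d voxel planes)",
                         format(index), nz))
  }
  slab <- phantom$labels[, , z_from:z_to, drop = FALSE]
  dmx <- dim(slab)[[1]]; dmy <- dim(slab)[[2]]
  best_code <- matrix(PHANTOM_LABELS[["neuropil"]], dmx, dmy)
  best_count <- matrix(-1L, dmx, dmy)
  for (code in rev(unname(PHANTOM_LABELS))) {  # descending: deeper wins ties
    cnt <- rowSums(slab == code, dims = 2)
    take <- cnt > best_count
    best_code[take] <- code
    best_count[take] <- cnt[take]
  }
  structure(list(labels = best_code, section_index = index,
                 section_thickness_nm = section_thickness_nm,
                 pixel_size_nm = phantom$voxel_size_nm,
                 z_from = z_from, z_to = z_to),
            class = "section_labelmap")
}

#' Default label-to-material mapping for rendering
#' @return Named character vector (label name -> material id).
#' @export
default_label_materials <- function() {
  c(neuropil = "stained_tissue", vessel_lumen = "resin",
    cytoplasm = "stained_cell", nucleus = "stained_cell",
    nucleolus = "stained_cell")
}

#' Render a reflected-light image of a section
#'
#' For each label present, the stack reflectance is computed once with the
#' section layer set to that label's material (the rest of the configuration —
#' coating, tape, carbon tape, substrate — is shared). Pixel intensity is
#' `gain * R + offset`, with optional scaled-Poisson shot noise and additive
#' Gaussian read noise, both seeded.
#'
#' @param labelmap A `section_labelmap`.
#' @param config An [omlit_config()]; its `section_thickness_nm` should match
#'   the labelmap's (it is overridden to the labelmap value, which is the
#'   physical thickness of the rendered section).
#' @param illum An [illumination()].
#' @param lib A [material_library()].
#' @param label_materials Named character vector mapping every label present to
#'   a material id (default [default_label_materials()]).
#' @param gain,offset Affine intensity calibration.
#' @param noise_sd Additive Gaussian noise standard deviation (0 = none).
#' @param poisson_scale Intensity per photon count; > 0 replaces each pixel by
#'   `rpois(intensity / poisson_scale) * poisson_scale` before Gaussian noise.
#' @param seed Seed for the noise draws (required when any noise is enabled).
#' @return A `section_image`: numeric matrix with metadata attributes.
#' @export
render_section <- function(labelmap, config, illum, lib,
                           label_materials = default_label_materials(),
                           gain = 1, offset = 0,
                           noise_sd = 0, poisson_scale = 0, seed = NULL) {
  stopifnot(inherits(labelmap, "section_labelmap"), inherits(config, "omlit_config"))
  if ((noise_sd > 0 || poisson_scale > 0) && is.null(seed)) {
    rlang::abort("`seed` is required when noise is enabled")
  }
  config$section_thickness_nm <- labelmap$section_thickness_nm
  present <- sort(unique(as.vector(labelmap$labels)))
  lab_names <- names(PHANTOM_LABELS)[match(present, PHANTOM_LABELS)]
  unmapped <- lab_names[!lab_names %in% names(label_materials)]
  if (length(unmapped) > 0) {
    rlang::abort(paste0("unmapped label(s): ", paste(unmapped, collapse = ", ")))
  }
  R_of <- vapply(lab_names, function(ln) {
    st <- build_stacks(config, section_material = label_materials[[ln]])$cell
    stack_reflectance(st, illum, lib)$R
  }, numeric(1))
  img <- matrix(R_of[match(labelmap$labels, present)],
                nrow = nrow(labelmap$labels), ncol = ncol(labelmap$labels))
  img <- gain * img + offset
  img <- with_seed(seed, {
    if (poisson_scale > 0) {
      img[] <- stats::rpois(length(img), pmax(img, 0) / poisson_scale) * poisson_scale
    }
    if (noise_sd > 0) {
      img[] <- img + stats::rnorm(length(img), sd = noise_sd)
    }
    img
  })
  structure(img, class = c("section_image", "matrix", "array"),
            pixel_size_nm = labelmap$pixel_size_nm,
            metadata = list(wavelength_nm = illum$wavelength_nm,
                            polarization = illum$polarization,
                            section_thickness_nm = labelmap$section_thickness_nm,
                            section_index = labelmap$section_index,
                            coating = config$coating,
                            gain = gain, offset = offset,
                            noise_sd = noise_sd, poisson_scale = poisson_scale,
                            seed = seed))
}

#' @export
print.section_image <- function(x, ...) {
  md <- attr(x, "metadata")
  cat(sprintf("<section_image> %d x %d px @ %g nm, %g nm illumination, range [%.4g, %.4g]\n",
              nrow(x), ncol(x), attr(x, "pixel_size_nm"),
              md$wavelength_nm, min(x), max(x)))
  invisible(x)
}

#' Inject coating-defect artifacts into a section image
#'
#' Emulates the defects of imperfect metal coatings: scratches (straight dark
#' line segments of a given width), cracks (jagged random-walk polylines), and
#' peeling/dust specks (disks). Offsets are added to the affected pixels;
#' placement is seeded and deterministic. The modified pixel mask is attached
#' as attribute `defect_mask`.
#'
#' @param image A `section_image` (or plain numeric matrix).
#' @param n_scratches,n_cracks,n_specks Defect counts (all default 0).
#' @param scratch_width_px Scratch width in pixels.
#' @param scratch_delta,crack_delta,speck_delta Intensity offsets applied to
#'   the affected pixels (dark scratches/cracks, bright specks by default).
#' @param speck_radius_px Length-2 range of speck radii.
#' @param seed Integer seed (required when any count is positive).
#' @return The image with defects applied; same class and attributes.
#' @export
add_defects <- function(image, n_scratches = 0, n_cracks = 0, n_specks = 0,
                        scratch_width_px = 3, scratch_delta = -0.25,
                        crack_delta = -0.4, speck_delta = 0.3,
                        speck_radius_px = c(2, 5), seed = NULL) {
  stopifnot(is.matrix(image))
  total <- n_scratches + n_cracks + n_specks
  if (total == 0) {
    attr(image, "defect_mask") <- matrix(FALSE, nrow(image), ncol(image))
    return(image)
  }
  if (is.null(seed)) rlang::abort("`seed` is required when defects are enabled")
  nr <- nrow(image); nc <- ncol(image)
  mask_line <- function(mask, from, to, half_width) {
    len <- sqrt(sum((to - from)^2))
    for (t in seq(0, 1, length.out = max(2L, ceiling(len * 2)))) {
      p <- from + t * (to - from)
      x_lo <- max(1, floor(p[[1]] - half_width)); x_hi <- min(nr, ceiling(p[[1]] + half_width))
      y_lo <- max(1, floor(p[[2]] - half_width)); y_hi <- min(nc, ceiling(p[[2]] + half_width))
      if (x_lo > x_hi || y_lo > y_hi) next
      xs <- seq(x_lo, x_hi)
      ys <- seq(y_lo, y_hi)
      d2 <- outer((xs - p[[1]])^2, (ys - p[[2]])^2, "+")
      sub <- mask[xs, ys, drop = FALSE]
      sub[d2 <= half_width^2] <- TRUE
      mask[xs, ys] <- sub
    }
    mask
  }
  out <- with_seed(seed, {
    deltas <- numeric(0)
    masks <- list()
    for (s in seq_len(n_scratches)) {
      # a straight segment spanning the full field in a random direction
      ang <- stats::runif(1, 0, pi)
      cen <- c(stats::runif(1, 1, nr), stats::runif(1, 1, nc))
      dir <- c(cos(ang), sin(ang))
      ext <- (nr + nc)
      m <- mask_line(matrix(FALSE, nr, nc), cen - ext * dir, cen + ext * dir,
                     (scratch_width_px - 1) / 2)
      masks <- c(masks, list(m)); deltas <- c(deltas, scratch_delta)
    }
    for (cr in seq_len(n_cracks)) {
      m <- matrix(FALSE, nr, nc)
      pos <- c(stats::runif(1, 1, nr), stats::runif(1, 1, nc))
      ang <- stats::runif(1, 0, 2 * pi)
      for (s in seq_len(12)) {
        ang <- ang + stats::rnorm(1, sd = 0.7)  # jagged turns
        nxt <- pos + c(cos(ang), sin(ang)) * stats::runif(1, 4, 12)
        m <- mask_line(m, pos, nxt, 0.5)
        pos <- nxt
      }
      masks <- c(masks, list(m)); deltas <- c(deltas, crack_delta)
    }
    for (sp in seq_len(n_specks)) {
      cen <- c(stats::runif(1, 1, nr), stats::runif(1, 1, nc))
      rad <- stats::runif(1, speck_radius_px[[1]], speck_radius_px[[2]])
      m <- mask_line(matrix(FALSE, nr, nc), cen, cen + 1e-6, rad)
      masks <- c(masks, list(m)); deltas <- c(deltas, speck_delta)
    }
    img <- image
    total_mask <- matrix(FALSE, nr, nc)
    for (i in seq_along(masks)) {
      img[masks[[i]]] <- img[masks[[i]]] + deltas[[i]]
      total_mask <- total_mask | masks[[i]]
    }
    attr(img, "defect_mask") <- total_mask
    img
  })
  md <- attr(out, "metadata")
  if (!is.null(md)) {
    md$defects <- list(n_scratches = n_scratches, n_cracks = n_cracks,
                       n_specks = n_specks, seed = seed)
    attr(out, "metadata") <- md
  }
  out
}

#' Write a section image (or label map) to 16-bit TIFF
#'
#' Intensities are clipped to \[0, 1\] and quantized to 16 bits; label maps are
#' written as integer palettes scaled into the 16-bit range.
#'
#' @param image A `section_image` or numeric matrix in \[0, 1\].
#' @param path Destination `.tif` path.
#' @return `path`, invisibly.
#' @export
write_section_tiff <- function(image, path) {
  img <- pmin(pmax(unclass(image), 0), 1)
  attributes(img) <- list(dim = dim(img))
  tiff::writeTIFF(img, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Read a grayscale TIFF as a plain intensity matrix
#' @param path TIFF path.
#' @return Numeric matrix in \[0, 1\].
#' @export
read_section_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img
}
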