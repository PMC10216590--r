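# Shared fixtures: synthetic material libraries, random stacks, and a
# brute-force 3D connected-components oracle.

# dispersionless library: constant n, k per material over 300-800 nm
flat_library <- function(n, k = NULL) {
  ids <- names(n)
  kk <- stats::setNames(rep(0, length(ids)), ids)
  if (!is.null(k)) kk[names(k)] <- k
  k <- kk
  material_library(tibble::tibble(
    material_id = rep(ids, each = 2),
    wavelength_nm = rep(c(300, 800), length(ids)),
    n = rep(unname(n), each = 2),
    k = rep(unname(k[ids]), each = 2)))
}

# seeded random coherent stacks (absorbing and lossless mixes, oblique)
random_stack_cases <- function(n_cases, seed = 20240901) {
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code
  }
  withr_seed({
    lapply(seq_len(n_cases), function(i) {
      nl <- sample(1:6, 1)
      ids <- c("inc", paste0("m", seq_len(nl)), "sub")
      lossless <- stats::runif(1) < 0.3
      lib <- material_library(tibble::tibble(
        material_id = rep(ids, each = 2),
        wavelength_nm = rep(c(300, 800), length(ids)),
        n = rep(stats::runif(length(ids), 0.3, 4), each = 2),
        k = rep(c(0, if (lossless) rep(0, nl + 1) else
          stats::runif(nl + 1, 0, 3)), each = 2)))
      list(
        lib = lib,
        lossless = lossless,
        stack = layer_stack("inc", lapply(seq_len(nl), function(j)
          layer(paste0("m", j), stats::runif(1, 5, 500))), "sub"),
        illum = illumination(stats::runif(1, 350, 750),
                             angle_deg = stats::runif(1, 0, 80),
                             polarization = sample(c("s", "p", "unpolarized"), 1)))
    })
  })
}

# brute-force 6-connected component count of a logical 3D array
count_components_3d <- function(mask) {
  dm <- dim(mask)
  seen <- array(FALSE, dm)
  offsets <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                   c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  n_comp <- 0L
  remaining <- which(mask)
  while (length(remaining) > 0) {
    n_comp <- n_comp + 1L
    frontier <- remaining[[1]]
    seen[frontier] <- TRUE
    while (length(frontier) > 0) {
      ai <- arrayInd(frontier, dm)
      nb <- do.call(rbind, lapply(seq_len(6), function(o)
        sweep(ai, 2, offsets[o, ], "+")))
      ok <- nb[, 1] >= 1 & nb[, 1] <= dm[1] & nb[, 2] >= 1 & nb[, 2] <= dm[2] &
        nb[, 3] >= 1 & nb[, 3] <= dm[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- unique(nb[, 1] + (nb[, 2] - 1L) * dm[1] +
                      (nb[, 3] - 1L) * dm[1] * dm[2])
      frontier <- lin[mask[lin] & !seen[lin]]
      seen[frontier] <- TRUE
    }
    remaining <- remaining[!seen[remaining]]
  }
  n_comp
}

# quasi-2D phantom with many somata whose mid-slice cross-sections all admit
# an 11 px ROI (soma radius >= 10 um in a 10 um-tall slab)
roi_test_phantom <- function(seed = 11, n_somata = 60) {
  generate_phantom(dim_vox = c(320L, 320L, 10L), voxel_size_nm = 1000,
                   n_somata = n_somata, soma_radius_nm = c(10000, 13000),
                   n_vessels = 0, processes_per_cell = 0, seed = seed)
}
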