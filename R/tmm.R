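#' Transfer-matrix optics for planar multilayers
#'
#' The engine evaluates reflectance, transmittance and absorptance of an
#' arbitrary stack under monochromatic illumination by multiplying per-layer
#' 2x2 characteristic matrices. Incoherent (optically thick) layers are handled
#' by averaging the fully coherent result over a uniform round-trip phase, and
#' an independent Parratt-style interface recursion is provided as a
#' cross-check. Conventions: complex index \eqn{\tilde n = n + i k}; time
#' dependence such that \eqn{Im(\delta) > 0} means decay; the incident medium
#' must be lossless.
#'
#' @name tmm
NULL

# cap on Im(phase thickness): attenuation e^-40 is far below double precision
# relevance but keeps cos/sin of complex arguments from overflowing for
# optically thick absorbing layers (e.g. 100 um carbon tape).
.IM_DELTA_CAP <- 40
# round-trip attenuation threshold below which nothing returns from deeper
# layers and the stack can be truncated there (exact to ~1e-17)
.OPAQUE_2IM <- 40
# midpoint phase samples per incoherent layer (over one half-period pi)
.N_PHASE <- 64L

.cos_in_medium <- function(n_med, s0) {
  # complex cosine of the propagation angle, branch chosen so the wave decays
  # into an absorbing medium: Im(n cos) >= 0; for lossless media Re(cos) >= 0
  cs <- sqrt(1 - (s0 / n_med)^2)
  flip <- Im(n_med * cs) < -1e-14 |
    (abs(Im(n_med * cs)) <= 1e-14 & Re(cs) < 0)
  cs[flip] <- -cs[flip]
  cs
}

.eta_of <- function(n_med, cs, pol) {
  if (pol == "s") n_med * cs else n_med / cs
}

.cap_delta <- function(delta) {
  im <- pmin(pmax(Im(delta), -.IM_DELTA_CAP), .IM_DELTA_CAP)
  complex(real = Re(delta), imaginary = im)
}

# resolve materials at one wavelength; returns complex indices
.resolve_stack <- function(stack, lib, wavelength_nm) {
  n_inc <- complex_index(lib, stack$incident, wavelength_nm)
  if (abs(Im(n_inc)) > 1e-12) {
    rlang::abort(sprintf(
      "incident medium `%s` must be lossless (k = 0) at %g nm", stack$incident,
      wavelength_nm))
  }
  lay <- stack$layers
  list(
    n_inc = n_inc,
    n_lay = if (nrow(lay) > 0)
      vapply(lay$material, function(m) complex_index(lib, m, wavelength_nm),
             complex(1), USE.NAMES = FALSE)
    else complex(0),
    d = lay$thickness_nm,
    incoh = lay$coherence == "incoherent",
    n_sub = complex_index(lib, stack$substrate, wavelength_nm)
  )
}

# characteristic-matrix chain; deltas may be scalars or equal-shaped arrays.
# Returns list(B, C) with (B, C)^T = (prod M_j) (1, eta_sub)^T
.chain_bc <- function(deltas, etas, eta_sub) {
  B <- 1 + 0i
  C <- eta_sub
  for (j in rev(seq_along(deltas))) {
    cd <- cos(deltas[[j]])
    sd <- sin(deltas[[j]])
    Bn <- cd * B + (1i * sd / etas[[j]]) * C
    Cn <- (1i * etas[[j]] * sd) * B + cd * C
    B <- Bn
    C <- Cn
  }
  list(B = B, C = C)
}

# single-polarization, single-point evaluation with incoherent phase averaging
.reflect_once <- function(rs, theta0_rad, wavelength_nm, pol) {
  d <- rs$d
  n_lay <- rs$n_lay
  incoh <- rs$incoh
  s0 <- Re(rs$n_inc) * sin(theta0_rad)

  cs_lay <- if (length(d) > 0) .cos_in_medium(n_lay, s0) else complex(0)
  # the characteristic-matrix formalism is written in the e^{i(wt - kz)} time
  # convention, in which an absorbing layer (k > 0 stored as n + ik) carries a
  # conjugated phase thickness with Im(delta) < 0
  delta <- if (length(d) > 0)
    .cap_delta(Conj(2 * pi * n_lay * d * cs_lay / wavelength_nm)) else complex(0)

  # opacity truncation: below a layer with round-trip attenuation < e^-40
  # nothing returns; treat that layer as the semi-infinite substrate
  truncated <- FALSE
  opaque <- which(2 * abs(Im(delta)) > .OPAQUE_2IM)
  if (length(opaque) > 0) {
    jcut <- opaque[[1]]
    n_sub <- n_lay[[jcut]]
    keep <- seq_len(jcut - 1L)
    n_lay <- n_lay[keep]; d <- d[keep]; incoh <- incoh[keep]
    cs_lay <- cs_lay[keep]; delta <- delta[keep]
    truncated <- TRUE
  } else {
    n_sub <- rs$n_sub
  }

  cs0 <- cos(theta0_rad) + 0i
  cs_sub <- .cos_in_medium(n_sub, s0)
  eta0 <- Re(.eta_of(rs$n_inc, cs0, pol))
  eta_sub <- Conj(.eta_of(n_sub, cs_sub, pol))
  etas <- if (length(d) > 0) Conj(.eta_of(n_lay, cs_lay, pol)) else complex(0)

  ii <- which(incoh & d > 0)
  if (length(ii) > 3) {
    rlang::abort("at most 3 incoherent layers are supported per coherent evaluation")
  }
  dl <- as.list(delta)
  if (length(ii) > 0) {
    # joint uniform phase grid (midpoint rule) over one half-period per layer
    phi <- pi * (seq_len(.N_PHASE) - 0.5) / .N_PHASE
    dims <- rep(.N_PHASE, length(ii))
    total <- prod(dims)
    for (m in seq_along(ii)) {
      ph <- array(rep(phi, each = .N_PHASE^(m - 1L)), dim = dims)
      dl[[ii[[m]]]] <- array(dl[[ii[[m]]]] + ph, dim = dims)
    }
    if (total > 64^3) rlang::abort("incoherent phase grid too large")
  }
  bc <- .chain_bc(dl, as.list(etas), eta_sub)
  denom <- eta0 * bc$B + bc$C
  r <- (eta0 * bc$B - bc$C) / denom
  R <- mean(Mod(r)^2)
  T <- if (truncated) 0 else mean(4 * eta0 * Re(eta_sub) / Mod(denom)^2)
  list(R = R, T = T)
}

.reflectance_tibble <- function(Rs, Ts, Rp, Tp, illum) {
  pol <- illum$polarization
  R <- switch(pol, s = Rs, p = Rp, unpolarized = (Rs + Rp) / 2)
  T <- switch(pol, s = Ts, p = Tp, unpolarized = (Ts + Tp) / 2)
  clip01 <- function(x) min(max(x, 0), 1)
  A <- 1 - R - T
  if (A > -1e-9 && A < 0) A <- 0
  tibble::tibble(
    wavelength_nm = illum$wavelength_nm, angle_deg = illum$angle_deg,
    polarization = pol,
    R = clip01(R), T = clip01(T), A = A,
    R_s = Rs, R_p = Rp, T_s = Ts, T_p = Tp)
}

#' Reflectance of a multilayer stack
#'
#' Computes reflectance R, transmittance T and absorptance A (A = 1 - R - T;
#' for an absorbing substrate A includes the substrate's absorption of the
#' transmitted wave). Coherent sub-stacks are evaluated with the
#' characteristic-matrix product; incoherent layers are combined by averaging
#' the coherent result over a uniform round-trip phase (64 midpoint samples per
#' incoherent layer). If the illumination specifies `fwhm_nm > 0` or `na > 0`
#' the result is additionally averaged by [spectral_angular_average()].
#'
#' @param stack A [layer_stack()].
#' @param illum An [illumination()].
#' @param lib A [material_library()].
#' @return One-row tibble with columns `wavelength_nm`, `angle_deg`,
#'   `polarization`, `R`, `T`, `A` and per-polarization components `R_s`,
#'   `R_p`, `T_s`, `T_p`.
#' @examples
#' lib <- material_library(tibble::tibble(
#'   material_id = rep(c("air", "glass"), each = 2),
#'   wavelength_nm = rep(c(400, 700), 2),
#'   n = c(1, 1, 1.5, 1.5), k = 0))
#' stack_reflectance(layer_stack("air", list(), "glass"),
#'                   illumination(550), lib)  # Fresnel R = 0.04
#' @export
stack_reflectance <- function(stack, illum, lib) {
  stopifnot(inherits(stack, "layer_stack"), inherits(illum, "illumination"))
  if (illum$fwhm_nm > 0 || illum$na > 0) {
    return(spectral_angular_average(stack, illum, lib))
  }
  rs <- .resolve_stack(stack, lib, illum$wavelength_nm)
  th <- deg2rad(illum$angle_deg)
  s_res <- .reflect_once(rs, th, illum$wavelength_nm, "s")
  if (illum$angle_deg == 0) {
    p_res <- s_res  # s and p coincide at normal incidence
  } else {
    p_res <- .reflect_once(rs, th, illum$wavelength_nm, "p")
  }
  .reflectance_tibble(s_res$R, s_res$T, p_res$R, p_res$T, illum)
}

#' Reflectance by bottom-up interface recursion (independent oracle)
#'
#' Parratt-style recursion over Fresnel amplitude coefficients with phase
#' factors, implemented without the matrix formalism; used as an independent
#' cross-check of [stack_reflectance()] for coherent stacks.
#'
#' @inheritParams stack_reflectance
#' @return Reflectance R as a single number.
#' @export
reflectance_recursive <- function(stack, illum, lib) {
  stopifnot(inherits(stack, "layer_stack"), inherits(illum, "illumination"))
  if (any(stack$layers$coherence == "incoherent" & stack$layers$thickness_nm > 0)) {
    rlang::abort("reflectance_recursive supports coherent stacks only")
  }
  rs <- .resolve_stack(stack, lib, illum$wavelength_nm)
  th <- deg2rad(illum$angle_deg)
  one_pol <- function(pol) {
    s0 <- Re(rs$n_inc) * sin(th)
    n_med <- c(rs$n_inc, rs$n_lay, rs$n_sub)
    cs <- .cos_in_medium(n_med, s0)
    cs[[1]] <- cos(th) + 0i
    eta <- .eta_of(n_med, cs, pol)
    m <- length(rs$d)
    # beta_j: round-trip phase factor of layer j (media index j + 1)
    beta <- if (m > 0)
      exp(2i * (2 * pi * rs$n_lay * rs$d * cs[seq(2, m + 1)] / illum$wavelength_nm))
    else complex(0)
    rho <- (eta[-length(eta)] - eta[-1]) / (eta[-length(eta)] + eta[-1])
    r <- rho[[m + 1]]
    if (m > 0) {
      for (j in seq(m, 1)) {
        r <- (rho[[j]] + r * beta[[j]]) / (1 + rho[[j]] * r * beta[[j]])
      }
    }
    Mod(r)^2
  }
  switch(illum$polarization,
         s = one_pol("s"),
         p = one_pol("p"),
         unpolarized = (one_pol("s") + one_pol("p")) / 2)
}

#' Complex refraction angle in a layer (Snell's law)
#'
#' Solves \eqn{\tilde n_0 \sin\theta_0 = \tilde n_j \sin\theta_j} with the
#' branch chosen so the wave decays into an absorbing layer.
#'
#' @param n0 Real refractive index of the (lossless) incident medium.
#' @param theta0_deg Angle of incidence in degrees.
#' @param nj Complex refractive index of the layer.
#' @return Complex propagation angle in degrees.
#' @export
refraction_angle <- function(n0, theta0_deg, nj) {
  if (abs(Im(n0)) > 1e-12) rlang::abort("incident medium index must be real")
  s <- Re(n0) * sin(deg2rad(theta0_deg)) / nj
  cs <- .cos_in_medium(nj, Re(n0) * sin(deg2rad(theta0_deg)))
  theta <- -1i * log(cs + 1i * s)  # exp(i theta) = cos + i sin
  if (abs(Im(theta)) < 1e-14) theta <- complex(real = Re(theta), imaginary = 0)
  rad2deg(theta)
}

#' Optical admittance of a medium
#'
#' In normalized units (free-space admittance = 1): \eqn{\eta = \tilde n
#' \cos\theta} for s-polarization, \eqn{\eta = \tilde n / \cos\theta} for p.
#'
#' @param n Complex refractive index.
#' @param theta_deg Complex propagation angle in degrees.
#' @param polarization `"s"` or `"p"`.
#' @return Complex admittance.
#' @export
admittance <- function(n, theta_deg, polarization = c("s", "p")) {
  polarization <- match.arg(polarization)
  cs <- cos(deg2rad(theta_deg))
  if (Mod(cs) < 1e-12) rlang::abort("degenerate geometry: cos(theta) = 0")
  if (polarization == "s") n * cs else n / cs
}

#' Characteristic matrix of a coherent layer
#'
#' With phase thickness \eqn{\delta = 2\pi \tilde n d \cos\theta / \lambda} and
#' admittance \eqn{\eta}, the 2x2 matrix is
#' \deqn{M = [[\cos\delta, i \sin\delta / \eta], [i \eta \sin\delta, \cos\delta]]}
#' (determinant 1).
#'
#' @param lay A [layer()] row (must be coherent).
#' @param wavelength_nm Wavelength in nm.
#' @param theta_deg Complex propagation angle inside the layer, degrees.
#' @param polarization `"s"` or `"p"`.
#' @param lib A [material_library()].
#' @return 2x2 complex matrix.
#' @export
characteristic_matrix <- function(lay, wavelength_nm, theta_deg,
                                  polarization = c("s", "p"), lib) {
  polarization <- match.arg(polarization)
  stopifnot(is.data.frame(lay), nrow(lay) == 1L)
  if (lay$coherence != "coherent") {
    rlang::abort("characteristic_matrix is defined for coherent layers only")
  }
  # e^{i(wt - kz)} time convention: an absorbing layer enters the matrix with
  # conjugated index/angle, so lossless closed forms keep their textbook signs
  n <- Conj(complex_index(lib, lay$material, wavelength_nm))
  cs <- Conj(cos(deg2rad(theta_deg)))
  eta <- .eta_of(n, cs, polarization)
  delta <- .cap_delta(2 * pi * n * lay$thickness_nm * cs / wavelength_nm)
  matrix(c(cos(delta), 1i * eta * sin(delta),
           1i * sin(delta) / eta, cos(delta)), nrow = 2, ncol = 2)
}

#' Spectral and angular averaging of stack reflectance
#'
#' Gaussian-weighted average of the single-point result over wavelength (FWHM
#' as given, truncated at +/- 2 FWHM, 16-point Gauss-Legendre quadrature) and a
#' uniform-pupil-irradiance average over incidence angles up to `asin(na)`
#' (weight \eqn{\sin\theta\cos\theta}, 8-point quadrature). Collapses to the
#' single-point evaluation when both `fwhm_nm` and `na` are 0. Angular
#' averaging is implemented about the normal axis (`angle_deg` must be 0 when
#' `na > 0`).
#'
#' @inheritParams stack_reflectance
#' @return Same one-row tibble as [stack_reflectance()].
#' @export
spectral_angular_average <- function(stack, illum, lib) {
  stopifnot(inherits(illum, "illumination"))
  if (illum$na >= 1) rlang::abort("`na` must be < 1")
  if (illum$na > 0 && illum$angle_deg != 0) {
    rlang::abort("NA-averaging is implemented about the normal axis (angle_deg = 0)")
  }
  gauss_nodes <- function(order, a, b) {
    g <- pracma::gaussLegendre(order, a, b)
    list(x = g$x, w = g$w)
  }
  if (illum$fwhm_nm > 0) {
    gl <- gauss_nodes(16L, illum$wavelength_nm - 2 * illum$fwhm_nm,
                      illum$wavelength_nm + 2 * illum$fwhm_nm)
    sigma <- illum$fwhm_nm / (2 * sqrt(2 * log(2)))
    wl_nodes <- gl$x
    wl_w <- gl$w * exp(-(gl$x - illum$wavelength_nm)^2 / (2 * sigma^2))
    wl_w <- wl_w / sum(wl_w)
  } else {
    wl_nodes <- illum$wavelength_nm
    wl_w <- 1
  }
  if (illum$na > 0) {
    ga <- gauss_nodes(8L, 0, asin(illum$na))
    th_nodes <- ga$x
    th_w <- ga$w * sin(ga$x) * cos(ga$x)
    # the exact normal ray has zero weight under the annular measure; the
    # quadrature nodes are interior so no degenerate node arises
    th_w <- th_w / sum(th_w)
  } else {
    th_nodes <- deg2rad(illum$angle_deg)
    th_w <- 1
  }
  acc <- c(Rs = 0, Ts = 0, Rp = 0, Tp = 0)
  for (i in seq_along(wl_nodes)) {
    rs <- .resolve_stack(stack, lib, wl_nodes[[i]])
    for (j in seq_along(th_nodes)) {
      w <- wl_w[[i]] * th_w[[j]]
      s_res <- .reflect_once(rs, th_nodes[[j]], wl_nodes[[i]], "s")
      p_res <- if (th_nodes[[j]] == 0) s_res else
        .reflect_once(rs, th_nodes[[j]], wl_nodes[[i]], "p")
      acc <- acc + w * c(s_res$R, s_res$T, p_res$R, p_res$T)
    }
  }
  .reflectance_tibble(acc[["Rs"]], acc[["Ts"]], acc[["Rp"]], acc[["Tp"]], illum)
}
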