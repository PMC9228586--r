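#' Stokes drag coefficient of a spherical hub
#'
#' First-order (bulk) approximation `gamma = 6 * pi * eta_fluid * R` for a
#' sphere far from any wall.  Near a surface the true drag is larger; the
#' model nevertheless treats the drag coefficient as a constant because the
#' hub stays tethered at a fixed height above the track.
#'
#' @param eta_fluid Fluid viscosity (Pa s).
#' @param R Hub radius (m).
#' @return Drag coefficient (N s / m).
#' @examples
#' drag_coefficient(1e-3, 1e-6)   # ~1.885e-8 N s/m for a 1 um bead in water
#' @export
drag_coefficient <- function(eta_fluid, R) {
  if (eta_fluid < 0 || R < 0) {
    stop("drag_coefficient(): eta_fluid and R must be non-negative")
  }
  6 * pi * eta_fluid * R
}

#' Characteristic fluctuation length of the substrate tethers
#'
#' The root-mean-square excursion `sigma = sqrt(kBT / k_spring)` of a
#' surface polymer with entropic spring constant `k_spring` at thermal
#' energy `kBT`.  All positions in the dimensionless model are measured in
#' units of this length.
#'
#' @param kBT Thermal energy (pN nm).
#' @param k_spring Effective spring constant of the tethers (pN / nm).
#' @return Characteristic length (nm).
#' @examples
#' characteristic_length(4.1, 2e-4)   # ~143 nm (0.2 pN/um tethers)
#' @export
characteristic_length <- function(kBT, k_spring) {
  if (kBT <= 0 || k_spring <= 0) {
    stop("characteristic_length(): kBT and k_spring must be positive")
  }
  sqrt(kBT / k_spring)
}

#' Reference line concentration for non-dimensionalization
#'
#' `a0 = gamma * r * sigma / kBT`, the substrate line density at which the
#' elastic force from a fully bound kernel-width of complex balances drag at
#' speed `sigma * r`.  Concentrations in the dimensionless model are
#' measured in units of `a0`.
#'
#' @param gamma Drag coefficient (N s / m).
#' @param r Complex formation rate (1 / s).
#' @param sigma Characteristic length (nm).
#' @param kBT Thermal energy (pN nm).
#' @return Reference concentration (1 / um).
#' @examples
#' reference_concentration(drag_coefficient(1e-3, 1e-6), 20, 100, 4.1)  # ~9.2 / um
#' @export
reference_concentration <- function(gamma, r, sigma, kBT) {
  if (gamma <= 0 || r <= 0 || sigma <= 0 || kBT <= 0) {
    stop("reference_concentration(): all inputs must be positive")
  }
  # SI internally: sigma nm -> m, kBT pN nm -> J; result 1/m -> 1/um
  (gamma * r * (sigma * 1e-9) / (kBT * 1e-21)) * 1e-6
}

#' Physical (dimensional) motor parameters
#'
#' Bundles the dimensional quantities of the model in the units the field
#' prints: viscosity in Pa s, radius in m, energies in pN nm, stiffness in
#' pN/nm, rates in 1/s, lengths in nm, line concentrations in 1/um.  The
#' drag coefficient may be given directly or derived from `(eta_fluid, R)`
#' via [drag_coefficient()]; supplying both inconsistently (beyond 1%
#' relative) is an error rather than a silent preference.
#'
#' @param kBT Thermal energy (pN nm).
#' @param k_spring Tether spring constant (pN / nm).
#' @param r Complex formation rate (1 / s).
#' @param nu Substrate burn rate (1 / s).
#' @param koff Surface unbinding rate of substrate (1 / s).
#' @param Atot Total substrate line concentration (1 / um).
#' @param DeltaG Free energy released per burned substrate (pN nm).
#' @param kon Surface binding rate of free substrate (1 / s); defaults to
#'   `r` (binding to the surface assumed kinetically similar to binding the
#'   hub).
#' @param omega Complex dissociation rate at zero force (1 / s).
#' @param Delta Distance between the bound-complex and surface-bound states
#'   along the unbinding coordinate (nm).
#' @param gamma Drag coefficient (N s / m); derived from `eta_fluid`, `R`
#'   when omitted.
#' @param eta_fluid Fluid viscosity (Pa s); optional when `gamma` is given.
#' @param R Hub radius (m); optional when `gamma` is given.
#' @return An object of class `physical_params`.
#' @examples
#' phys <- physical_params(kBT = 4.1, k_spring = 2e-4, r = 20, nu = 20,
#'                         koff = 0.2, Atot = 10, DeltaG = 61.5,
#'                         eta_fluid = 1e-3, R = 1e-6)
#' to_dimensionless(phys)
#' @export
physical_params <- function(kBT, k_spring, r, nu, koff, Atot, DeltaG,
                            kon = r, omega = 0, Delta = 0,
                            gamma = NULL, eta_fluid = NULL, R = NULL) {
  have_gamma <- !is.null(gamma)
  have_eta <- !is.null(eta_fluid) && !is.null(R)
  if (!have_gamma && !have_eta) {
    stop("physical_params(): supply gamma or both of eta_fluid and R")
  }
  if (have_eta) {
    gamma_derived <- drag_coefficient(eta_fluid, R)
    if (have_gamma) {
      if (abs(gamma - gamma_derived) > 0.01 * max(gamma, gamma_derived)) {
        stop("physical_params(): gamma and 6*pi*eta_fluid*R disagree by more than 1%")
      }
    } else {
      gamma <- gamma_derived
    }
  }
  vals <- c(kBT = kBT, k_spring = k_spring, r = r, nu = nu, koff = koff,
            kon = kon, omega = omega, Delta = Delta, Atot = Atot,
            DeltaG = DeltaG, gamma = gamma)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("physical_params(): all parameters must be finite and non-negative")
  }
  structure(list(eta_fluid = eta_fluid, R = R, gamma = gamma, kBT = kBT,
                 k_spring = k_spring, r = r, nu = nu, koff = koff, kon = kon,
                 omega = omega, Delta = Delta, Atot = Atot, DeltaG = DeltaG),
            class = "physical_params")
}

#' Characteristic scales of the non-dimensionalization
#'
#' @param p A [physical_params()] object.
#' @return An object of class `characteristic_scales` with fields `sigma`
#'   (length, nm), `tau_unit` (time, s, equal to `1/r`) and `a0`
#'   (concentration, 1/um).
#' @export
characteristic_scales <- function(p) {
  stopifnot(inherits(p, "physical_params"))
  if (p$gamma <= 0 || p$kBT <= 0 || p$k_spring <= 0 || p$r <= 0) {
    stop("characteristic_scales(): gamma, kBT, k_spring and r must be positive")
  }
  sigma <- characteristic_length(p$kBT, p$k_spring)
  structure(list(sigma = sigma,
                 tau_unit = 1 / p$r,
                 a0 = reference_concentration(p$gamma, p$r, sigma, p$kBT)),
            class = "characteristic_scales")
}

#' Dimensionless control parameters
#'
#' The four control parameters of the dimensionless model -- total substrate
#' `atot` (units of the reference concentration a0), burn rate `nu_p`
#' (units of the complex formation rate r), surface unbinding `koff_p`
#' (units of r) and the turnover equilibrium constant `K = koff/kon` --
#' plus the zero-force complex dissociation rate `omega_p`, the Bell
#' unbinding distance `delta` (units of sigma) and the free energy per
#' burned substrate `dg` (units of kBT).  With the default `kon_p = 1`
#' (surface binding as fast as hub binding), `K` equals `koff_p`.
#'
#' @param atot Total substrate concentration (a0 units).
#' @param nu_p Burn rate (r units).
#' @param koff_p Surface unbinding rate (r units).
#' @param kon_p Surface binding rate (r units); default 1.
#' @param omega_p Complex dissociation rate at zero force (r units).
#' @param delta Bell unbinding distance (sigma units).
#' @param dg Free energy per burned substrate (kBT units).
#' @return An object of class `dimensionless_params`.
#' @examples
#' dimensionless_params(atot = 1, nu_p = 1)          # reference parameter set
#' @export
dimensionless_params <- function(atot = 1, nu_p = 1, koff_p = 0.01,
                                 kon_p = 1, omega_p = 0, delta = 0,
                                 dg = 15) {
  vals <- c(atot = atot, nu_p = nu_p, koff_p = koff_p, kon_p = kon_p,
            omega_p = omega_p, delta = delta, dg = dg)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("dimensionless_params(): all parameters must be finite and non-negative")
  }
  if (kon_p <= 0 && koff_p > 0) {
    stop("dimensionless_params(): kon_p must be positive when koff_p > 0")
  }
  K <- if (koff_p == 0) 0 else koff_p / kon_p
  structure(list(atot = atot, nu_p = nu_p, koff_p = koff_p, kon_p = kon_p,
                 K = K, omega_p = omega_p, delta = delta, dg = dg),
            class = "dimensionless_params")
}

#' @export
print.dimensionless_params <- function(x, ...) {
  cat("Dimensionless BBR parameters\n")
  cat(sprintf("  atot = %g, nu' = %g, koff' = %g, K = %g\n",
              x$atot, x$nu_p, x$koff_p, x$K))
  cat(sprintf("  omega' = %g, delta = %g, dg = %g\n",
              x$omega_p, x$delta, x$dg))
  invisible(x)
}

#' Convert physical parameters to dimensionless form
#'
#' Non-dimensionalizes by the characteristic length `sigma = sqrt(kBT/k)`,
#' time `1/r` and concentration `a0 = gamma*r*sigma/kBT`: rates are divided
#' by `r`, the unbinding distance by `sigma`, the substrate concentration
#' by `a0` and the free energy by `kBT`.
#'
#' @param p A [physical_params()] object.
#' @return A list with components `params` ([dimensionless_params()]) and
#'   `scales` ([characteristic_scales()]).
#' @seealso [from_dimensionless()] for the inverse.
#' @export
to_dimensionless <- function(p) {
  stopifnot(inherits(p, "physical_params"))
  if (p$r <= 0 || p$kon <= 0 || p$kBT <= 0) {
    stop("to_dimensionless(): r, kon and kBT must be positive")
  }
  scales <- characteristic_scales(p)
  params <- dimensionless_params(
    atot = p$Atot / scales$a0,
    nu_p = p$nu / p$r,
    koff_p = p$koff / p$r,
    kon_p = p$kon / p$r,
    omega_p = p$omega / p$r,
    delta = p$Delta / scales$sigma,
    dg = p$DeltaG / p$kBT
  )
  list(params = params, scales = scales)
}

#' Reconstruct physical parameters from dimensionless ones
#'
#' Exact inverse of [to_dimensionless()] given the dimensional anchors
#' `gamma`, `kBT` and `r` that the dimensionless form cannot retain.
#'
#' @param d A [dimensionless_params()] object.
#' @param scales A [characteristic_scales()] object.
#' @param anchors Named list with elements `gamma` (N s/m), `kBT` (pN nm)
#'   and `r` (1/s).
#' @return A [physical_params()] object.
#' @export
from_dimensionless <- function(d, scales, anchors) {
  stopifnot(inherits(d, "dimensionless_params"),
            inherits(scales, "characteristic_scales"))
  need <- c("gamma", "kBT", "r")
  if (!all(need %in% names(anchors))) {
    stop("from_dimensionless(): anchors must supply gamma, kBT and r")
  }
  if (any(unlist(anchors[need]) <= 0)) {
    stop("from_dimensionless(): anchors must be positive")
  }
  k_spring <- anchors$kBT / scales$sigma^2
  physical_params(
    kBT = anchors$kBT, k_spring = k_spring, r = anchors$r,
    nu = d$nu_p * anchors$r, koff = d$koff_p * anchors$r,
    kon = d$kon_p * anchors$r, omega = d$omega_p * anchors$r,
    Delta = d$delta * scales$sigma, Atot = d$atot * scales$a0,
    DeltaG = d$dg * anchors$kBT, gamma = anchors$gamma
  )
}

#' Read a parameter file
#'
#' Reads a YAML parameter file containing exactly one of the top-level
#' blocks `physical` or `dimensionless`; returns the corresponding
#' dimensionless parameter set (physical blocks are converted).
#'
#' @param path Path to a YAML file.
#' @return A [dimensionless_params()] object.  For a `physical` block the
#'   characteristic scales are attached as attribute `"scales"`.
#' @export
read_params <- function(path) {
  cfg <- yaml::read_yaml(path)
  has_phys <- !is.null(cfg$physical)
  has_dim <- !is.null(cfg$dimensionless)
  if (has_phys == has_dim) {
    stop("read_params(): exactly one of 'physical' or 'dimensionless' must be present")
  }
  if (has_dim) {
    do.call(dimensionless_params, cfg$dimensionless)
  } else {
    conv <- to_dimensionless(do.call(physical_params, cfg$physical))
    structure(conv$params, scales = conv$scales)
  }
}
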