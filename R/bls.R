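#' Bilayer-sonophore parameter set
#'
#' Physical constants of the intramembrane-cavitation (bilayer sonophore)
#' model: a nanoscale gas-filled cavity between the two phospholipid leaflets
#' whose ultrasound-driven oscillation modulates the membrane capacitance.
#' Two derived quantities are computed on construction:
#'
#' * `Delta`, the resting inter-leaflet gap, is the root of the resting
#'   molecular-pressure balance
#'   `Ar * ((delta_star/Delta)^x - (delta_star/Delta)^y) = P0`
#'   (residual checked to < 1e-6 * P0);
#' * `Cg = P0 / kH`, the dissolved-gas concentration at Henry equilibrium
#'   with the ambient pressure.
#'
#' The inter-leaflet molecular pressure `PM(Z)` is evaluated by
#' Gauss-Legendre quadrature over the leaflet and tabulated on a fine
#' deflection grid once per parameter set; the integrators interpolate that
#' table.
#'
#' @param a sonophore radius, m
#' @param T temperature, K
#' @param Rg universal gas constant, Pa m^3 / (mol K)
#' @param Ar intermolecular pressure coefficient, Pa
#' @param x_rep,y_att repulsion / attraction exponents
#' @param delta_star molecular-pressure length scale, m
#' @param P0 ambient (extramembrane) pressure, Pa
#' @param ks areal compression modulus of a leaflet, N/m
#' @param eps0,eps_r vacuum and relative permittivity
#' @param rho_l density of the extramembrane medium, kg/m^3
#' @param mu_l,mu_s viscosity of the extramembrane medium / of the leaflets,
#'   Pa s
#' @param delta0 leaflet thickness, m
#' @param Dgl air diffusion coefficient, m^2/s
#' @param xi boundary-layer thickness for gas transport, m
#' @param Cm0 resting membrane capacitance, F/m^2 (1 uF/cm^2 = 1e-2 F/m^2)
#' @param kH Henry's constant, Pa m^3 / mol
#' @param pm_nodes Gauss-Legendre node count of the molecular-pressure
#'   quadrature
#' @param pm_grid_n,pm_zmax size and upper deflection bound of the tabulated
#'   PM grid
#' @return an object of class `tfus_bls`
#' @export
bls_params <- function(a = 32e-9, T = 309.15, Rg = 8.314, Ar = 1e5,
                       x_rep = 5, y_att = 3.3, delta_star = 1.4e-9, P0 = 1e5,
                       ks = 0.24, eps0 = 8.854e-12, eps_r = 1, rho_l = 1075,
                       mu_l = 7e-4, mu_s = 0.035, delta0 = 2e-9,
                       Dgl = 3.6e-9, xi = 0.5e-9, Cm0 = 1e-2, kH = 1.613e5,
                       pm_nodes = 64, pm_grid_n = 360000, pm_zmax = 96e-9) {
  p <- list(a = a, T = T, Rg = Rg, Ar = Ar, x_rep = x_rep, y_att = y_att,
            delta_star = delta_star, P0 = P0, ks = ks, eps0 = eps0,
            eps_r = eps_r, rho_l = rho_l, mu_l = mu_l, mu_s = mu_s,
            delta0 = delta0, Dgl = Dgl, xi = xi, Cm0 = Cm0, kH = kH)
  bad <- names(p)[!vapply(p, function(v) is.numeric(v) && v > 0, logical(1))]
  if (length(bad))
    stop("bls_params: non-positive value for ", paste(bad, collapse = ", "))
  # resting gap from the molecular-pressure balance against P0
  bal <- function(D) Ar * ((delta_star / D)^x_rep - (delta_star / D)^y_att) - P0
  p$Delta <- uniroot(bal, c(delta_star / 4, delta_star * 0.999999),
                     tol = 1e-18)$root
  if (abs(bal(p$Delta)) >= 1e-6 * P0)
    stop("bls_params: resting-gap root residual exceeds 1e-6 * P0")
  p$Cg <- P0 / kH
  p$pm_nodes <- as.integer(pm_nodes)
  zg <- seq(-0.4995 * p$Delta, pm_zmax, length.out = pm_grid_n)
  pm <- pm_profile_cpp(zg, p, p$pm_nodes)
  p$pm_z <- zg
  p$pm_val <- pm
  structure(p, class = "tfus_bls")
}

#' @export
print.tfus_bls <- function(x, ...) {
  cat(sprintf("<tfus_bls> a = %g nm, Delta = %.4f nm, Cm0 = %g uF/cm^2\n",
              x$a * 1e9, x$Delta * 1e9, x$Cm0 * 1e2))
  invisible(x)
}

#' Membrane capacitance at a given apex deflection
#'
#' Deflection-dependent capacitance of the sonophore-bearing membrane patch;
#' tends to `Cm0` as `Z -> 0` and decreases as the leaflets bow apart.
#'
#' @param Z apex deflection(s), m (must stay above `-Delta/2`)
#' @param params a [bls_params()]
#' @return capacitance in F/m^2
#' @export
membrane_capacitance <- function(Z, params) {
  stopifnot(inherits(params, "tfus_bls"))
  if (any(Z <= -params$Delta / 2))
    stop("mechanical failure: Z at or below -Delta/2")
  cm_cpp(Z, params)
}

#' Inter-leaflet molecular pressure
#'
#' Direct Gauss-Legendre evaluation of the repulsion/attraction pressure
#' integrated over the leaflet (no table interpolation); used to validate the
#' tabulated profile.
#'
#' @param Z apex deflection(s), m
#' @param params a [bls_params()]
#' @param nodes quadrature nodes (defaults to the configured count)
#' @return pressure in Pa
#' @export
molecular_pressure <- function(Z, params, nodes = NULL) {
  stopifnot(inherits(params, "tfus_bls"))
  pm_profile_cpp(Z, params, as.integer(nodes %||% params$pm_nodes))
}

#' Quasi-static equilibrium deflection at a given membrane charge
#'
#' Deflection at which the molecular, electrostatic and tension pressures
#' balance with the gas at Henry equilibrium (`Pin = P0`).
#'
#' @param Qm membrane charge density, C/m^2
#' @param params a [bls_params()]
#' @return deflection in m
#' @export
bls_equilibrium <- function(Qm, params) {
  stopifnot(inherits(params, "tfus_bls"))
  bls_equilibrium_cpp(Qm, params)
}
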