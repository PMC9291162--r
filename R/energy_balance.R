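#' Saturation vapour pressure of water
#'
#' Tetens-form saturation curve, used for the leaf-internal air space
#' (assumed saturated at leaf temperature) and for ambient vapour pressure
#' from relative humidity.
#'
#' @param t temperature, deg C (valid -20..60).
#' @return saturation vapour pressure, kPa.
#' @export
#' @examples
#' saturation_vapor_pressure(28) # ~3.78 kPa; at RH 0.65 the VPD is ~1.32
saturation_vapor_pressure <- function(t) {
  if (any(t <= -20 | t >= 60)) {
    abort("temperature outside (-20, 60) C", class = "c4dyn_domain_error")
  }
  0.61078 * exp(17.27 * t / (t + 237.3))
}

#' Leaf boundary-layer conductance to water vapour
#'
#' Both forced and free convection are considered; the boundary-layer
#' conductance is the maximum of the two. The forced term grows with the
#' square root of wind speed and the free term with the quarter power of the
#' leaf-air temperature difference. A small
#' floor prevents a zero conductance in the still-air isothermal case.
#'
#' @param t_air,t_leaf air and leaf temperature (deg C).
#' @param u wind speed (m s-1), >= 0.
#' @param d_o characteristic leaf dimension (m), > 0.
#' @param pa atmospheric pressure (kPa).
#' @param c_f,c_e forced/free convection coefficients.
#' @param gb_floor lower bound on the returned conductance (mol m-2 s-1).
#' @return boundary-layer conductance to H2O, mol m-2 s-1.
#' @export
boundary_layer_conductance <- function(t_air, t_leaf, u, d_o, pa,
                                       c_f = 4.322e-3, c_e = 1.6361e-3,
                                       gb_floor = 1e-4) {
  if (any(u < 0)) abort("wind speed must be >= 0", class = "c4dyn_domain_error")
  if (any(d_o <= 0)) abort("leaf dimension must be > 0",
                           class = "c4dyn_domain_error")
  ta_k <- t_air + 273.15
  tl_k <- t_leaf + 273.15
  g_bf <- c_f * ta_k^0.56 * ((ta_k + 120) * (u / d_o / pa))^0.5
  g_br <- c_e * tl_k^0.56 * ((tl_k + 120) / pa)^0.5 *
    abs(t_leaf - t_air)^0.25
  pmax(pmax(g_bf, g_br), gb_floor)
}

#' Rate of leaf temperature change from the energy balance
#'
#' Leaf temperature is a dynamic state: the net energy flux (absorbed
#' radiation minus sensible heat, latent heat, net long-wave exchange and
#' the energy consumed by photosynthesis) divided by the areal heat capacity
#' of the leaf. Absorbed PAR converts quantum flux to energy (0.2175 J per
#' umol photons) before applying the 0.85 leaf absorptance. The long-wave
#' term is the net exchange with surroundings at air temperature,
#' `2 eps sigma (T_leaf^4 - T_air^4)`, which is the closure consistent with
#' setting absorbed NIR and long-wave inputs to zero.
#'
#' @param t_leaf,t_air leaf and air temperature (deg C).
#' @param par photosynthetic photon flux (umol m-2 s-1).
#' @param rh relative humidity (fraction).
#' @param u wind speed (m s-1).
#' @param gs stomatal conductance to H2O (mol m-2 s-1), >= 0.
#' @param a net CO2 uptake (umol m-2 s-1); the energy stored by
#'   photosynthesis is `0.506 * a` W m-2.
#' @param p energy-balance parameter list (see `network_defaults()$energy_balance`).
#' @param pa atmospheric pressure (kPa).
#' @return d T_leaf / dt, deg C s-1.
#' @export
leaf_temperature_rate <- function(t_leaf, t_air, par, rh, u, gs, a, p,
                                  pa = 101.325) {
  if (any(gs < 0)) abort("gs must be >= 0", class = "c4dyn_domain_error")
  g_b <- boundary_layer_conductance(t_air, t_leaf, u, p$d_leaf, pa,
                                    p$c_f, p$c_e, p$gb_floor)
  g_bh <- 0.924 * g_b
  par_abs <- p$absorptance_par * par * p$par_to_watts
  h <- 2 * p$cp_air * g_bh * (t_leaf - t_air)
  g_l <- ifelse(gs > 0, 1 / (1 / gs + 1 / g_b), 0)
  e_sat_leaf <- saturation_vapor_pressure(t_leaf)
  e_air <- rh * saturation_vapor_pressure(t_air)
  le <- p$c_lv * g_l / pa * (e_sat_leaf - e_air)
  e_emit <- 2 * p$emissivity * p$sigma *
    ((t_leaf + 273.15)^4 - (t_air + 273.15)^4)
  me <- 0.506 * a
  net <- par_abs + p$nir + p$lr - (h + le + e_emit + me)
  net / (p$cp_leaf * p$m_leaf)
}
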