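#' PPDK regulatory protein (PDRP) reaction rates
#'
#' PDRP is a bifunctional protein kinase/phosphatase that interconverts
#' active PPDK (E) and phospho-inactivated PPDK (EP) in the mesophyll
#' chloroplast. Inactivation (the kinase reaction) requires ADP as the
#' phosphoryl donor and is competitively inhibited by pyruvate; activation
#' (the phosphorolytic phosphatase reaction) requires inorganic phosphate
#' and is inhibited by ADP. Both rates are first order in PDRP content, so
#' the PDRP concentration sets the speed of light-dark switching of PPDK.
#'
#' @param pdrp list of PDRP kinetic constants: `kcat_i`, `kcat_a` (s-1),
#'   `km_ppdk_i`, `km_adp_i`, `ki_pyr_i`, `km_ppdk_a`, `km_pi_a`,
#'   `ki_adp_a` (mM).
#' @param pdrp_conc PDRP concentration in the mesophyll chloroplast (mM).
#' @param e,ep active and phospho-inactive PPDK concentrations (mM).
#' @param adp,pyr,pi ADP, pyruvate and Pi concentrations (mM) in the
#'   mesophyll chloroplast.
#' @return list with elements `v_inact` and `v_act` (mM s-1). The PPDK pair
#'   evolves as `dE/dt = v_act - v_inact`, which conserves E + EP.
#' @export
#' @examples
#' p <- network_defaults()$pdrp_kinetics
#' pdrp_rates(p, 0.006, e = 0.8, ep = 0.2, adp = 0.5, pyr = 1, pi = 10)
pdrp_rates <- function(pdrp, pdrp_conc, e, ep, adp, pyr, pi) {
  if (min(e, ep, adp, pyr, pi) < 0) {
    abort("pdrp_rates: concentrations must be non-negative",
          class = "c4dyn_domain_error")
  }
  v_inact <- pdrp_conc * pdrp$kcat_i *
    (e / (e + pdrp$km_ppdk_i)) *
    (adp / (adp + pdrp$km_adp_i * (1 + pyr / pdrp$ki_pyr_i)))
  v_act <- pdrp_conc * pdrp$kcat_a *
    (ep / (ep + pdrp$km_ppdk_a * (1 + adp / pdrp$ki_adp_a))) *
    (pi / (pi + pdrp$km_pi_a))
  list(v_inact = v_inact, v_act = v_act)
}

#' Total Rubisco activase content implied by the activation time constant
#'
#' The measured Rubisco activation time constant is inversely proportional
#' to leaf Rubisco activase content: `[Rca] = k / tau`, with
#' k = 216.9 min mg m-2.
#'
#' @param tau_rubisco Rubisco activation time constant (min).
#' @param k_rca the proportionality constant (min mg m-2).
#' @return Rca content, mg m-2.
#' @export
#' @examples
#' rca_total_from_tau(3.881) # maize
rca_total_from_tau <- function(tau_rubisco, k_rca = 216.9) {
  if (any(tau_rubisco <= 0)) {
    abort("tau_rubisco must be positive", class = "c4dyn_domain_error")
  }
  k_rca / tau_rubisco
}

#' Steady-state (target) Rubisco activity under a given light level
#'
#' The steady-state maximal Rubisco activity saturates with the content of
#' *active* activase, `Rca_A = Rca_total * a_rca`, with half-saturation
#' constant 12.3 mg m-2; the active fraction `a_rca` follows the generic
#' clamped-linear light response.
#'
#' @param vmax_full fully activated Rubisco capacity (umol m-2 s-1).
#' @param rca_total total activase content (mg m-2).
#' @param a_rca active fraction of activase in `[0, 1]`.
#' @param k_activase half-saturation constant (mg m-2).
#' @return target Rubisco activity, umol m-2 s-1; monotone in both
#'   `a_rca` and `rca_total`.
#' @export
rubisco_target_vmax <- function(vmax_full, rca_total, a_rca,
                                k_activase = 12.3) {
  rca_a <- rca_total * pmin(pmax(a_rca, 0), 1)
  vmax_full * rca_a / (k_activase + rca_a)
}

#' First-order approach of a transient activity to its target
#'
#' All post-translational activation states in the model relax exponentially
#' towards their light-dependent steady-state targets:
#' `d v / dt = (target - v) / tau`.
#'
#' @param current transient value.
#' @param target steady-state target.
#' @param tau time constant (min).
#' @return rate of change, per minute.
#' @export
first_order_activation <- function(current, target, tau) {
  if (any(tau <= 0)) {
    abort("tau must be positive", class = "c4dyn_domain_error")
  }
  (target - current) / tau
}

#' Steady-state activation fraction under light
#'
#' Clamped-linear light response of the activation state of a
#' light-regulated enzyme: `a_s = min(k_a * I + c_a, 1)`.
#'
#' @param i photosynthetic photon flux density (umol m-2 s-1), >= 0.
#' @param k_a slope ((umol m-2 s-1)-1).
#' @param c_a intercept (dark activation fraction), in `[0, 1]`.
#' @return activation fraction in `[c_a, 1]`.
#' @export
steady_activation_fraction <- function(i, k_a, c_a) {
  if (any(i < 0)) abort("light intensity must be >= 0",
                        class = "c4dyn_domain_error")
  pmin(k_a * i + c_a, 1)
}

#' Temperature scaling factor for enzymatic parameters
#'
#' Three response forms are used, all normalized to 1 at 25 C:
#' \describe{
#'   \item{`arrhenius`}{`exp(Ea (T - 25) / (298.15 R T_K))`.}
#'   \item{`peaked_arrhenius`}{the Arrhenius rise multiplied by a
#'     high-temperature deactivation ratio governed by `Hd` and `dS`.}
#'   \item{`q10`}{`Q10^((T - 25)/10)`.}
#' }
#'
#' @param tr list describing the response: `form` (one of
#'   `"peaked_arrhenius"`, `"arrhenius"`, `"q10"`) plus `ea`, `hd`, `ds`
#'   (J mol-1, J mol-1, J mol-1 K-1) or `q10` as required by the form.
#' @param t_leaf leaf temperature (deg C).
#' @return dimensionless multiplicative factor.
#' @export
#' @examples
#' temperature_scale(list(form = "q10", q10 = 2), 35) # == 2
temperature_scale <- function(tr, t_leaf) {
  if (any(t_leaf < -10 | t_leaf > 60)) {
    abort("t_leaf outside plausible range (-10..60 C)",
          class = "c4dyn_domain_error")
  }
  tk <- t_leaf + 273.15
  switch(tr$form,
    q10 = tr$q10^((t_leaf - 25) / 10),
    arrhenius = exp(tr$ea * (t_leaf - 25) / (T_REF_K * R_GAS * tk)),
    peaked_arrhenius = {
      rise <- exp(tr$ea * (t_leaf - 25) / (T_REF_K * R_GAS * tk))
      num <- 1 + exp((T_REF_K * tr$ds - tr$hd) / (T_REF_K * R_GAS))
      den <- 1 + exp((tk * tr$ds - tr$hd) / (tk * R_GAS))
      rise * num / den
    },
    abort(paste0("unsupported temperature response form: ", tr$form),
          class = "c4dyn_config_error")
  )
}
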