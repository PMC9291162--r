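# Reduced-order NADP-ME C4 metabolic network.
#
# Two cell types (mesophyll M, bundle sheath BS), four compartments
# (cytosol/chloroplast in each; pools are lumped per cell except the
# energy/redox pools, which live in the chloroplast stroma). Concentrations
# in mM, fluxes in umol m-2 s-1 (leaf area), compartment volumes in L m-2.

# metabolite states, in order
MET_NAMES <- c(
  "co2_m", "hco3_m", "pep_m", "pyr_m", "oaa_m", "mal_m", "pga_m", "t3p_m",
  "atp_m", "adp_m", "nadph_m", "nadp_m", "pi_m",
  "co2_b", "mal_b", "pyr_b", "pga_b", "t3p_b", "rubp_b", "ru5p_b", "hep_b",
  "atp_b", "adp_b", "nadph_b", "nadp_b")

# dynamic regulation + physiology states appended to the metabolites
REG_NAMES <- c("e_ppdk", "ep_ppdk", "r_rub", "a_atpase", "a_fbpase",
               "a_gapdh", "a_prk", "a_rca", "a_sbpase", "a_pepc",
               "gs", "tleaf")

STATE_NAMES <- c(MET_NAMES, REG_NAMES)

# reaction/transport steps, in FluxVector order
RXN_NAMES <- c(
  "v_stomatal_co2_influx", "v_ca", "v_pepc", "v_mdh", "v_ppdk", "v_me",
  "v_rubisco_c", "v_gapdh_m", "v_gapdh_b", "v_fbpase", "v_sbpase", "v_prk",
  "v_mutase_enolase", "v_lr_m", "v_lr_b", "v_atps_m", "v_nox_m", "v_nox_b",
  "v_starch_mob", "v_glyc_pga", "v_maint_m", "v_maint_b", "v_pyr_decay", "v_oaa_decay",
  "v_t_mal", "v_t_pyr", "v_t_pga",
  "v_t_t3p", "v_co2_leak", "v_export", "v_rd")

# enzymes that must carry an activity entry (the flux-control set plus the
# thylakoid ATPase driving the light reactions)
ACTIVITY_NAMES <- c("pepc", "ppdk", "mdh", "me", "mutase_enolase", "rubisco",
                    "gapdh", "fbpase", "sbpase", "prk", "atpase")

# carbon atoms carried by each metabolite
CARBON_PER_MET <- c(
  co2_m = 1, hco3_m = 1, pep_m = 3, pyr_m = 3, oaa_m = 4, mal_m = 4,
  pga_m = 3, t3p_m = 3, atp_m = 0, adp_m = 0, nadph_m = 0, nadp_m = 0,
  pi_m = 0, co2_b = 1, mal_b = 4, pyr_b = 3, pga_b = 3, t3p_b = 3,
  rubp_b = 5, ru5p_b = 5, hep_b = 6, atp_b = 0, adp_b = 0, nadph_b = 0,
  nadp_b = 0)

#' Stoichiometry matrix of the reduced network
#'
#' Rows are the 25 metabolite states, columns the 30 reaction/transport
#' steps in `FluxVector` order. Metabolite derivatives are
#' `S %*% v / compartment volume`.
#'
#' @return numeric matrix with dimnames (metabolite x reaction).
#' @export
stoich_matrix <- function() {
  S <- matrix(0, length(MET_NAMES), length(RXN_NAMES),
              dimnames = list(MET_NAMES, RXN_NAMES))
  put <- function(rxn, ...) {
    d <- c(...)
    S[names(d), rxn] <<- d
  }
  put("v_stomatal_co2_influx", co2_m = 1)
  put("v_ca", co2_m = -1, hco3_m = 1)
  put("v_pepc", hco3_m = -1, pep_m = -1, oaa_m = 1)
  put("v_mdh", oaa_m = -1, mal_m = 1, nadph_m = -1, nadp_m = 1)
  put("v_ppdk", pyr_m = -1, pep_m = 1, atp_m = -2, adp_m = 2, pi_m = 2)
  put("v_me", mal_b = -1, pyr_b = 1, co2_b = 1, nadph_b = 1, nadp_b = -1)
  put("v_rubisco_c", rubp_b = -1, co2_b = -1, pga_b = 2)
  put("v_gapdh_m", pga_m = -1, t3p_m = 1, atp_m = -1, adp_m = 1, pi_m = 1,
      nadph_m = -1, nadp_m = 1)
  put("v_gapdh_b", pga_b = -1, t3p_b = 1, atp_b = -1, adp_b = 1,
      nadph_b = -1, nadp_b = 1)
  put("v_fbpase", t3p_b = -2, hep_b = 1)
  put("v_sbpase", hep_b = -1, t3p_b = -3, ru5p_b = 3)
  put("v_prk", ru5p_b = -1, rubp_b = 1, atp_b = -1, adp_b = 1)
  put("v_mutase_enolase", pga_m = -1, pep_m = 1)
  put("v_lr_m", nadp_m = -1, nadph_m = 1)
  put("v_lr_b", adp_b = -1, atp_b = 1)
  put("v_atps_m", adp_m = -1, atp_m = 1, pi_m = -1)
  put("v_nox_m", nadph_m = -1, nadp_m = 1)
  put("v_nox_b", nadph_b = -1, nadp_b = 1)
  put("v_starch_mob", hep_b = -1, t3p_b = 2)
  put("v_glyc_pga", t3p_b = -1, pga_b = 1)
  put("v_maint_m", atp_m = -1, adp_m = 1, pi_m = 1)
  put("v_maint_b", atp_b = -1, adp_b = 1)
  put("v_pyr_decay", pyr_m = -1, co2_m = 3)
  put("v_oaa_decay", oaa_m = -1, co2_m = 4)
  put("v_t_mal", mal_m = -1, mal_b = 1)
  put("v_t_pyr", pyr_b = -1, pyr_m = 1)
  put("v_t_pga", pga_b = -1, pga_m = 1)
  put("v_t_t3p", t3p_m = -1, t3p_b = 1)
  put("v_co2_leak", co2_b = -1, co2_m = 1)
  put("v_export", t3p_b = -1)
  put("v_rd", co2_m = NA, co2_b = NA) # placeholder, set below
  # Rd splits between the two cell types
  S["co2_m", "v_rd"] <- NA_real_
  S["co2_b", "v_rd"] <- NA_real_
  S
}

# Rd partitioning depends on rd_frac_bs, resolved in the derivative assembly;
# the matrix form used numerically carries the split explicitly.
stoich_with_rd <- function(rd_frac_bs) {
  S <- stoich_matrix()
  S["co2_m", "v_rd"] <- 1 - rd_frac_bs
  S["co2_b", "v_rd"] <- rd_frac_bs
  S
}

# flatten the nested parameter list into the cache used by the RHS
build_param_cache <- function(params) {
  g <- params$geometry
  k <- params$km
  v <- params$vmax
  s4 <- params$scale_c4
  s3 <- params$scale_c3
  mult <- params$vmax_mult
  if (is.null(mult)) mult <- numeric(0)
  m <- function(enz) if (enz %in% names(mult)) mult[[enz]] else 1
  list(
    vols = {
      vv <- c(rep(g$vol_m_cyt, 8), rep(g$vol_m_chl, 5),
              rep(g$vol_b_cyt, 3), rep(g$vol_b_chl, 9)) |>
        setNames(MET_NAMES)
      # CO2 equilibrates with a larger bicarbonate pool in the bundle sheath
      vv[["co2_b"]] <- vv[["co2_b"]] * g$co2_buffer_bs
      vv
    },
    kh_co2 = g$kh_co2,
    o2_factor = g$o2_factor,
    gm = params$conductances$gm,
    gs_min = params$conductances$gs_min,
    p_co2_pd = params$conductances$p_co2_pd * m("p_co2_pd"),
    k_mal = params$conductances$k_mal,
    k_pyr = params$conductances$k_pyr,
    k_pga = params$conductances$k_pga,
    k_t3p = params$conductances$k_t3p,
    vmax_ca = v$ca * s4 * m("ca"),
    vmax_pepc = params$vmax_pepc * m("pepc"),
    vmax_ppdk = v$ppdk * s4 * m("ppdk"),
    vmax_mdh = v$mdh * s4 * m("mdh"),
    vmax_me = v$me * s4 * m("me"),
    vmax_mutase = v$mutase * s4 * m("mutase_enolase"),
    vmax_rubisco = params$vmax_rubisco * m("rubisco"),
    vmax_gapdh_m = v$gapdh_m * s3 * m("gapdh"),
    vmax_gapdh_b = v$gapdh_b * s3 * m("gapdh"),
    vmax_fbpase = v$fbpase * s3 * m("fbpase"),
    vmax_sbpase = v$sbpase * s3 * m("sbpase"),
    vmax_prk = v$prk * s3 * m("prk"),
    vmax_export = v$export * s3,
    vmax_starch_mob = v$starch_mob * s3,
    vmax_glyc = v$glycolysis * s3,
    vmax_atps_m = v$atps_m * s3,
    k_nox = v$nox,
    k_maint = v$maint,
    k_pyr_decay = v$pyr_decay,
    k_oaa_decay = v$oaa_decay,
    jmax_m = v$jmax_m * s3 * m("atpase"),
    jmax_b = v$jmax_b * s3 * m("atpase"),
    km = k,
    rd = params$rd,
    rd_frac_bs = params$pools$rd_frac_bs,
    temp = params$temperature,
    fixed_ci = params$fixed_ci %||% NA_real_
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# temperature factors used by the rate laws, scalar tleaf
temp_factors <- function(temp, tleaf) {
  list(
    pepc = temperature_scale(temp$pepc, tleaf),
    ca = temperature_scale(temp$ca, tleaf),
    ppdk = temperature_scale(temp$ppdk, tleaf),
    jmax = temperature_scale(temp$jmax, tleaf),
    rubisco = temperature_scale(temp$rubisco, tleaf),
    kc = temperature_scale(temp$kc, tleaf),
    q10 = temperature_scale(temp$q10_default, tleaf)
  )
}

# core flux computation; y is the named metabolite vector, act the named
# activity vector (fractions in [0,1] unless stated), env a list with
# par/ca/pa/rh/tair/wind, gs the stomatal conductance (H2O), gb the
# boundary-layer conductance (H2O)
compute_fluxes <- function(y, act, tleaf, gs, gb, env, pc) {
  f <- temp_factors(pc$temp, tleaf)
  k <- pc$km
  mm <- function(s, km) s / (s + km)

  # gas exchange: dissolved CO2 -> partial pressure -> mole fraction
  co2_m_ubar <- y[["co2_m"]] / pc$kh_co2
  cm_ppm <- co2_m_ubar * 100 / env$pa
  if (is.finite(pc$fixed_ci)) {
    v_in <- pc$gm * (pc$fixed_ci - cm_ppm)
  } else {
    g_sc <- 1 / (1.6 / gs + 1.37 / gb)  # CO2 conductance, stomata+boundary
    g_tc <- 1 / (1 / g_sc + 1 / pc$gm)
    v_in <- g_tc * (env$ca - cm_ppm)
  }

  v_ca <- pc$vmax_ca * f$ca * (y[["co2_m"]] - y[["hco3_m"]] / k$keq_ca)
  # PEPC with feedback inhibition by malate
  v_pepc <- pc$vmax_pepc * f$pepc * act[["pepc"]] *
    mm(y[["pep_m"]], k$pepc_pep) * mm(y[["hco3_m"]], k$pepc_hco3) /
    (1 + y[["mal_m"]] / k$ki_pepc_mal)
  v_mdh <- pc$vmax_mdh * f$q10 * act[["mdh"]] *
    mm(y[["oaa_m"]], k$mdh_oaa) * mm(y[["nadph_m"]], k$mdh_nadph)
  v_ppdk <- pc$vmax_ppdk * f$ppdk * act[["ppdk"]] *
    mm(y[["pyr_m"]], k$ppdk_pyr) * mm(y[["atp_m"]], k$ppdk_atp)
  # product inhibition (pyruvate, CO2) feeds bundle-sheath CO2 status back
  # to the C4 pump and self-limits overpumping
  v_me <- pc$vmax_me * f$q10 * act[["me"]] *
    mm(y[["mal_b"]], k$me_mal) * mm(y[["nadp_b"]], k$me_nadp) /
    ((1 + y[["pyr_b"]] / k$ki_me_pyr) * (1 + y[["co2_b"]] / k$ki_me_co2))
  km_co2 <- k$rub_co2 * pc$o2_factor * f$kc
  v_rub <- pc$vmax_rubisco * f$rubisco * act[["rubisco"]] *
    mm(y[["co2_b"]], km_co2) * mm(y[["rubp_b"]], k$rub_rubp)
  v_gapdh_m <- pc$vmax_gapdh_m * f$q10 * act[["gapdh"]] *
    mm(y[["pga_m"]], k$gapdh_pga) * mm(y[["atp_m"]], k$gapdh_atp) *
    mm(y[["nadph_m"]], k$gapdh_nadph)
  v_gapdh_b <- pc$vmax_gapdh_b * f$q10 * act[["gapdh"]] *
    mm(y[["pga_b"]], k$gapdh_pga) * mm(y[["atp_b"]], k$gapdh_atp) *
    mm(y[["nadph_b"]], k$gapdh_nadph)
  # hexose-P feedback keeps the FBPase/SBPase branch point balanced
  v_fbp <- pc$vmax_fbpase * f$q10 * act[["fbpase"]] *
    mm(y[["t3p_b"]], k$fbpase_t3p) / (1 + y[["hep_b"]] / k$ki_fbp_hep)
  v_sbp <- pc$vmax_sbpase * f$q10 * act[["sbpase"]] *
    mm(y[["hep_b"]], k$sbpase_hep) * mm(y[["t3p_b"]], k$sbpase_t3p) /
    (1 + y[["ru5p_b"]] / k$ki_sbp_ru5p)
  # RuBP product inhibition keeps the RuBP pool bounded when Rubisco is
  # CO2- or activation-limited
  v_prk <- pc$vmax_prk * f$q10 * act[["prk"]] *
    mm(y[["ru5p_b"]], k$prk_ru5p) * mm(y[["atp_b"]], k$prk_atp) /
    (1 + y[["rubp_b"]] / k$ki_prk_rubp)
  # reversible (equilibrium strongly favours PGA)
  v_mut <- pc$vmax_mutase * f$q10 * act[["mutase_enolase"]] *
    (y[["pga_m"]] - y[["pep_m"]] / k$keq_mutase) /
    (k$mutase_pga + y[["pga_m"]] + y[["pep_m"]] / k$keq_mutase)
  light <- env$par / (env$par + k$light_i)
  # electron transport: NADPH output gated by NADP pool and light; ATP
  # synthesis (thylakoid ATPase, linear + cyclic flow) gated by ADP
  v_lr_m <- pc$jmax_m * f$jmax * light * mm(y[["nadp_m"]], k$lr_nadp)
  v_lr_b <- pc$jmax_b * f$jmax * act[["atpase"]] * light *
    mm(y[["adp_b"]], k$lr_adp)
  v_atps_m <- pc$vmax_atps_m * f$jmax * act[["atpase"]] * light *
    mm(y[["adp_m"]], k$lr_adp)
  v_nox_m <- pc$k_nox * y[["nadph_m"]]
  v_nox_b <- pc$k_nox * y[["nadph_b"]]
  v_starch <- pc$vmax_starch_mob * f$q10 * mm(y[["hep_b"]], k$starch_hep)
  # cytosolic/NAD glycolysis sustains PGA (and hence PEP) in darkness
  v_glyc <- pc$vmax_glyc * f$q10 * mm(y[["t3p_b"]], k$glyc_t3p)
  v_maint_m <- pc$k_maint * y[["atp_m"]]
  v_maint_b <- pc$k_maint * y[["atp_b"]]
  # respiratory consumption keeps the C4 acid pools near zero in darkness
  v_pyr_decay <- pc$k_pyr_decay * y[["pyr_m"]]
  v_oaa_decay <- pc$k_oaa_decay * y[["oaa_m"]]
  v_t_mal <- pc$k_mal * (y[["mal_m"]] - y[["mal_b"]])
  v_t_pyr <- pc$k_pyr * (y[["pyr_b"]] - y[["pyr_m"]])
  v_t_pga <- pc$k_pga * (y[["pga_b"]] - y[["pga_m"]])
  v_t_t3p <- pc$k_t3p * (y[["t3p_m"]] - y[["t3p_b"]])
  v_leak <- pc$p_co2_pd * (y[["co2_b"]] - y[["co2_m"]])
  # sigmoidal in triose-P: export shuts off when the cycle runs low
  v_exp <- pc$vmax_export * f$q10 * y[["t3p_b"]]^2 /
    (k$export_t3p^2 + y[["t3p_b"]]^2)

  c(v_stomatal_co2_influx = v_in, v_ca = v_ca, v_pepc = v_pepc,
    v_mdh = v_mdh, v_ppdk = v_ppdk, v_me = v_me, v_rubisco_c = v_rub,
    v_gapdh_m = v_gapdh_m, v_gapdh_b = v_gapdh_b, v_fbpase = v_fbp,
    v_sbpase = v_sbp, v_prk = v_prk, v_mutase_enolase = v_mut,
    v_lr_m = v_lr_m, v_lr_b = v_lr_b, v_atps_m = v_atps_m,
    v_nox_m = v_nox_m, v_nox_b = v_nox_b, v_starch_mob = v_starch,
    v_glyc_pga = v_glyc, v_maint_m = v_maint_m, v_maint_b = v_maint_b,
    v_pyr_decay = v_pyr_decay, v_oaa_decay = v_oaa_decay, v_t_mal = v_t_mal,
    v_t_pyr = v_t_pyr, v_t_pga = v_t_pga, v_t_t3p = v_t_t3p,
    v_co2_leak = v_leak, v_export = v_exp, v_rd = pc$rd)
}

check_activities <- function(activities) {
  absent <- setdiff(ACTIVITY_NAMES, names(activities))
  if (length(absent) > 0) {
    abort(paste0("missing activity entry for enzyme(s): ",
                 paste(absent, collapse = ", ")),
          class = "c4dyn_config_error")
  }
  invisible(TRUE)
}

#' Reaction and transport rates of the metabolic network
#'
#' Evaluates every rate law of the reduced NADP-ME network at a given
#' metabolic state, set of enzyme activities and leaf temperature. Each
#' enzymatic rate scales linearly with its transient capacity (activity
#' times Vmax); the plasmodesmatal CO2 leak is
#' `P_CO2_pd ([CO2]_BSC - [CO2]_MC)`.
#'
#' @param state data frame or named vector with the 25 metabolite
#'   concentrations (mM); see `c4dyn:::MET_NAMES`.
#' @param activities named vector/list of activity fractions for
#'   `pepc, ppdk, mdh, me, mutase_enolase, rubisco, gapdh, fbpase, sbpase,
#'   prk, atpase`. A missing entry is a configuration error naming the
#'   enzyme.
#' @param t_leaf leaf temperature (deg C).
#' @param params model parameters from [c4_params()].
#' @param gs stomatal conductance to H2O (mol m-2 s-1).
#' @param env environment list (`par`, `ca`, `rh`, `tair`, `wind`, `pa`);
#'   defaults to the configured chamber conditions.
#' @return tibble with columns `reaction` and `flux` (umol m-2 s-1), one
#'   row per step in `FluxVector` order.
#' @export
reaction_rates <- function(state, activities, t_leaf, params = c4_params(),
                           gs = 0.3, env = NULL) {
  check_activities(activities)
  if (is.data.frame(state)) state <- unlist(state[1, , drop = FALSE])
  state <- state[MET_NAMES]
  if (anyNA(state)) {
    abort("state is missing metabolite entries", class = "c4dyn_config_error")
  }
  if (any(state < 0)) {
    abort("metabolite concentrations must be >= 0",
          class = "c4dyn_domain_error")
  }
  if (is.null(env)) {
    env <- network_defaults()$environment_defaults
    env$par <- 1800
  }
  pc <- build_param_cache(params)
  gb <- boundary_layer_conductance(env$tair, t_leaf, env$wind,
                                   params$energy_balance$d_leaf, env$pa,
                                   gb_floor = params$energy_balance$gb_floor)
  v <- compute_fluxes(state, as.list(activities), t_leaf, gs, gb, env, pc)
  tibble(reaction = names(v), flux = unname(v))
}

#' Time derivatives of the coupled model state
#'
#' Assembles the right-hand side of the full dynamic model: metabolite
#' derivatives (`stoichiometry x fluxes / compartment volume`), the PDRP
#' interconversion of PPDK, first-order enzyme activation, stomatal
#' dynamics and the leaf energy balance. Exposed mainly for testing; use
#' [c4_simulate()] to integrate.
#'
#' @param t time (s).
#' @param state full named state vector (`c4dyn:::STATE_NAMES`).
#' @param params model parameters from [c4_params()].
#' @param forcing forcing object from [c4_forcing()].
#' @param scenario scenario flag list from [c4_scenario()].
#' @return list: derivative vector, then named diagnostic/global values
#'   (A, Ci, phi and all fluxes), as used by `deSolve`.
#' @export
derivatives <- function(t, state, params, forcing, scenario = c4_scenario(6)) {
  ctx <- make_rhs_context(params, scenario)
  ctx$rhs(t, state, forcing)
}

# builds a closure evaluating the RHS quickly; called once per simulation
make_rhs_context <- function(params, scenario) {
  pc <- build_param_cache(params)
  S <- stoich_with_rd(params$pools$rd_frac_bs)
  vols <- pc$vols
  eb <- params$energy_balance
  la <- params$light_activation
  pdrp <- params$pdrp_kinetics
  pdrp_conc <- params$pdrp_conc
  rca_total <- params$rca_total
  k_activase <- params$rubisco_activation$k_activase
  tau_rub_s <- params$tau_rubisco * 60
  ki <- params$gs_ki
  kd <- params$gs_kd
  slope_bb <- params$slope_bb
  intercept_bb <- params$intercept_bb
  la_enz <- c("atpase", "fbpase", "gapdh", "prk", "rca", "sbpase", "pepc")
  la_tau <- vapply(la_enz, function(e) la[[e]]$tau * 60, 0)
  la_k <- vapply(la_enz, function(e) la[[e]]$k_a, 0)
  la_c <- vapply(la_enz, function(e) la[[e]]$c_a, 0)
  nmet <- length(MET_NAMES)

  rhs <- function(t, y, forcing) {
    env <- forcing_at(forcing, t)
    ym <- y[seq_len(nmet)]
    names(ym) <- MET_NAMES
    gs <- y[["gs"]]
    tleaf <- y[["tleaf"]]

    frac_ppdk <- if (scenario$dynamic_ppdk) {
      y[["e_ppdk"]] / (y[["e_ppdk"]] + y[["ep_ppdk"]])
    } else 1
    r_rub <- if (scenario$dynamic_rubisco) y[["r_rub"]] else 1
    a_of <- function(e) if (scenario$dynamic_other) y[[paste0("a_", e)]] else 1
    act <- list(
      pepc = a_of("pepc"), ppdk = frac_ppdk, mdh = 1, me = 1,
      mutase_enolase = 1, rubisco = r_rub, gapdh = a_of("gapdh"),
      fbpase = a_of("fbpase"), sbpase = a_of("sbpase"), prk = a_of("prk"),
      atpase = a_of("atpase"))

    gb <- boundary_layer_conductance(env$tair, tleaf, env$wind, eb$d_leaf,
                                     env$pa, eb$c_f, eb$c_e, eb$gb_floor)
    v <- compute_fluxes(ym, act, tleaf, gs, gb, env, pc)
    if (anyNA(v) || any(!is.finite(v))) {
      bad <- RXN_NAMES[!is.finite(v)]
      abort(paste0("non-finite flux in reaction(s): ",
                   paste(bad, collapse = ", "), " at t = ", signif(t, 6)),
            class = "c4dyn_integration_error")
    }
    dmet <- as.vector(S %*% v) / vols / 1000  # umol m-2 s-1 -> mM s-1

    # PDRP-mediated PPDK interconversion (mesophyll chloroplast, mM s-1)
    if (scenario$dynamic_ppdk) {
      pr <- pdrp_rates(pdrp, pdrp_conc, y[["e_ppdk"]], y[["ep_ppdk"]],
                       adp = max(ym[["adp_m"]], 0),
                       pyr = max(ym[["pyr_m"]], 0),
                       pi = max(ym[["pi_m"]], 0))
      de <- pr$v_act - pr$v_inact
    } else de <- 0

    # Rubisco activation via active Rca
    a_rca_now <- if (scenario$dynamic_other || scenario$dynamic_rubisco) {
      y[["a_rca"]]
    } else 1
    if (scenario$dynamic_rubisco) {
      rca_a <- rca_total * min(max(a_rca_now, 0), 1)
      r_target <- rca_a / (k_activase + rca_a)
      dr <- (r_target - y[["r_rub"]]) / tau_rub_s
    } else dr <- 0

    # generic light activation states (always integrated; only read when
    # the corresponding scenario flag is on)
    a_s <- pmin(la_k * env$par + la_c, 1)
    a_now <- y[paste0("a_", la_enz)]
    da <- (a_s - a_now) / la_tau

    # stomata
    a_net <- v[["v_stomatal_co2_influx"]]
    if (scenario$dynamic_stomata) {
      gs_target <- ball_berry_steady(a_net, env$rh, env$ca,
                                     slope_bb, intercept_bb)
      # stomata do not close completely in darkness: the target is floored
      # at the residual conductance when the light is off
      if (env$par < 1) gs_target <- max(gs_target, pc$gs_min)
      dgs <- gs_rate(gs, gs_target, ki, kd) / 60
    } else dgs <- 0

    dtleaf <- leaf_temperature_rate(tleaf, env$tair, env$par, env$rh,
                                    env$wind, max(gs, 0), a_net, eb, env$pa)

    ci <- if (is.finite(pc$fixed_ci)) pc$fixed_ci else {
      env$ca - a_net * (1.6 / gs + 1.37 / gb)
    }
    phi <- if (v[["v_pepc"]] > 0.1) v[["v_co2_leak"]] / v[["v_pepc"]] else 0

    dy <- c(dmet, de, -de, dr, da, dgs, dtleaf)
    list(dy, c(A = unname(a_net), ci = unname(ci), phi = unname(phi), v))
  }
  list(rhs = rhs, pc = pc, S = S)
}
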