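#' Species parameter sets
#'
#' The eleven leaf-level input parameters of the dynamic model for the three
#' NADP-ME crops (maize, sorghum, sugarcane) plus the literature-derived
#' "original" set used for the scenario analyses. Values are shipped as a
#' plain CSV in `inst/extdata/species_params.csv`.
#'
#' Columns: Ball-Berry slope and intercept (`slope_bb`, `intercept_bb`),
#' stomatal opening/closing rate constants `gs_ki`, `gs_kd` (min-1), maximum
#' PEPC and Rubisco activities from A-Ci fits `vpmax`, `vcmax`
#' (umol m-2 s-1), Rubisco activation time constant `tau_rubisco` (min),
#' model-to-measurement capacity scalars `f_vmpepc`, `f_vmrubisco`, PPDK
#' regulatory protein content `pdrp` (umol m-2) and dark respiration `rd`
#' (umol m-2 s-1).
#'
#' @param species optional character vector to filter by species name.
#' @return a tibble, one row per species.
#' @export
#' @examples
#' species_params("maize")
species_params <- function(species = NULL) {
  path <- system.file("extdata", "species_params.csv", package = "c4dyn")
  tab <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  if (!is.null(species)) {
    missing <- setdiff(species, tab$species)
    if (length(missing) > 0) {
      abort(paste0("unknown species: ", paste(missing, collapse = ", "),
                   " (available: ", paste(tab$species, collapse = ", "), ")"),
            class = "c4dyn_unknown_species")
    }
    tab <- tab[match(species, tab$species), ]
  }
  tab
}

#' Network and physics defaults
#'
#' Reads (and caches) the kinetic, regulatory, energy-balance and solver
#' defaults of the reduced-order NADP-ME network from the single YAML
#' configuration document shipped with the package.
#'
#' @param path path to an alternative YAML document (defaults to the shipped
#'   one). The document is schema-validated: every required section and key
#'   must be present and positive where positivity is required.
#' @return a nested list.
#' @export
network_defaults <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(the$network)) return(the$network)
    path <- system.file("extdata", "network.yaml", package = "c4dyn")
    cfg <- validate_network(yaml::read_yaml(path))
    the$network <- cfg
    return(cfg)
  }
  validate_network(yaml::read_yaml(path))
}

# required sections and, for flat numeric sections, required keys
.network_schema <- list(
  geometry = c("vol_m_cyt", "vol_m_chl", "vol_b_cyt", "vol_b_chl",
               "kh_co2", "co2_buffer_bs", "o2_factor"),
  conductances = c("gm", "gs_min", "p_co2_pd", "k_mal", "k_pyr", "k_pga", "k_t3p"),
  reference = c("vmax_pepc_ref", "vmax_rubisco_ref"),
  vmax = c("ca", "ppdk", "mdh", "me", "mutase", "gapdh_m", "gapdh_b",
           "fbpase", "sbpase", "prk", "export", "starch_mob", "glycolysis", "jmax_m",
           "jmax_b", "atps_m", "nox", "maint", "pyr_decay", "oaa_decay"),
  km = c("keq_ca", "pepc_pep", "pepc_hco3", "ppdk_pyr", "ppdk_atp",
         "mdh_oaa", "mdh_nadph", "me_mal", "me_nadp", "ki_me_pyr", "ki_me_co2", "rub_co2", "rub_rubp",
         "gapdh_pga", "gapdh_atp", "gapdh_nadph", "fbpase_t3p", "sbpase_hep",
         "sbpase_t3p", "ki_sbp_ru5p", "prk_ru5p", "ki_prk_rubp", "prk_atp", "mutase_pga", "keq_mutase", "ki_fbp_hep",
         "ki_pepc_mal", "export_t3p", "starch_hep", "glyc_t3p", "light_i", "lr_adp",
         "lr_nadp"),
  pools = c("adenylate_m", "adenylate_b", "nadp_m", "nadp_b", "pi_total_m",
            "ppdk_total", "rd_frac_bs"),
  pdrp_kinetics = c("kcat_i", "kcat_a", "km_ppdk_i", "km_adp_i", "ki_pyr_i",
           "km_ppdk_a", "km_pi_a", "ki_adp_a"),
  rubisco_activation = c("k_rca", "k_activase"),
  light_activation = NULL,
  temperature = NULL,
  energy_balance = NULL,
  environment_defaults = c("tair", "rh", "ca", "wind", "pa"),
  initial_state = NULL,
  solver = c("rtol", "atol", "dt_out")
)

validate_network <- function(cfg) {
  for (section in names(.network_schema)) {
    if (is.null(cfg[[section]])) {
      abort(paste0("network config: missing section '", section, "'"),
            class = "c4dyn_config_error")
    }
    keys <- .network_schema[[section]]
    if (!is.null(keys)) {
      absent <- setdiff(keys, names(cfg[[section]]))
      if (length(absent) > 0) {
        abort(paste0("network config: section '", section, "' is missing ",
                     paste(absent, collapse = ", ")),
              class = "c4dyn_config_error")
      }
      vals <- unlist(cfg[[section]][keys])
      if (!is.numeric(vals) || anyNA(vals)) {
        abort(paste0("network config: non-numeric values in '", section, "'"),
              class = "c4dyn_config_error")
      }
      if (section != "environment_defaults" && any(vals < 0)) {
        abort(paste0("network config: negative value in '", section, "'"),
              class = "c4dyn_config_error")
      }
    }
  }
  enz <- c("atpase", "fbpase", "gapdh", "prk", "rca", "sbpase", "pepc")
  absent <- setdiff(enz, names(cfg$light_activation))
  if (length(absent) > 0) {
    abort(paste0("network config: light_activation missing ",
                 paste(absent, collapse = ", ")),
          class = "c4dyn_config_error")
  }
  for (e in enz) {
    la <- cfg$light_activation[[e]]
    if (la$tau <= 0 || la$c_a < 0 || la$c_a > 1 || la$k_a < 0) {
      abort(paste0("network config: invalid light_activation for ", e),
            class = "c4dyn_config_error")
    }
  }
  cfg
}

#' Assemble a full model parameter set
#'
#' Combines a species parameter row (the eleven gas-exchange-derived inputs)
#' with the network defaults into the single list consumed by
#' [c4_simulate()]. Enzyme capacities of the C4 cycle scale with the species
#' PEPC capacity (`vpmax / f_vmpepc`) and those of the Calvin cycle and
#' electron transport with the species Rubisco capacity
#' (`vcmax / f_vmrubisco`), relative to the original parameter set.
#'
#' @param species species name (see [species_params()]) or a one-row data
#'   frame/list with the same fields.
#' @param network network defaults, see [network_defaults()].
#' @param ... named overrides of species-level fields (e.g. `pdrp = 0.08`).
#' @return a list of class `c4_params`.
#' @export
#' @examples
#' p <- c4_params("maize")
#' p$vmax_pepc
c4_params <- function(species = "original", network = network_defaults(), ...) {
  if (is.character(species)) {
    sp <- as.list(species_params(species))
  } else {
    sp <- as.list(species)
  }
  need <- c("slope_bb", "intercept_bb", "gs_ki", "gs_kd", "vpmax", "vcmax",
            "tau_rubisco", "f_vmpepc", "f_vmrubisco", "pdrp", "rd")
  absent <- setdiff(need, names(sp))
  if (length(absent) > 0) {
    abort(paste0("species parameters missing: ", paste(absent, collapse = ", ")),
          class = "c4dyn_config_error")
  }
  dots <- list(...)
  for (nm in names(dots)) sp[[nm]] <- dots[[nm]]
  bad <- need[vapply(sp[need], function(x) !is.numeric(x) || x <= 0, TRUE)]
  if (length(bad) > 0) {
    abort(paste0("species parameters must be positive: ",
                 paste(bad, collapse = ", ")),
          class = "c4dyn_domain_error")
  }
  p <- c(sp[c("species", need)[c("species", need) %in% names(sp)]], network)
  p$vmax_pepc    <- sp$vpmax / sp$f_vmpepc
  p$vmax_rubisco <- sp$vcmax / sp$f_vmrubisco
  p$scale_c4 <- p$vmax_pepc / network$reference$vmax_pepc_ref
  p$scale_c3 <- p$vmax_rubisco / network$reference$vmax_rubisco_ref
  p$rca_total <- rca_total_from_tau(sp$tau_rubisco)
  # PDRP concentration in the mesophyll chloroplast, mM
  p$pdrp_conc <- sp$pdrp / network$geometry$vol_m_chl / 1000
  class(p) <- c("c4_params", "list")
  p
}
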