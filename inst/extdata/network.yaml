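# Reduced-order NADP-ME C4 metabolic network: kinetic defaults.
# One document; schema-validated by c4dyn:::validate_network().
#
# Units (fixed conventions, see the methods vignette):
#   Vmax, fluxes            umol m-2 s-1 (leaf area basis), values at 25 C
#   transfer coefficients   umol m-2 s-1 per mM concentration difference
#   Km, Ki, concentrations  mM
#   compartment volumes     L m-2 leaf
#   tau (activation)        min
#   k_a (light activation)  (umol m-2 s-1)-1, c_a dimensionless
#
# Species scaling: C4-cycle capacities (pepc, ca, ppdk, mdh, me, mutase) are
# multiplied by Vmax_PEPC/vmax_pepc_ref; Calvin-cycle capacities and electron
# transport (gapdh_*, fbpase, sbpase, prk, jmax_*) by Vmax_Rubisco/
# vmax_rubisco_ref, where Vmax_PEPC = Vpmax/f_vmpepc, Vmax_Rubisco =
# Vcmax/f_vmrubisco (the two printed scalars).

geometry:
  vol_m_cyt: 0.020      # mesophyll cytosol
  vol_m_chl: 0.010      # mesophyll chloroplast stroma
  vol_b_cyt: 0.010      # bundle-sheath cytosol
  vol_b_chl: 0.010      # bundle-sheath chloroplast stroma
  kh_co2: 3.34e-5       # CO2 solubility, mM per ubar (25 C)
  co2_buffer_bs: 340    # effective CO2+HCO3 pool of the bundle sheath
  o2_factor: 1.43       # (1 + O/Ko) folded into the Rubisco CO2 Km

conductances:
  gm: 3.0               # mesophyll CO2 conductance, mol m-2 s-1
  gs_min: 0.066         # residual stomatal conductance in darkness (H2O)
  p_co2_pd: 140         # plasmodesmatal CO2 leak coefficient
  k_mal: 12.0           # malate shuttle M -> BS
  k_pyr: 12.0           # pyruvate shuttle BS -> M
  k_pga: 8.0            # PGA shuttle BS -> M
  k_t3p: 12.0           # triose-P shuttle M -> BS

reference:
  vmax_pepc_ref: 120    # original-parameter-set PEPC capacity
  vmax_rubisco_ref: 70.59  # original Vcmax / f_vmrubisco = 60/0.85

vmax:                   # capacities at the reference (original) scaling
  ca: 11000             # linear CA coefficient, umol m-2 s-1 per mM CO2
  ppdk: 30
  mdh: 300
  me: 150
  mutase: 25
  gapdh_m: 85
  gapdh_b: 85
  fbpase: 70
  sbpase: 60
  prk: 150
  export: 60            # triose-P export to sucrose synthesis
  starch_mob: 0.04      # starch/hexose-P mobilisation into triose-P
  glycolysis: 2.0       # dark glycolytic PGA supply from triose-P
  jmax_m: 150           # mesophyll whole-chain e- transport, NADPH units
  jmax_b: 150           # bundle-sheath cyclic e- transport, ATP units
  atps_m: 240           # mesophyll ATP synthesis capacity (linear + cyclic)
  nox: 8.0              # NADPH overflow oxidation, umol m-2 s-1 per mM
  maint: 0.5            # ATP maintenance drain, umol m-2 s-1 per mM
  pyr_decay: 0.08       # respiratory consumption of pyruvate, per mM
  oaa_decay: 0.15       # respiratory consumption of OAA, per mM

km:
  keq_ca: 11.0          # [HCO3-]/[CO2] at cytosolic pH
  pepc_pep: 1.0
  pepc_hco3: 0.012
  ppdk_pyr: 0.25
  ppdk_atp: 0.08
  mdh_oaa: 0.056
  mdh_nadph: 0.05
  me_mal: 3.0
  me_nadp: 0.05
  ki_me_pyr: 3.0        # pyruvate product inhibition of NADP-ME
  ki_me_co2: 0.10       # CO2 product inhibition of NADP-ME
  rub_co2: 0.0217       # 650 ubar; multiplied by o2_factor in the rate law
  rub_rubp: 1.0
  gapdh_pga: 5.0
  gapdh_atp: 0.10
  gapdh_nadph: 0.05
  fbpase_t3p: 0.8
  ki_fbp_hep: 30.0      # hexose-P feedback on FBPase
  sbpase_hep: 0.5
  sbpase_t3p: 0.8
  ki_sbp_ru5p: 2.0      # Ru5P product inhibition of the SBPase lump
  prk_ru5p: 0.25
  ki_prk_rubp: 0.26     # RuBP product inhibition of PRK
  prk_atp: 0.10
  mutase_pga: 1.0
  glyc_t3p: 1.0
  keq_mutase: 1.5       # overall [PEP]/[PGA] poise of mutase+enolase
  ki_pepc_mal: 45.0     # malate inhibition of PEPC
  export_t3p: 3.0
  starch_hep: 5.0
  light_i: 150          # light half-saturation of J(I), umol m-2 s-1
  lr_adp: 0.05
  lr_nadp: 0.05

pools:                  # conserved totals, mM
  adenylate_m: 1.5
  adenylate_b: 1.5
  nadp_m: 0.5
  nadp_b: 0.5
  pi_total_m: 15.0
  ppdk_total: 1.0       # total PPDK in mesophyll chloroplast, mM
  rd_frac_bs: 0.5       # fraction of Rd released in the bundle sheath

pdrp_kinetics:          # PPDK regulatory protein (bifunctional) kinetics
  kcat_i: 1.0           # s-1, inactivation (kinase)
  kcat_a: 0.5           # s-1, activation (phosphatase)
  km_ppdk_i: 0.30
  km_adp_i: 0.06
  ki_pyr_i: 0.50
  km_ppdk_a: 0.30
  km_pi_a: 0.60
  ki_adp_a: 0.08

rubisco_activation:
  k_rca: 216.9          # min mg m-2; [Rca] = k_rca / tau_Rubisco
  k_activase: 12.3      # mg m-2, half-saturation of activation by active Rca

light_activation:       # a_s = min(k_a * I + c_a, 1); tau in min
  atpase:  {tau: 0.3, k_a: 0.0035, c_a: 0.30}
  fbpase:  {tau: 0.3, k_a: 0.0030, c_a: 0.05}
  gapdh:   {tau: 0.3, k_a: 0.0030, c_a: 0.25}
  prk:     {tau: 0.3, k_a: 0.0030, c_a: 0.20}
  rca:     {tau: 1.0, k_a: 0.0030, c_a: 0.50}
  sbpase:  {tau: 0.3, k_a: 0.0030, c_a: 0.0}
  pepc:    {tau: 8.0, k_a: 0.0030, c_a: 0.30}

temperature:            # Ea, Hd in J mol-1; dS in J mol-1 K-1
  pepc:    {form: peaked_arrhenius, ea: 64800, hd: 200000, ds: 650}
  ca:      {form: peaked_arrhenius, ea: 40000, hd: 200000, ds: 650}
  ppdk:    {form: arrhenius, ea: 58000}
  jmax:    {form: arrhenius, ea: 43500}
  rubisco: {form: arrhenius, ea: 64800}
  kc:      {form: arrhenius, ea: 80990}
  q10_default: {form: q10, q10: 2}

energy_balance:
  absorptance_par: 0.85
  par_to_watts: 0.2175  # J per umol photons (550 nm mean)
  nir: 0
  lr: 0
  cp_leaf: 4.184        # J g-1 C-1
  m_leaf: 198           # g m-2
  cp_air: 29.3          # J mol-1 C-1
  c_lv: 44000           # J mol-1
  emissivity: 0.97
  sigma: 5.670374419e-8
  d_leaf: 0.08          # characteristic leaf dimension, m
  c_f: 4.322e-3
  c_e: 1.6361e-3
  gb_floor: 1.0e-4      # mol m-2 s-1

environment_defaults:
  tair: 28
  rh: 0.65              # gives VPD 1.32 kPa at 28 C
  ca: 400
  wind: 1.0
  pa: 101.325           # kPa

initial_state:          # dark reference metabolite concentrations, mM
  co2_m: 0.012
  hco3_m: 0.06
  pep_m: 0.5
  pyr_m: 1.0
  oaa_m: 0.05
  mal_m: 1.0
  pga_m: 5.0
  t3p_m: 0.5
  atp_m: 0.3
  adp_m: 1.2
  nadph_m: 0.1
  nadp_m: 0.4
  pi_m: 14.7
  co2_b: 0.012
  mal_b: 1.0
  pyr_b: 1.0
  pga_b: 5.0
  t3p_b: 0.5
  rubp_b: 1.0
  ru5p_b: 0.3
  hep_b: 40.0
  atp_b: 0.3
  adp_b: 1.2
  nadph_b: 0.1
  nadp_b: 0.4

solver:
  rtol: 1.0e-6
  atol: 1.0e-9
  dt_out: 2             # s, output grid spacing
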