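# Default configuration for the synthetic porcine cohorts.
#
# Trajectory-mode group presets follow the study's printed group-mean
# trajectories (windowed Figure-2 values; Table-1/Figure-1 hemodynamics);
# mechanistic-mode parameters are literature-plausible Starling-model values
# chosen once so that baseline net extravasation is ~0.18-0.19 ml/kg/min and
# femoral venous pressure tracks intra-abdominal pressure (~17 mmHg at IAP 15,
# ~28.5 mmHg at IAP 30). Between-animal and measurement noise magnitudes are
# set to the order of the printed group SDs. All values are configuration, not
# measurements.

cohort:
  weight_kg: 42.0
  grid_start_min: -60
  grid_end_min: 240
  grid_step_min: 30
  infusion_ml_kg_h: 10.0
  blood_loss_ml_per_interval: 15.0   # ~5 ml laboratory sampling + ~10 ml oozing
  replacement_factor: 3.0            # crystalloid given per ml blood lost
  hufner_ml_per_g: 1.39
  mchc_g_l: 310.0                    # blood Hb (g/l) per unit hematocrit

noise:
  hct_sd: 0.005            # fraction, i.e. 0.5 hematocrit points
  hb_sd_g_dl: 0.15
  protein_sd_g_l: 1.0
  albumin_sd_g_l: 1.0
  urine_frac_sd: 0.10
  hemo_animal_rel_sd: 0.08 # per-animal multiplicative offset, hemodynamics
  hemo_meas_rel_sd: 0.05   # per-measurement multiplicative noise

between_animal:
  pv_ml_kg_sd: 6.0
  hct0_sd: 0.016
  nfb_ml_kg_min_sd: 0.008
  weight_kg_sd: 2.9

trajectory:
  C:
    hct0: 0.261
    pv_knots:
      time: [-60, 240]
      pv_ml_kg: [65.1, 65.1]
    nfb_ml_kg_min: {baseline: 0.18, early: 0.18, late: 0.18}
    protein_g_l: {time: [-60, 0, 240], value: [47.0, 47.0, 43.3]}
    albumin_g_l: {time: [-60, 0, 240], value: [31.1, 31.1, 28.9]}
    hemo:
      map:      {time: [-60, 240], value: [65.8, 64.5]}
      mpap:     {time: [-60, 0, 240], value: [18.5, 18.5, 21.6]}
      pcwp:     {time: [-60, 0, 240], value: [11.0, 11.0, 11.5]}
      cvp_ra:   {time: [-60, 0, 240], value: [8.0, 8.0, 8.9]}
      cvp_fv:   {time: [-60, 0, 240], value: [8.8, 8.8, 10.2]}
      iap:      {time: [-60, 0, 240], value: [4.4, 4.4, 5.4]}
      icp:      {time: [-60, 0, 120, 240], value: [16.3, 16.3, 19.9, 20.6]}
      co_l_min: {time: [-60, 0, 60, 240], value: [5.1, 5.1, 5.3, 4.8]}
  P:
    hct0: 0.277
    pv_knots:
      time: [-60, 0, 120, 240]
      pv_ml_kg: [60.9, 60.9, 53.2, 43.6]
    nfb_ml_kg_min: {baseline: 0.16, early: 0.175, late: 0.19}
    protein_g_l: {time: [-60, 0, 240], value: [46.9, 46.9, 47.8]}
    albumin_g_l: {time: [-60, 0, 240], value: [31.4, 31.4, 32.3]}
    hemo:
      map:      {time: [-60, 240], value: [72.3, 71.0]}
      mpap:     {time: [-60, 0, 240], value: [20.0, 20.0, 30.4]}
      pcwp:     {time: [-60, 0, 240], value: [11.0, 11.0, 16.0]}
      cvp_ra:   {time: [-60, 0, 240], value: [7.5, 7.5, 13.0]}
      cvp_fv:   {time: [-60, 0, 30, 120, 150, 240],
                 value: [9.6, 9.6, 17.3, 17.3, 28.5, 28.5]}
      iap:      {time: [-60, 0, 30, 120, 150, 240],
                 value: [5.5, 5.5, 15.0, 15.0, 30.0, 30.0]}
      icp:      {time: [-60, 0, 60, 120, 180, 240],
                 value: [16.9, 16.9, 21.6, 24.0, 26.7, 26.9]}
      co_l_min: {time: [-60, 0, 60, 120, 180, 240],
                 value: [5.4, 5.4, 5.2, 5.1, 3.8, 4.3]}

mechanistic:
  weight_kg: 42.0
  pv0_ml_kg: 62.0
  hct0: 0.27
  protein_g_l: 47.0
  interstitial_volume_ml_kg: 170.0
  interstitial_protein_g_l: 17.0
  k_f_ml_min_mmhg: 0.95        # whole-body capillary filtration coefficient
  sigma: 0.9                   # plasma-protein reflection coefficient
  delta_fc_mmhg: 8.0           # P_c offset above venous pressure (F * R_v)
  p_v0_mmhg: 9.0
  k_iap: 0.65                  # venous-pressure coupling to IAP
  cap_transmission: 0.4        # fraction of the venous rise seen by capillaries
  p_i0_mmhg: -2.0
  c_int_ml_mmhg: 8000.0        # interstitial compliance (edema range)
  a_cop_mmhg_g_l: 0.4          # colloid-osmotic pressure per g/l protein
  lymph_l0_ml_min: 1.5
  lymph_l1_ml_min_mmhg: 0.05
  lymph_iap_factor: 0.03       # lymph attenuation 1 / (1 + factor * IAP)
  iap_baseline_mmhg: 5.0
  urine_u0_ml_min: 0.2
  urine_pv_exp: 3.0
  urine_iap_coef: 0.05
  infusion_ml_kg_h: 10.0
  sample_ml_per_30min: 5.0
  bleed_ml_per_30min: 0.0
  dt_min: 1.0
  co0_l_min: 5.1
  map0_mmhg: 66.0
  mpap0_mmhg: 19.0
  pcwp0_mmhg: 11.0
  icp0_mmhg: 16.5

microspheres:
  n_total: 12000000
  q_ref_ml_min: 2.0
  cardiac_output_ml_min: 5000.0
  animal_rel_sd: 0.15          # shared between phases within an animal
  phase_rel_sd: 0.05
  tissues:
    - {tissue: ileum_muscularis, sample_mass_g: 5.0,
       c_baseline: 0.154, p_baseline: 0.136, c_end: 0.149, p_end: 0.105}
    - {tissue: ileum_mucosa, sample_mass_g: 5.0,
       c_baseline: 0.373, p_baseline: 0.462, c_end: 0.372, p_end: 0.364}
    - {tissue: stomach_muscularis, sample_mass_g: 5.0,
       c_baseline: 0.053, p_baseline: 0.055, c_end: 0.065, p_end: 0.050}
    - {tissue: stomach_mucosa, sample_mass_g: 5.0,
       c_baseline: 0.350, p_baseline: 0.352, c_end: 0.396, p_end: 0.291}
    - {tissue: pancreas, sample_mass_g: 3.0,
       c_baseline: 0.293, p_baseline: 0.379, c_end: 0.402, p_end: 0.255}
    - {tissue: right_kidney, sample_mass_g: 2.0,
       c_baseline: 2.385, p_baseline: 3.136, c_end: 1.969, p_end: 1.506}
    - {tissue: left_kidney, sample_mass_g: 2.0,
       c_baseline: 2.437, p_baseline: 3.063, c_end: 2.006, p_end: 1.540}
    - {tissue: skin, sample_mass_g: 10.0,
       c_baseline: 0.014, p_baseline: 0.016, c_end: 0.018, p_end: 0.011}
    - {tissue: brain, sample_mass_g: 5.0,
       c_baseline: 0.366, p_baseline: 0.386, c_end: 0.354, p_end: 0.489}
    - {tissue: right_ventricle, sample_mass_g: 3.0,
       c_baseline: 0.511, p_baseline: 0.654, c_end: 0.583, p_end: 0.633}
    - {tissue: left_ventricle, sample_mass_g: 3.0,
       c_baseline: 0.537, p_baseline: 0.738, c_end: 0.599, p_end: 0.664}
    - {tissue: skeletal_muscle, sample_mass_g: 10.0,
       c_baseline: 0.021, p_baseline: 0.022, c_end: 0.021, p_end: 0.018}

tissue_water:
  replicates: 2
  dry_mg_mean: 150.0
  dry_mg_sd: 20.0
  tissues:
    - {tissue: right_myocardium, c_mean: 4.15, c_sd: 0.32, p_mean: 4.04, p_sd: 0.14}
    - {tissue: left_myocardium, c_mean: 3.98, c_sd: 0.15, p_mean: 3.87, p_sd: 0.13}
    - {tissue: lung, c_mean: 5.21, c_sd: 0.25, p_mean: 4.86, p_sd: 0.19}
    - {tissue: liver, c_mean: 3.47, c_sd: 0.29, p_mean: 3.66, p_sd: 0.15}
    - {tissue: right_kidney, c_mean: 5.42, c_sd: 0.75, p_mean: 4.70, p_sd: 0.22}
    - {tissue: left_kidney, c_mean: 5.36, c_sd: 0.74, p_mean: 4.55, p_sd: 0.28}
    - {tissue: stomach_muscularis, c_mean: 4.79, c_sd: 0.31, p_mean: 4.50, p_sd: 0.36}
    - {tissue: stomach_mucosa, c_mean: 4.77, c_sd: 0.99, p_mean: 4.08, p_sd: 0.29}
    - {tissue: pancreas, c_mean: 3.00, c_sd: 0.53, p_mean: 3.15, p_sd: 0.23}
    - {tissue: ileum_muscularis, c_mean: 4.69, c_sd: 0.59, p_mean: 4.39, p_sd: 0.34}
    - {tissue: ileum_mucosa, c_mean: 5.33, c_sd: 0.27, p_mean: 4.82, p_sd: 0.82}
    - {tissue: skeletal_muscle, c_mean: 4.07, c_sd: 0.40, p_mean: 4.09, p_sd: 0.32}
    - {tissue: skin, c_mean: 2.84, c_sd: 0.46, p_mean: 2.68, p_sd: 0.65}
    - {tissue: brain, c_mean: 4.54, c_sd: 0.27, p_mean: 4.35, p_sd: 0.32}
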