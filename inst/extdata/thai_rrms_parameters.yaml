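transitions:
  p_edss3:
    family: beta
    mean: 0.0075
    sd: 0.0046
    source: progression EDSS 0.0-2.5 -> 3.0-5.5
  p_edss6:
    family: beta
    mean: 0.0079
    sd: 0.0021
    source: progression EDSS 3.0-5.5 -> 6.0-7.5
  p_edss8:
    family: beta
    mean: 0.0018
    sd: 0.0018
    source: progression EDSS 6.0-7.5 -> 8.0-9.5
  p_edss10:
    family: beta
    mean: 0.0017
    sd: 0.0017
    source: progression EDSS 8.0-9.5 -> death
  p_relapse:
    family: beta
    mean: 0.0755
    sd: 0.0755
    source: relapse, EDSS < 6
  p_death_edss0:
    family: beta
    mean: 0.0009
    sd: 0.0009
    source: MS death from EDSS 0.0-2.5
  p_death_edss3:
    family: beta
    mean: 0.0011
    sd: 0.0011
    source: MS death from EDSS 3.0-5.5
  p_death_edss6:
    family: fixed
    mean: 0.0013
    sd: 0.0
    source: MS death from EDSS 6.0-7.5; calibrated
treatment_effect:
  relapse_effect_rtx:
    family: beta
    mean: 0.422
    sd: 0.1727
    source: relative risk of relapse on rituximab
  p_prog_rtx_0to3:
    family: beta
    mean: 0.0041
    sd: 0.0008
    source: progression 0.0-2.5 -> 3.0-5.5 on rituximab
  p_prog_rtx_3to6:
    family: beta
    mean: 0.0041
    sd: 0.0008
    source: progression 3.0-5.5 -> 6.0-7.5 on rituximab
adverse_events:
  p_infusion_reaction:
    family: beta
    mean: 0.188
    sd: 0.0376
    source: infusion-related reaction
  p_minor_infection:
    family: beta
    mean: 0.169
    sd: 0.0338
    source: minor infection
  p_agranulocytosis:
    family: beta
    mean: 0.0111
    sd: 0.0022
    source: agranulocytosis
  p_pneumonia:
    family: beta
    mean: 0.0065
    sd: 0.0013
    source: hospitalisation, pneumonia
costs:
  c_opd_edss0:
    family: gamma
    mean: 1317.700000000000045
    sd: 131.840000000000003
    source: OPD medical cost/month, EDSS 0.0-2.5
  c_opd_edss3:
    family: gamma
    mean: 2408.769999999999982
    sd: 349.199999999999989
    source: OPD medical cost/month, EDSS 3.0-5.5
  c_opd_edss6:
    family: gamma
    mean: 2202.099999999999909
    sd: 256.560000000000002
    source: OPD medical cost/month, EDSS 6.0-7.5
  c_opd_edss8:
    family: gamma
    mean: 2013.25
    sd: 260.120000000000005
    source: OPD medical cost/month, EDSS 8.0-9.5
  c_relapse_edss0:
    family: gamma
    mean: 40585.629999999997381
    sd: 4407.760000000000218
    source: medical cost of relapse, EDSS 0.0-2.5
  c_relapse_edss3:
    family: gamma
    mean: 71144.229999999995925
    sd: 7710.909999999999854
    source: medical cost of relapse, EDSS 3.0-5.5
  c_relapse_edss6:
    family: gamma
    mean: 80814.940000000002328
    sd: 9688.530000000000655
    source: medical cost of relapse, EDSS 6.0-7.5
  c_relapse_edss8:
    family: gamma
    mean: 55626.190000000002328
    sd: 7917.579999999999927
    source: medical cost of relapse, EDSS 8.0-9.5
  c_nonmed_edss0:
    family: gamma
    mean: 2686.699999999999818
    sd: 734.029999999999973
    source: direct non-medical cost/month, EDSS 0.0-2.5
  c_nonmed_edss3:
    family: gamma
    mean: 2975.329999999999927
    sd: 1172.319999999999936
    source: direct non-medical cost/month, EDSS 3.0-5.5
  c_nonmed_edss6:
    family: gamma
    mean: 10846.590000000000146
    sd: 1949.1099999999999
    source: direct non-medical cost/month, EDSS 6.0-7.5
  c_nonmed_edss8:
    family: gamma
    mean: 15061.940000000000509
    sd: 2782.909999999999854
    source: direct non-medical cost/month, EDSS 8.0-9.5
  c_rituximab_month:
    family: gamma
    mean: 8236.0
    sd: 1647.0
    source: originator rituximab, THB/month (5-y average)
  c_biosimilar_month:
    family: gamma
    mean: 2967.0
    sd: 590.0
    source: rituximab biosimilar, THB/month (5-y average)
  c_admin_month:
    family: gamma
    mean: 506.339999999999975
    sd: 101.0
    source: administration, THB/month
  c_infusion_reaction:
    family: gamma
    mean: 1465.119999999999891
    sd: 293.0
    source: treatment cost, infusion reaction
  c_minor_infection:
    family: gamma
    mean: 4999.920000000000073
    sd: 1000.0
    source: treatment cost, minor infection
  c_agranulocytosis:
    family: gamma
    mean: 23952.0
    sd: 4790.0
    source: treatment cost, agranulocytosis
  c_pneumonia:
    family: gamma
    mean: 9118.030000000000655
    sd: 1824.0
    source: treatment cost, pneumonia
utilities:
  u_edss0:
    family: beta
    mean: 0.6
    sd: 0.02
    source: utility, EDSS 0.0-2.5
  u_relapse0:
    family: beta
    mean: 0.524
    sd: 0.1
    source: utility, EDSS 0.0-2.5 with relapse
  u_edss3:
    family: beta
    mean: 0.49
    sd: 0.04
    source: utility, EDSS 3.0-5.5
  u_relapse3:
    family: beta
    mean: 0.414
    sd: 0.08
    source: utility, EDSS 3.0-5.5 with relapse
  u_edss6:
    family: beta
    mean: 0.17
    sd: 0.06
    source: utility, EDSS 6.0-7.5
  u_edss8:
    family: beta
    mean: 0.026
    sd: 0.01
    source: utility, EDSS 8.0-9.5
settings:
  cycle_length: 1.0
  horizon_cycles: 720
  discount_cost_annual: 0.03
  discount_outcome_annual: 0.03
  wtp: 160000.0
  thb_per_usd: 37.969999999999999
  psa_draws: 1000
  relapse_effect: relative_risk
  relapse_return: one_cycle
  relapse_progression: yes
  late_relapse_costs: yes
  half_cycle: no
  discount_ly: yes
  ci_method: quantile
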