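name,role,base,low,high,limit_rule,units,sample
age_start,resource_count,21,16.8,25.2,assumed_20pct,years,FALSE
p_atonic,probability,0.80,0.64,0.96,assumed_20pct,,TRUE
rr_further_txa,relative_risk,0.96,0.76,1.15,assumed_20pct,,TRUE
rr_further_soc,relative_risk,1.05,0.84,1.26,source_CI,,TRUE
p_further_txa,probability,0.22,0.18,0.27,source_CI,,TRUE
p_further_soc,probability,0.23,0.19,0.28,assumed_20pct,,TRUE
p_ubt_primary,probability,0.19,0.15,0.22,assumed_20pct,,TRUE
p_ubt_secondary,probability,0.33,0.26,0.40,assumed_20pct,,TRUE
p_ubt_tertiary,probability,0.48,0.39,0.58,assumed_20pct,,TRUE
p_ubt_effective,probability,0.92,0.74,0.98,assumed_20pct,,TRUE
rr_death_bleed_txa,relative_risk,0.69,0.52,0.91,source_CI,,TRUE
p_death_bleed_soc,probability,0.02,0.01,0.02,assumed_20pct,,TRUE
p_direct_hyst,probability,0.15,0.12,0.18,assumed_20pct,,TRUE
p_hyst_after_devasc,probability,0.22,0.18,0.26,assumed_20pct,,TRUE
rr_death_all_txa,relative_risk,0.88,0.74,1.05,source_CI,,TRUE
p_death_all_soc,probability,0.03,0.02,0.03,assumed_20pct,,TRUE
p_icu_uncontrolled,probability,0.77,0.62,0.92,assumed_20pct,,TRUE
p_icu_controlled,probability,0.03,0.02,0.03,assumed_20pct,,TRUE
p_trauma_local_control,probability,0.45,0.36,0.55,assumed_20pct,,TRUE
cost_med_txa_primary,cost,451,353,560,cost_simulated_CI,INR,TRUE
cost_med_txa_secondary,cost,1685,1405,1945,cost_simulated_CI,INR,TRUE
cost_med_txa_tertiary,cost,2812,2433,3176,cost_simulated_CI,INR,TRUE
cost_med_soc_primary,cost,241,139,353,cost_simulated_CI,INR,TRUE
cost_med_soc_secondary,cost,1475,1207,1740,cost_simulated_CI,INR,TRUE
cost_med_soc_tertiary,cost,2601,2171,3053,cost_simulated_CI,INR,TRUE
cost_ubt_primary,cost,281,254,308,cost_simulated_CI,INR,TRUE
cost_ubt_secondary,cost,531,446,618,cost_simulated_CI,INR,TRUE
cost_ubt_tertiary,cost,1303,1170,1433,cost_simulated_CI,INR,TRUE
cost_devasc_secondary,cost,4991,3986,5997,cost_simulated_CI,INR,TRUE
cost_devasc_tertiary,cost,8271,6483,10109,cost_simulated_CI,INR,TRUE
cost_hyst_secondary,cost,7535,6150,9016,cost_simulated_CI,INR,TRUE
cost_hyst_tertiary,cost,11462,9529,13343,cost_simulated_CI,INR,TRUE
cost_ipd_secondary,cost,2230,1290,3310,cost_simulated_CI,INR,TRUE
cost_ipd_tertiary,cost,3273,2387,4236,cost_simulated_CI,INR,TRUE
cost_icu_tertiary,cost,9901,4759,15731,cost_simulated_CI,INR,TRUE
cost_local_primary,cost,264,177,351,cost_simulated_CI,INR,TRUE
cost_local_secondary,cost,387,302,470,cost_simulated_CI,INR,TRUE
cost_local_tertiary,cost,689,532,851,cost_simulated_CI,INR,TRUE
cost_referral,cost,1096,876,1315,source_CI,INR,TRUE
cost_oop_childbirth,cost,3015,2412,3618,assumed_20pct,INR,TRUE
n_txa_doses,resource_count,1.29,1.28,1.30,source_CI,,TRUE
u_death,utility,0,0,0,source_CI,,FALSE
u_discharge_medical,utility,0.930,0.910,0.940,source_CI,,TRUE
u_conservative,utility,0.895,0.892,0.897,source_CI,,TRUE
u_devasc_short,utility,0.565,0.300,0.870,assumed_20pct,,TRUE
u_devasc_long,utility,0.909,0.500,0.960,source_CI,,TRUE
u_hyst_short,utility,0.560,0.448,0.672,assumed_20pct,,TRUE
u_hyst_long,utility,0.880,0.704,1.000,assumed_20pct,,TRUE
u_icu,utility,0.490,0.392,0.588,assumed_20pct,,TRUE
discount_rate,rate,0.030,0.000,0.050,source_CI,per annum,FALSE
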