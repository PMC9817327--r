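target,arm,value,weight
cost_societal_per_patient,txa,6607,1
cost_societal_per_patient,soc,6486,1
cost_health_system_per_patient,txa,5934,1
cost_health_system_per_patient,soc,5782,1
qaly_undiscounted_per_patient,txa,44.894,1
qaly_undiscounted_per_patient,soc,44.712,1
qaly_discounted_per_patient,txa,20.250,1
qaly_discounted_per_patient,soc,20.168,1
surgeries_cohort,txa,19387,1
surgeries_cohort,soc,20293,1
icu_admissions_cohort,txa,27181,1
icu_admissions_cohort,soc,27836,1
maternal_deaths_cohort,txa,13923,1
maternal_deaths_cohort,soc,15913,1
incremental_cost_societal,diff,121,2
incremental_cost_health_system,diff,152,2
incremental_qaly_discounted,diff,0.082,2
incremental_qaly_undiscounted,diff,0.182,2
maternal_deaths_averted,diff,1990,2
surgeries_averted,diff,905,2
icu_admissions_averted,diff,655,2
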