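year,total_patients,txa_patients,soc_patients
2021,643226,119704,523522
2022,676439,348637,327802
2023,666150,666150,0
2024,596409,596409,0
2025,471710,471710,0
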