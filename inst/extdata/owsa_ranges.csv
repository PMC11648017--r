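"name","lo","hi"
"arpi_abi_share",0,1
"ctdna_ppv",0.65,0.95
"lines.enzalutamide.drug_cost_per_cycle",245,2450
"lines.abiraterone.drug_cost_per_cycle",70,700
"lines.cabazitaxel.drug_cost_per_cycle",390,3900
"ctdna_cost_per_sample",100,350
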