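schema_version: 1
parameters: parameters.csv
life_table: life_table.csv
utility_age: utility_age.csv
population_oc: incidence_population_oc.csv
genes:
  BRCA1:
    oc: incidence_brca1_oc.csv
    lifetime_oc_risk: 0.46
    surveillance_tier: high
    bc: incidence_brca1_bc.csv
    lifetime_bc_risk: 0.685
  BRCA2:
    oc: incidence_brca2_oc.csv
    lifetime_oc_risk: 0.185
    surveillance_tier: high
    bc: incidence_brca2_bc.csv
    lifetime_bc_risk: 0.65
  PALB2:
    oc: incidence_palb2_oc.csv
    lifetime_oc_risk: 0.05
    surveillance_tier: high
    bc: incidence_palb2_bc.csv
    lifetime_bc_risk: 0.53
  RAD51C:
    oc: incidence_rad51c_oc.csv
    lifetime_oc_risk: 0.11
    surveillance_tier: moderate
    bc: incidence_rad51c_bc.csv
    lifetime_bc_risk: 0.21
  RAD51D:
    oc: incidence_rad51d_oc.csv
    lifetime_oc_risk: 0.13
    surveillance_tier: moderate
    bc: incidence_rad51d_bc.csv
    lifetime_bc_risk: 0.2
  BRIP1:
    oc: incidence_brip1_oc.csv
    lifetime_oc_risk: 0.056827464599
    surveillance_tier: none
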