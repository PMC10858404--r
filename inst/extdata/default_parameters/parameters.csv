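"name","base","low","high","dist","units"
"rrso_oc_multiplier",0.04,0.01,0.1,"beta","probability/weight"
"rrso_bc_multiplier_BRCA1",1,1,1,"fixed","probability/weight"
"rrso_bc_multiplier_BRCA2",0.56,0.4,0.8,"beta","probability/weight"
"rrso_bc_multiplier_PALB2",0.56,0.4,0.8,"beta","probability/weight"
"rrso_bc_multiplier_RAD51C",1,1,1,"fixed","probability/weight"
"rrso_bc_multiplier_RAD51D",1,1,1,"fixed","probability/weight"
"rrso_bc_multiplier_BRIP1",1,1,1,"fixed","probability/weight"
"rrso_acm_multiplier_BRCA1",0.85,0.7,0.99,"beta","probability/weight"
"rrso_acm_multiplier_BRCA2",0.85,0.7,0.99,"beta","probability/weight"
"rrso_acm_multiplier_PALB2",0.85,0.7,0.99,"beta","probability/weight"
"rrso_acm_multiplier_RAD51C",0.85,0.7,0.99,"beta","probability/weight"
"rrso_acm_multiplier_RAD51D",0.85,0.7,0.99,"beta","probability/weight"
"rrso_acm_multiplier_BRIP1",0.85,0.7,0.99,"beta","probability/weight"
"rrm_bc_multiplier",0.08,0.05,0.15,"beta","probability/weight"
"chemoprev_bc_multiplier_pre",0.7,0.55,0.85,"beta","probability/weight"
"chemoprev_bc_multiplier_post",0.5,0.35,0.65,"beta","probability/weight"
"chd_mortality_multiplier",1.03,1,1.08,"lognormal","probability/weight"
"ht_uptake",0.8,0.6,0.95,"beta","probability/weight"
"chemoprev_uptake",0.163,0.1,0.25,"beta","probability/weight"
"fp_prob_mri",0.08,0.04,0.12,"beta","probability/weight"
"fp_prob_mammo",0.04,0.02,0.06,"beta","probability/weight"
"oc_survival_10yr",0.35,0.3,0.4,"beta","probability/weight"
"bc_survival_10yr_high",0.81,0.75,0.87,"beta","probability/weight"
"bc_survival_10yr_moderate",0.85,0.8,0.9,"beta","probability/weight"
"discount_rate",0.035,0.035,0.035,"fixed","probability/weight"
"menopause_age",51,51,51,"fixed","years"
"cost_rrso",2950,2065,3835,"gamma","GBP-2021"
"cost_rrm",8100,5670,10530,"gamma","GBP-2021"
"cost_mri",181,127,235,"gamma","GBP-2021"
"cost_mammo",96,67,125,"gamma","GBP-2021"
"cost_fp_workup",450,315,585,"gamma","GBP-2021"
"cost_chemoprev_year",55,38,72,"gamma","GBP-2021"
"cost_ht_year",130,91,169,"gamma","GBP-2021"
"cost_chd_year",180,126,234,"gamma","GBP-2021"
"cost_oc_year1",17500,12250,22750,"gamma","GBP-2021"
"cost_oc_subseq",2600,1820,3380,"gamma","GBP-2021"
"cost_oc_terminal",9000,6300,11700,"gamma","GBP-2021"
"cost_bc_year1",13600,9520,17680,"gamma","GBP-2021"
"cost_bc_subseq",1650,1155,2145,"gamma","GBP-2021"
"cost_bc_terminal",7800,5460,10140,"gamma","GBP-2021"
"util_mult_oc",0.71,0.64,0.78,"lognormal","probability/weight"
"util_mult_bc",0.79,0.71,0.87,"lognormal","probability/weight"
"util_mult_oc_survivor",0.88,0.79,0.97,"lognormal","probability/weight"
"util_mult_bc_survivor",0.92,0.83,0.99,"lognormal","probability/weight"
"disutil_rrso",0.05,0.045,0.055,"gamma","probability/weight"
"disutil_rrm",0.1,0.09,0.11,"gamma","probability/weight"
"disutil_chemoprev",0.01,0.009,0.011,"gamma","probability/weight"
"disutil_screen",0.006,0.0054,0.0066,"gamma","probability/weight"
"disutil_fp",0.05,0.045,0.055,"gamma","probability/weight"
"disutil_chd",0.05,0.045,0.055,"gamma","probability/weight"
"brip1_oc_rr",3.41,2.2,5.54,"lognormal","probability/weight"
"parpi_cost_oc_year1",38000,38000,38000,"fixed","GBP-2021"
"parpi_cost_bc_year1",21000,21000,21000,"fixed","GBP-2021"
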