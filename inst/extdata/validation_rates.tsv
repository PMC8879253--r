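# Published and in-study validation pairs: biomass-specific substrate
# consumption (mmol.gDW-1.h-1) and the observed specific growth rate (h-1).
reference	substrate	q_s_gdw_h	mu_obs
cui2018	glucose	0.65	0.051
cui2018_eta	glucose	0.61	0.047
this_study	glucose	0.59	0.044
taborda2021	glucose	0.37	0.017
this_study	glycerol	0.44	0.023
taborda2021	glycerol	0.43	0.019
this_study	ethanol	1.41	0.046
taborda2021	acetate	0.60	0.025
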