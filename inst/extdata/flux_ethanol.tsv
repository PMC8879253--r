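# label: ethanol_batch
# substrate: ethanol
# uptake_rate: 7.76
# units: mmol.min-1.L-1
# provenance notes: uptake is the measured batch-cultivation rate; the
# Acetyl-CoA production flux and Krebs segment flux are the simulated values
# reported for this scenario; remaining entries close the steady-state
# balances of the pathway (synthetic).
reaction	flux	weight	provenance
etoht	7.76	10	measured
adh	7.76	1	synthetic
aldh	7.76	1	synthetic
acalig	7.76	1	synthetic
accoat	7.76	1	synthetic
cs	7.76	1	synthetic
aco	3.00	1	synthetic
ogdh	3.00	1	measured
pyc	0.10	1	synthetic
me	0.10	1	synthetic
citt	4.76	1	measured
oaat	4.76	1	synthetic
accoa_sink	4.76	1	synthetic
acl	4.76	10	measured
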