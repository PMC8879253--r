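# label: glycerol_batch
# substrate: glycerol
# uptake_rate: 2.42
# units: mmol.min-1.L-1
# provenance notes: uptake is the measured batch-cultivation rate; the
# Acetyl-CoA production flux and Krebs segment flux are the simulated values
# reported for this scenario; remaining entries are growth-consistent
# synthetic fill-ins.
reaction	flux	weight	provenance
glyct	2.42	10	measured
glyk	2.42	1	synthetic
g3pd	2.42	1	synthetic
tpi	2.40	1	synthetic
gra3pdh	2.40	1	synthetic
pgk	2.40	1	synthetic
pgm	2.35	1	synthetic
eno	2.35	1	synthetic
pyk	2.27	1	synthetic
pyrt	2.20	1	synthetic
pyc	0.08	1	synthetic
me	0.08	1	synthetic
pdh	2.10	1	synthetic
cs	2.10	1	synthetic
ogdh	0.90	1	measured
citt	1.44	1	measured
oaat	1.44	1	synthetic
accoa_sink	1.44	1	synthetic
acl	1.44	10	measured
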