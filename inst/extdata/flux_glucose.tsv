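# label: glucose_13c
# substrate: glucose
# uptake_rate: 3.575
# units: mmol.min-1.L-1
# provenance notes: entries marked "measured" are the printed anchors of the
# 13C-based glucose flux set (uptake, lumped lower-Krebs-segment flux, and
# ATP-citrate lyase).  Entries marked "synthetic" are growth-consistent
# fill-ins derived from the package's stoichiometric reconstruction at the
# observed growth rate (mu = 0.051/h) with the anchors imposed and the
# classical EMP/PDH-dominant route caps applied; they stand in for the
# branch fluxes the source does not print.  Weight-0 rows duplicate
# information already carried by the anchors (lower-Krebs segment) or are
# structurally tied in the closed kinetic topology (anaplerotic pair,
# shuttles); they are listed for the coupling analysis but do not pull the
# kinetic fit.
reaction	flux	weight	provenance
glct	3.5750	10	measured
hk	3.5750	0.3	synthetic
pgi	3.1425	0.3	synthetic
pfk	2.8325	0.3	synthetic
ald	2.8325	0.3	synthetic
tpi	2.8325	0.3	synthetic
gra3pdh	5.6425	0.3	synthetic
pgk	5.6425	0.3	synthetic
pgm	5.6824	0.3	synthetic
eno	5.6824	0.3	synthetic
pyk	5.4972	0.3	synthetic
pyrt	5.2425	0.3	synthetic
pdh	4.5100	0.3	synthetic
pyc	4.3449	0	synthetic
cs	6.6409	0.3	synthetic
aco	2.7748	0	synthetic
ide	2.7748	0	synthetic
ogdh	2.4276	1	measured
ss	2.4276	0	synthetic
sde	2.4276	0	synthetic
fuh	2.4276	0	synthetic
me	3.6124	0	synthetic
citt	3.8661	10	measured
acl	3.8661	10	measured
oaat	2.2960	0	synthetic
accoat	2.1309	0	synthetic
accoa_sink	2.0927	0	synthetic
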