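# Heptad propensity table MTIDK (extended coiled-coil reference set),
# registers a-g. Row X (propensity 1 at every register) is added by the
# loader.
# The 'gauss' lines carry the two-Gaussian decision parameters per scan
# window: window, cc_mean, cc_sd, glob_mean, glob_sd. They were calibrated
# against this package's background composition and ideal-heptad scores
# (see the methods vignette), not fitted to an external database.
# gauss 14 2.80 0.30 0.76 0.23
# gauss 21 2.80 0.30 0.69 0.18
# gauss 28 2.80 0.30 0.67 0.15
aa	a	b	c	d	e	f	g
A	1.283	1.364	1.077	2.219	0.490	1.265	0.903
R	1.014	1.476	1.771	0.114	1.667	2.006	1.844
N	1.231	1.683	2.157	0.197	1.653	2.430	2.065
D	0.068	2.103	1.646	0.182	0.664	1.581	1.401
C	0.918	0.002	0.385	0.440	0.138	0.432	0.079
Q	0.311	2.290	2.330	0.811	2.596	2.155	2.585
E	0.281	3.351	2.998	0.789	4.868	2.735	3.812
G	0.084	0.215	0.432	0.111	0.153	0.367	0.125
H	0.590	0.646	0.584	0.842	0.307	0.611	0.396
I	2.408	0.261	0.345	0.931	0.402	0.440	0.289
L	2.998	0.269	0.367	3.852	0.510	0.514	0.562
K	1.233	2.194	1.817	0.611	2.095	1.686	2.027
M	2.161	0.605	0.442	1.441	0.607	0.457	0.570
F	0.490	0.075	0.391	0.639	0.125	0.081	0.038
P	0.004	0.108	0.018	0.006	0.010	0.004	0.007
S	0.332	0.753	0.930	0.424	0.734	0.801	0.518
T	0.197	0.543	0.647	0.680	0.905	0.643	0.808
W	0.066	0.064	0.065	0.747	0.006	0.115	0.014
Y	1.319	0.064	0.081	1.526	0.204	0.118	0.096
V	1.525	0.479	0.350	0.887	0.286	0.350	0.362
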