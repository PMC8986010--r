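complex	id	term	mean	sd
IL-6-ZINC02997430	ZINC02997430	dE_vdW	-26.48	3.55
IL-6-ZINC02997430	ZINC02997430	dE_elec	-28.13	9.28
IL-6-ZINC02997430	ZINC02997430	dG_GB	39.10	7.75
IL-6-ZINC02997430	ZINC02997430	dG_SA	-3.63	0.39
IL-6-ZINC02997430	ZINC02997430	dG_bind	-19.15	4.04
IL6-Ra-ZINC72026870	ZINC72026870	dE_vdW	-14.21	4.47
IL6-Ra-ZINC72026870	ZINC72026870	dE_elec	-354.25	28.73
IL6-Ra-ZINC72026870	ZINC72026870	dG_GB	355.95	25.82
IL6-Ra-ZINC72026870	ZINC72026870	dG_SA	-3.76	0.47
IL6-Ra-ZINC72026870	ZINC72026870	dG_bind	-16.26	5.13
IL6-Ra-ZINC46227820	ZINC46227820	dE_vdW	-17.14	4.22
IL6-Ra-ZINC46227820	ZINC46227820	dE_elec	-230.58	35.90
IL6-Ra-ZINC46227820	ZINC46227820	dG_GB	242.22	31.68
IL6-Ra-ZINC46227820	ZINC46227820	dG_SA	-3.06	0.56
IL6-Ra-ZINC46227820	ZINC46227820	dG_bind	-8.57	4.63
IL6-Ra-ZINC83804241	ZINC83804241	dE_vdW	-14.78	4.18
IL6-Ra-ZINC83804241	ZINC83804241	dE_elec	-411.32	40.02
IL6-Ra-ZINC83804241	ZINC83804241	dG_GB	399.67	37.51
IL6-Ra-ZINC83804241	ZINC83804241	dG_SA	-3.84	0.42
IL6-Ra-ZINC83804241	ZINC83804241	dG_bind	-30.28	5.14
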