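complex	donor	acceptor	occupancy_percent
IL-6-ZINC04256801	Arg182-Side	LIG185-Side	96.48
IL-6-ZINC04256801	Arg179-Side	LIG185-Side	16.78
IL-6-ZINC04256801	Arg30-Side	LIG185-Side	8.16
IL-6-ZINC04256801	Gln75-Side	LIG185-Side	4.06
IL-6-ZINC04256801	LIG185-Side	Gln75-Main	6.16
IL-6-ZINC02997430	Arg179-Side	LIG185-Side	171.67
IL-6-ZINC02997430	Arg179-Side	LIG185-Main	54.84
IL-6-ZINC02997430	Ser176-Side	LIG185-Side	158.06
IL-6-ZINC02997430	LIG185-Side	Ser176-Side	38.46
IL-6-ZINC02997430	Gln175-Side	LIG185-Side	49.90
IL-6-ZINC02997430	LIG185-Side	Cys73-Main	48.74
IL-6-ZINC03000225	Arg182-Side	LIG185-Side	81.67
IL-6-ZINC03000225	Arg179-Side	LIG185-Side	16.71
IL-6-ZINC03000225	Gln175-Side	LIG185-Side	12.79
IL-6-ZINC03000225	Gln75-Side	LIG185-Side	14.57
IL-6-ZINC03000225	LIG185-Side	Gln75-Side	11.46
IL-6-ZINC03000225	Gln75-Main	LIG185-Side	10.62
IL6-Ra-ZINC72026870	LIG299-Side	Glu278-Side	106.78
IL6-Ra-ZINC72026870	LIG299-Side	Phe229-Main	31.94
IL6-Ra-ZINC72026870	Lys252-Side	LIG299-Side	138.38
IL6-Ra-ZINC46227820	LIG299-Side	Glu278-Side	103.42
IL6-Ra-ZINC46227820	LIG299-Side	Phe229-Main	20.95
IL6-Ra-ZINC46227820	LIG299-Side	Asp221-Side	39.4
IL6-Ra-ZINC83804241	LIG299-Main	Glu278-Side	392.92
IL6-Ra-ZINC83804241	LIG299-Side	Glu278-Side	99.22
IL6-Ra-ZINC83804241	LIG299-Side	Phe229-Main	92.34
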