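id	target	docking_score	contacts	lipinski_pass
ZINC04256801	IL-6	-27.57	Phe78,Leu178,Arg179,Arg182	TRUE
ZINC00753055	IL-6	-27.48	Phe74,Arg179,Arg182	TRUE
ZINC20247718	IL-6	-27.06	Phe78,Arg179,Arg182	TRUE
ZINC02997430	IL-6	-25.64	Phe74,Arg179,Arg182	TRUE
ZINC03000225	IL-6	-25.43	Phe74,Arg179,Arg182	TRUE
ZINC59449112	IL-6	-25.20	Phe74,Phe78,Arg179,Arg182	TRUE
ZINC02682855	IL-6	-25.00	Phe74,Arg179,Arg182	TRUE
ZINC32853685	IL-6Ra	-26.44	Phe229,Glu277,Glu278,Phe279	TRUE
ZINC57774399	IL-6Ra	-26.24	Phe229,Tyr230,Glu277,Glu278,Phe279	TRUE
ZINC72026870	IL-6Ra	-25.31	Phe229,Tyr230,Glu277,Glu278	TRUE
ZINC46227820	IL-6Ra	-25.25	Phe229,Tyr230,Glu277,Glu278	TRUE
ZINC83804241	IL-6Ra	-25.07	Phe229,Tyr230,Glu277,Glu278	TRUE
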