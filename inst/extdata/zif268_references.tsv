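# example reference ladder for the Zif268 zinc finger (nM)
sequence	kd_nM
GCGTGGGCGG	0.25728988
GCGTGGGAGG	0.579150579
GCGTGGGCGT	0.15026296
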