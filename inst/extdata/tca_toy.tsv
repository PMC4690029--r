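node	Oxaloacetate	compound
node	Citrate	compound
node	Isocitrate	compound
node	2-Oxoglutarate	compound
node	Succinyl-CoA	compound
node	Succinate	compound
node	Fumarate	compound
node	Malate	compound
node	CS	gene	CS
node	ACO2	gene	ACO2
node	IDH	gene	IDH1,IDH2,IDH3A
node	OGDH	gene	OGDH,DLST,DLD
node	SUCL	gene	SUCLG1,SUCLA2
node	SDH	gene	SDHA,SDHB,SDHC,SDHD
node	FH	gene	FH
node	MDH	gene	MDH1,MDH2
edge	Oxaloacetate	CS	activation
edge	CS	Citrate	activation
edge	Citrate	ACO2	activation
edge	ACO2	Isocitrate	activation
edge	Isocitrate	IDH	activation
edge	IDH	2-Oxoglutarate	activation
edge	2-Oxoglutarate	OGDH	activation
edge	OGDH	Succinyl-CoA	activation
edge	Succinyl-CoA	SUCL	activation
edge	SUCL	Succinate	activation
edge	Succinate	SDH	activation
edge	SDH	Fumarate	activation
edge	Fumarate	FH	activation
edge	FH	Malate	activation
edge	Malate	MDH	activation
edge	MDH	Oxaloacetate	activation
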