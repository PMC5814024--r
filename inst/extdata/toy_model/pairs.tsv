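reaction	reactant	product
HEX1	glc-D	g6p
HEX1	atp	adp
AKGDH	akg	succoa
AKGDH	akg	co2
AKGDH	coa	succoa
AKGDH	nad	nadh
SUCOAS	succ	succoa
SUCOAS	coa	succoa
SUCOAS	atp	adp
SUCOAS	atp	pi
ICL	icit	glx
ICL	icit	succ
MALS	accoa	mal-L
MALS	glx	mal-L
MALS	accoa	coa
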