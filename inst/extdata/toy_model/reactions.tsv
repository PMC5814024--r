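id	equation	synthetic
HEX1	atp + glc-D => adp + g6p + h	false
AKGDH	akg + coa + nad => co2 + nadh + succoa	false
SUCOAS	atp + coa + succ <=> adp + pi + succoa	false
ICL	icit => glx + succ	false
MALS	accoa + glx + h2o => coa + h + mal-L	false
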