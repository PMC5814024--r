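id	formula	name	compartment
glc-D	C6H12O6	D-Glucose
atp	C10H12N5O13P3	ATP
adp	C10H12N5O10P2	ADP
g6p	C6H11O9P	D-Glucose 6-phosphate
h	H	H+
akg	C5H4O5	2-Oxoglutarate
coa	C21H32N7O16P3S	Coenzyme A
succoa	C25H35N7O19P3S	Succinyl-CoA
co2	CO2	CO2
nad	C21H26N7O14P2	NAD
nadh	C21H27N7O14P2	NADH
pi	HO4P	Phosphate
succ	C4H4O4	Succinate
icit	C6H5O7	Isocitrate
glx	C2HO3	Glyoxylate
accoa	C23H34N7O17P3S	Acetyl-CoA
h2o	H2O	H2O
mal-L	C4H4O5	L-Malate
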