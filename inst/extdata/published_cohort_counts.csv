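variable,level,IA-IIA,IIB-IIIB
age,<=60,188,96
age,>60,195,144
sex,male,224,101
sex,female,159,69
histology,LUAD,269,113
histology,LUSC,92,39
histology,other,22,18
vte,yes,214,45
vte,no,169,125
vpi,PL0,157,49
vpi,PL1,194,117
vpi,PL2,32,4
dissected_ln,0-14,130,37
dissected_ln,>=15,253,133
relapse,yes,126,114
relapse,no,257,56
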