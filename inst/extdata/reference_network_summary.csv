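analyte,state,stressor,sigma,xbar,n_pos,n_neg
OGDHC,NP,control,4.27,0.27,1,0
ALA,NP,control,9.45,0.59,10,0
ARG,NP,control,10.89,0.68,13,0
ASP,NP,control,8.65,0.54,9,0
GABA,NP,control,10.21,0.64,11,0
GLU,NP,control,10.59,0.66,14,0
GLY,NP,control,9.62,0.6,10,0
HIS,NP,control,9.61,0.6,11,0
ILE,NP,control,10.59,0.66,12,0
LEU,NP,control,10.39,0.65,12,0
LYS,NP,control,7.24,0.45,4,0
MET,NP,control,8.42,0.53,9,0
PHE,NP,control,9.89,0.62,8,0
SER,NP,control,8.16,0.51,12,0
TRP,NP,control,4.49,0.28,2,0
TYR,NP,control,9.18,0.57,11,0
VAL,NP,control,10.63,0.66,13,0
OGDHC,NP,SP,6.96,0.43,0,6
ALA,NP,SP,11.78,0.74,12,1
ARG,NP,SP,11.73,0.73,12,0
ASP,NP,SP,8.99,0.56,8,1
GABA,NP,SP,9.93,0.62,10,1
GLU,NP,SP,10.4,0.65,11,1
GLY,NP,SP,11.25,0.7,11,0
HIS,NP,SP,11.62,0.73,12,0
ILE,NP,SP,11.69,0.73,12,1
LEU,NP,SP,11.58,0.72,12,1
LYS,NP,SP,10.81,0.68,11,0
MET,NP,SP,6.29,0.39,5,0
PHE,NP,SP,7.84,0.49,8,0
SER,NP,SP,8.76,0.55,9,0
TRP,NP,SP,5.97,0.37,3,0
TYR,NP,SP,11.77,0.74,13,0
VAL,NP,SP,6.92,0.43,7,0
OGDHC,P,control,6.04,0.38,0,0
ALA,P,control,8.95,0.6,3,0
ARG,P,control,10.19,0.68,5,0
ASP,P,control,9.12,0.61,0,0
GABA,P,control,9.29,0.62,5,0
GLU,P,control,5.28,0.35,0,0
GLY,P,control,9.28,0.62,4,0
HIS,P,control,5.82,0.39,1,0
ILE,P,control,9.81,0.65,6,0
LEU,P,control,9.95,0.66,6,0
LYS,P,control,9.72,0.65,2,0
MET,P,control,5.67,0.38,0,0
PHE,P,control,9.21,0.61,1,0
SER,P,control,7.78,0.52,1,0
TRP,P,control,6.13,0.41,0,0
TYR,P,control,10.49,0.7,5,0
VAL,P,control,5.09,0.34,1,0
OGDHC,P,SP,5.08,0.32,0,1
ALA,P,SP,11.06,0.69,9,0
ARG,P,SP,11.47,0.72,11,1
ASP,P,SP,6.97,0.44,2,1
GABA,P,SP,11.7,0.73,11,1
GLU,P,SP,4.89,0.31,1,1
GLY,P,SP,11.59,0.72,10,1
HIS,P,SP,9.44,0.59,7,0
ILE,P,SP,11.68,0.73,11,1
LEU,P,SP,11.7,0.73,11,1
LYS,P,SP,10.27,0.64,8,1
MET,P,SP,9.97,0.62,9,2
PHE,P,SP,11.7,0.73,12,1
SER,P,SP,8.06,0.5,3,1
TRP,P,SP,10.32,0.65,0,10
TYR,P,SP,9.05,0.57,8,0
VAL,P,SP,9.7,0.61,7,1
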