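hub,state,stressor,partner,r
OGDHC,NP,control,TRP,0.71
OGDHC,NP,control,ALA,0.12
OGDHC,NP,control,ARG,-0.3
OGDHC,NP,control,ASP,-0.47
OGDHC,NP,control,GABA,-0.4
OGDHC,NP,control,GLU,0.06
OGDHC,NP,control,GLY,-0.4
OGDHC,NP,control,HIS,-0.11
OGDHC,NP,control,ILE,-0.35
OGDHC,NP,control,LEU,-0.31
OGDHC,NP,control,LYS,0.28
OGDHC,NP,control,MET,0
OGDHC,NP,control,PHE,-0.24
OGDHC,NP,control,SER,0.03
OGDHC,NP,control,TYR,0.32
OGDHC,NP,control,VAL,-0.18
OGDHC,NP,SP,TRP,0.46
OGDHC,NP,SP,ALA,-0.58
OGDHC,NP,SP,ARG,-0.45
OGDHC,NP,SP,ASP,-0.66
OGDHC,NP,SP,GABA,-0.61
OGDHC,NP,SP,GLU,-0.72
OGDHC,NP,SP,GLY,-0.35
OGDHC,NP,SP,HIS,-0.39
OGDHC,NP,SP,ILE,-0.58
OGDHC,NP,SP,LEU,-0.64
OGDHC,NP,SP,LYS,-0.29
OGDHC,NP,SP,MET,0
OGDHC,NP,SP,PHE,-0.17
OGDHC,NP,SP,SER,-0.5
OGDHC,NP,SP,TYR,-0.45
OGDHC,NP,SP,VAL,0.35
OGDHC,NP,hypoxia,TRP,0.53
OGDHC,NP,hypoxia,ALA,-0.94
OGDHC,NP,hypoxia,ARG,-0.94
OGDHC,NP,hypoxia,ASP,-0.9
OGDHC,NP,hypoxia,GABA,-0.95
OGDHC,NP,hypoxia,GLU,-0.84
OGDHC,NP,hypoxia,GLY,-0.95
OGDHC,NP,hypoxia,HIS,-0.94
OGDHC,NP,hypoxia,ILE,-0.95
OGDHC,NP,hypoxia,LEU,-0.95
OGDHC,NP,hypoxia,LYS,-0.69
OGDHC,NP,hypoxia,MET,-0.65
OGDHC,NP,hypoxia,PHE,-0.95
OGDHC,NP,hypoxia,SER,-0.19
OGDHC,NP,hypoxia,TYR,-0.89
OGDHC,NP,hypoxia,VAL,0.11
TRP,NP,control,OGDHC,0.71
TRP,NP,control,ALA,0.39
TRP,NP,control,ARG,-0.14
TRP,NP,control,ASP,-0.4
TRP,NP,control,GABA,-0.3
TRP,NP,control,GLU,0.3
TRP,NP,control,GLY,-0.41
TRP,NP,control,HIS,-0.05
TRP,NP,control,ILE,-0.1
TRP,NP,control,LEU,-0.17
TRP,NP,control,LYS,0.62
TRP,NP,control,MET,-0.05
TRP,NP,control,PHE,-0.25
TRP,NP,control,SER,0.01
TRP,NP,control,TYR,0.47
TRP,NP,control,VAL,-0.11
TRP,NP,SP,OGDHC,0.46
TRP,NP,SP,ALA,0.15
TRP,NP,SP,ARG,0.25
TRP,NP,SP,ASP,-0.44
TRP,NP,SP,GABA,-0.32
TRP,NP,SP,GLU,-0.36
TRP,NP,SP,GLY,0.39
TRP,NP,SP,HIS,0.4
TRP,NP,SP,ILE,0.04
TRP,NP,SP,LEU,-0.04
TRP,NP,SP,LYS,0.39
TRP,NP,SP,MET,0.77
TRP,NP,SP,PHE,0.06
TRP,NP,SP,SER,-0.34
TRP,NP,SP,TYR,0.69
TRP,NP,SP,VAL,0.024
TRP,NP,hypoxia,OGDHC,0.53
TRP,NP,hypoxia,ALA,-0.68
TRP,NP,hypoxia,ARG,-0.66
TRP,NP,hypoxia,ASP,-0.33
TRP,NP,hypoxia,GABA,-0.56
TRP,NP,hypoxia,GLU,-0.39
TRP,NP,hypoxia,GLY,-0.56
TRP,NP,hypoxia,HIS,-0.58
TRP,NP,hypoxia,ILE,-0.56
TRP,NP,hypoxia,LEU,-0.6
TRP,NP,hypoxia,LYS,-0.67
TRP,NP,hypoxia,MET,-0.43
TRP,NP,hypoxia,PHE,-0.6
TRP,NP,hypoxia,SER,-0.11
TRP,NP,hypoxia,TYR,-0.63
TRP,NP,hypoxia,VAL,0.69
OGDHC,P,control,TRP,0.85
OGDHC,P,control,ALA,-0.35
OGDHC,P,control,ARG,-0.33
OGDHC,P,control,ASP,-0.04
OGDHC,P,control,GABA,-0.55
OGDHC,P,control,GLU,0.33
OGDHC,P,control,GLY,-0.51
OGDHC,P,control,HIS,0.76
OGDHC,P,control,ILE,-0.44
OGDHC,P,control,LEU,-0.42
OGDHC,P,control,LYS,0.07
OGDHC,P,control,MET,-0.15
OGDHC,P,control,PHE,-0.04
OGDHC,P,control,SER,0.36
OGDHC,P,control,TYR,-0.08
OGDHC,P,control,VAL,0.76
OGDHC,P,SP,TRP,-0.32
OGDHC,P,SP,ALA,-0.34
OGDHC,P,SP,ARG,-0.25
OGDHC,P,SP,ASP,-0.67
OGDHC,P,SP,GABA,-0.21
OGDHC,P,SP,GLU,-0.58
OGDHC,P,SP,GLY,-0.23
OGDHC,P,SP,HIS,-0.32
OGDHC,P,SP,ILE,-0.21
OGDHC,P,SP,LEU,-0.24
OGDHC,P,SP,LYS,0.27
OGDHC,P,SP,MET,0.24
OGDHC,P,SP,PHE,-0.11
OGDHC,P,SP,SER,0.42
OGDHC,P,SP,TYR,-0.32
OGDHC,P,SP,VAL,0.48
OGDHC,P,hypoxia,TRP,0.05
OGDHC,P,hypoxia,ALA,-0.17
OGDHC,P,hypoxia,ARG,-0.03
OGDHC,P,hypoxia,ASP,-0.06
OGDHC,P,hypoxia,GABA,-0.12
OGDHC,P,hypoxia,GLU,-0.22
OGDHC,P,hypoxia,GLY,-0.15
OGDHC,P,hypoxia,HIS,0.03
OGDHC,P,hypoxia,ILE,0.14
OGDHC,P,hypoxia,LEU,0.19
OGDHC,P,hypoxia,LYS,0.24
OGDHC,P,hypoxia,MET,0.63
OGDHC,P,hypoxia,PHE,0.08
OGDHC,P,hypoxia,SER,0.44
OGDHC,P,hypoxia,TYR,0.13
OGDHC,P,hypoxia,VAL,0.36
TRP,P,control,OGDHC,0.85
TRP,P,control,ALA,-0.21
TRP,P,control,ARG,-0.45
TRP,P,control,ASP,0.01
TRP,P,control,GABA,-0.55
TRP,P,control,GLU,0.64
TRP,P,control,GLY,-0.59
TRP,P,control,HIS,0.53
TRP,P,control,ILE,-0.46
TRP,P,control,LEU,-0.48
TRP,P,control,LYS,-0.08
TRP,P,control,MET,-0.63
TRP,P,control,PHE,-0.43
TRP,P,control,SER,0.02
TRP,P,control,TYR,-0.26
TRP,P,control,VAL,0.79
TRP,P,SP,OGDHC,-0.32
TRP,P,SP,ALA,-0.58
TRP,P,SP,ARG,-0.77
TRP,P,SP,ASP,-0.04
TRP,P,SP,GABA,-0.73
TRP,P,SP,GLU,0.52
TRP,P,SP,GLY,-0.78
TRP,P,SP,HIS,-0.43
TRP,P,SP,ILE,-0.8
TRP,P,SP,LEU,-0.78
TRP,P,SP,LYS,-0.84
TRP,P,SP,MET,-0.91
TRP,P,SP,PHE,-0.81
TRP,P,SP,SER,-0.66
TRP,P,SP,TYR,-0.57
TRP,P,SP,VAL,0.22
TRP,P,hypoxia,OGDHC,0.05
TRP,P,hypoxia,ALA,-0.02
TRP,P,hypoxia,ARG,-0.52
TRP,P,hypoxia,ASP,0.58
TRP,P,hypoxia,GABA,-0.45
TRP,P,hypoxia,GLU,0.89
TRP,P,hypoxia,GLY,-0.49
TRP,P,hypoxia,HIS,0.3
TRP,P,hypoxia,ILE,-0.39
TRP,P,hypoxia,LEU,-0.27
TRP,P,hypoxia,LYS,0.33
TRP,P,hypoxia,MET,-0.31
TRP,P,hypoxia,PHE,-0.64
TRP,P,hypoxia,SER,0.12
TRP,P,hypoxia,TYR,0.09
TRP,P,hypoxia,VAL,-0.79
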