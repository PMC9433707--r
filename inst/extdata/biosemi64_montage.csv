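label,x,y
Fp1,-0.2843,0.8750
AF7,-0.5407,0.7443
AF3,-0.3127,0.6707
F1,-0.1873,0.4636
F3,-0.3775,0.4663
F5,-0.5660,0.4920
F7,-0.7443,0.5407
FT7,-0.8750,0.2843
FC5,-0.6722,0.2580
FC3,-0.4414,0.2347
FC1,-0.2263,0.2263
C1,-0.2300,-0.0000
C3,-0.4600,-0.0000
C5,-0.6900,-0.0000
T7,-0.9200,-0.0000
TP7,-0.8750,-0.2843
CP5,-0.6722,-0.2580
CP3,-0.4414,-0.2347
CP1,-0.2263,-0.2263
P1,-0.1873,-0.4636
P3,-0.3775,-0.4663
P5,-0.5660,-0.4920
P7,-0.7443,-0.5407
P9,-0.9303,-0.6760
PO7,-0.5407,-0.7443
PO3,-0.3127,-0.6707
O1,-0.2843,-0.8750
Iz,0.0000,-1.1500
Oz,0.0000,-0.9200
POz,0.0000,-0.6900
Pz,0.0000,-0.4600
CPz,0.0000,-0.2300
Fpz,0.0000,0.9200
Fp2,0.2843,0.8750
AF8,0.5407,0.7443
AF4,0.3127,0.6707
AFz,0.0000,0.6900
Fz,0.0000,0.4600
F2,0.1873,0.4636
F4,0.3775,0.4663
F6,0.5660,0.4920
F8,0.7443,0.5407
FT8,0.8750,0.2843
FC6,0.6722,0.2580
FC4,0.4414,0.2347
FC2,0.2263,0.2263
FCz,0.0000,0.2300
Cz,0.0000,0.0000
C2,0.2300,0.0000
C4,0.4600,0.0000
C6,0.6900,0.0000
T8,0.9200,0.0000
TP8,0.8750,-0.2843
CP6,0.6722,-0.2580
CP4,0.4414,-0.2347
CP2,0.2263,-0.2263
P2,0.1873,-0.4636
P4,0.3775,-0.4663
P6,0.5660,-0.4920
P8,0.7443,-0.5407
P10,0.9303,-0.6760
PO8,0.5407,-0.7443
PO4,0.3127,-0.6707
O2,0.2843,-0.8750
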