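element,vdw_radius,mass
H,1.20,1.008
C,1.70,12.011
N,1.55,14.007
O,1.52,15.999
S,1.80,32.06
P,1.80,30.974
F,1.47,18.998
CL,1.75,35.45
BR,1.85,79.904
I,1.98,126.904
K,2.75,39.098
NA,2.27,22.990
MG,1.73,24.305
CA,2.31,40.078
ZN,1.39,65.38
FE,2.00,55.845
MN,2.00,54.938
SE,1.90,78.971
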