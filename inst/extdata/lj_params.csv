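type,sigma_angstrom,epsilon_kcal_mol
H,2.57,0.044
C,3.43,0.105
N,3.26,0.069
O,3.12,0.060
F,3.00,0.050
P,3.69,0.305
S,3.59,0.274
Cl,3.52,0.227
Br,3.73,0.251
I,4.01,0.339
B,3.64,0.180
Si,3.83,0.402
Se,3.77,0.291
Na,2.66,0.030
K,3.40,0.035
Mg,2.69,0.111
Ca,3.03,0.238
Zn,2.46,0.124
Fe,2.59,0.013
Mn,2.64,0.013
Cu,3.11,0.005
Ni,2.52,0.015
Co,2.56,0.014
Li,2.18,0.025
Al,4.01,0.505
As,3.77,0.309
[UNK],3.40,0.100
[MASK],3.40,0.100
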