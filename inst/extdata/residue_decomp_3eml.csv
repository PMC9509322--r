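residue,e_mm,e_polar,e_nonpolar,e_bind_res,source
PHE168,-11.72,4.54,-1.07,-8.25,reported
LEU249,-8.81,1.72,-0.61,-7.70,reported
MET270,-6.91,1.50,-0.85,-6.26,reported
ILE274,-4.59,1.09,-0.69,-4.19,reported
MET177,-3.74,0.91,-0.15,-2.98,reported
TRP246,-3.14,0.78,-0.41,-2.77,reported
ASP170,-0.45,-2.27,0.00,-2.72,reported
GLU13,0.67,-3.09,0.00,-2.42,reported
TYR271,-3.52,2.10,-0.55,-1.97,reported
LEU267,-1.36,-0.16,-0.29,-1.81,reported
VAL84,-2.67,1.15,-0.27,-1.79,reported
LEU85,-2.17,0.75,-0.23,-1.65,reported
GLU169,0.85,0.35,0.00,1.20,synthetic
ASN181,0.60,0.39,0.00,0.99,mixed
HIS250,0.25,0.20,0.00,0.45,synthetic
ASN253,0.18,0.12,0.00,0.30,synthetic
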