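residue,e_mm,e_polar,e_nonpolar,e_bind_res,source
PHE168,-12.26,5.06,-0.95,-8.15,reported
LEU85,-6.24,3.08,-0.29,-3.45,reported
VAL84,-5.79,2.98,-0.41,-3.22,reported
TRP246,-3.72,1.32,-0.71,-3.11,reported
MET177,-3.16,1.21,-0.37,-2.32,reported
ALA63,-3.71,2.21,-0.45,-1.95,reported
ASP52,-2.39,0.70,0.00,-1.69,reported
ILE60,-0.57,-0.51,-0.17,-1.25,reported
CYS185,-1.73,0.73,-0.16,-1.16,reported
ALA89,-1.66,0.65,-0.10,-1.11,reported
ILE66,-1.73,0.72,-0.09,-1.10,reported
ASP170,0.77,-1.78,0.00,-1.01,reported
ILE274,-0.75,0.20,-0.06,-0.61,mixed
LEU249,-1.10,0.40,-0.15,-0.85,synthetic
MET270,-0.80,0.35,-0.10,-0.55,synthetic
GLU169,0.50,0.25,0.00,0.75,synthetic
ASN181,2.90,1.68,0.00,4.58,mixed
HIS250,0.35,0.25,0.00,0.60,synthetic
ASN253,0.70,0.35,0.00,1.05,synthetic
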