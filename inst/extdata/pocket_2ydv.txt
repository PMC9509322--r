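ASP52
ILE60
ALA63
ILE66
VAL84
LEU85
ALA89
PHE168
GLU169
MET177
ASN181
CYS185
TRP246
LEU249
HIS250
ASN253
MET270
ILE274
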