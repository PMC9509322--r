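VAL84
LEU85
PHE168
GLU169
MET177
ASN181
TRP246
LEU249
HIS250
ASN253
LEU267
MET270
TYR271
ILE274
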