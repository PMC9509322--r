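system,ligand,e_vdw,e_vdw_sd,e_elec,e_elec_sd,e_polar,e_polar_sd,e_nonpolar,e_nonpolar_sd
3EML,ZMA241385,-142.27,10.66,-36.26,9.99,108.47,15.92,-17.36,0.97
2YDV,NECA,-121.89,8.62,-22.80,8.21,114.90,11.13,-15.50,0.84
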