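# Packaged example data

- `table1_summary.csv` — per-velocity SMD ensemble summaries (41 replicas per
  velocity, spring constant 600 kJ/mol/nm²) for the two A2A adenosine-receptor
  systems: 3EML/ZMA241385 (antagonist) and 2YDV/NECA (agonist). Input for
  fit-only runs of the Bell-Evans regression.
- `energy_components.csv` — MMPBSA binding-energy components (kJ/mol, with
  SDs) for the two systems.
- `residue_decomp_3eml.csv`, `residue_decomp_2ydv.csv` — per-residue MMPBSA
  decompositions. The `source` column marks provenance: `reported` rows are
  published per-residue values; `synthetic` rows are constructed values for
  the remaining common binding-pocket residues whose energies are not
  published per component — they preserve the published sign and hotspot
  classification of each residue but their magnitudes are illustrative only;
  `mixed` rows have a published total with a synthetic component split.
- `pocket_3eml.txt`, `pocket_2ydv.txt` — binding-pocket residue lists
  (heavy atoms within 5 Å of the ligand in the respective crystal
  structures); the two lists share 12 common residues.
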