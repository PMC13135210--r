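# Example code-set registry (symbolic codes; edit to taste).
# Load with: read_registry_yaml(system.file("extdata", "registry.yaml",
#                                           package = "teleabx"))
arti_viral: [ARTI-V1, ARTI-V2, ARTI-V3]
arti_strep: [ARTI-S1, ARTI-S2]
arti_aom: [ARTI-O1, ARTI-O2]
arti_sinusitis: [ARTI-N1, ARTI-N2]
excluded_dx: [EXC-PNEU, EXC-BRON, EXC-COV, EXC-FLU]
abx_warranting_codx: [CDX-UTI, CDX-SSTI]
well_visit_types: [well_child]
systemic_antibiotics:
  - amoxicillin
  - penicillin
  - amoxicillin-clavulanic acid
  - azithromycin
  - cefdinir
  - cephalexin
firstline:
  strep_pharyngitis: [amoxicillin, penicillin]
  acute_otitis_media: [amoxicillin, amoxicillin-clavulanic acid]
  bacterial_sinusitis: [amoxicillin, amoxicillin-clavulanic acid]
  viral_arti: []
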