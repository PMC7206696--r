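{
  "metabolites": [
    {"id": "glc_e", "name": "glucose", "compartment": "e"},
    {"id": "g6p_c", "name": "glucose-6-phosphate", "compartment": "c"},
    {"id": "pyr_c", "name": "pyruvate", "compartment": "c"}
  ],
  "reactions": [
    {"id": "EX_glc", "reactants": {}, "products": {"glc_e": 1},
     "reversible": false, "lower_bound": 0, "upper_bound": 10,
     "subsystem": "exchange", "gene_association": ""},
    {"id": "T_glc", "reactants": {"glc_e": 1}, "products": {"g6p_c": 1},
     "reversible": false, "lower_bound": 0, "upper_bound": 100,
     "subsystem": "transport", "gene_association": "g1"},
    {"id": "GLYC", "reactants": {"g6p_c": 1}, "products": {"pyr_c": 1},
     "reversible": false, "lower_bound": 0, "upper_bound": 100,
     "subsystem": "glycolysis", "gene_association": "g2 and g3"},
    {"id": "BIOMASS", "reactants": {"pyr_c": 1}, "products": {},
     "reversible": false, "lower_bound": 0, "upper_bound": 1000,
     "subsystem": "biomass", "gene_association": ""}
  ],
  "biomass_reaction": "BIOMASS",
  "biomass_components": ["pyr_c"],
  "media_components": ["glc_e"]
}
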