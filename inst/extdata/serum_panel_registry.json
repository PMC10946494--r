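{
  "name": "serum_plasma_16_panel",
  "description": "Registry of the 16 spin systems of the serum/plasma shift-mapping panel. Nominal delta values are standard positions for pH 7.4 phosphate-buffered serum/plasma at 600 MHz.",
  "systems": [
    {"id": "valine_CH3",         "metabolite": "valine",            "group": "-CH3",        "multiplicity": "doublet",  "nominal_delta": 0.9860, "chemical_class": "amino_acid"},
    {"id": "alanine_CH3",        "metabolite": "alanine",           "group": "-CH3",        "multiplicity": "doublet",  "nominal_delta": 1.4780, "chemical_class": "amino_acid"},
    {"id": "leucine_CH3",        "metabolite": "leucine",           "group": "(-CH3)2",     "multiplicity": "triplet",  "nominal_delta": 0.9550, "chemical_class": "amino_acid"},
    {"id": "isoleucine_CH3",     "metabolite": "isoleucine",        "group": "-CH3",        "multiplicity": "doublet",  "nominal_delta": 1.0090, "chemical_class": "amino_acid"},
    {"id": "tyrosine_CH",        "metabolite": "tyrosine",          "group": "(-CH)2",      "multiplicity": "multiplet","nominal_delta": 6.9030, "chemical_class": "amino_acid"},
    {"id": "glycine_CH2",        "metabolite": "glycine",           "group": "-CH2",        "multiplicity": "singlet",  "nominal_delta": 3.5620, "chemical_class": "amino_acid"},
    {"id": "histidine_CH",       "metabolite": "histidine",         "group": "-CH (imidazole)", "multiplicity": "singlet", "nominal_delta": 7.7890, "chemical_class": "amino_acid"},
    {"id": "phenylalanine_CH",   "metabolite": "phenylalanine",     "group": "(-CH)2",      "multiplicity": "doublet",  "nominal_delta": 7.3310, "chemical_class": "amino_acid"},
    {"id": "lactate_CH3",        "metabolite": "lactate",           "group": "-CH3",        "multiplicity": "doublet",  "nominal_delta": 1.3310, "chemical_class": "carboxylic_acid"},
    {"id": "acetate_CH3",        "metabolite": "acetate",           "group": "-CH3",        "multiplicity": "singlet",  "nominal_delta": 1.9190, "chemical_class": "carboxylic_acid"},
    {"id": "pyruvate_CH3",       "metabolite": "pyruvate",          "group": "-CH3",        "multiplicity": "singlet",  "nominal_delta": 2.3690, "chemical_class": "carboxylic_acid"},
    {"id": "formate_CH",         "metabolite": "formate",           "group": "-CH",         "multiplicity": "singlet",  "nominal_delta": 8.4580, "chemical_class": "carboxylic_acid",
     "note": "one-proton CH singlet; some figure captions label the group -CH2, the structure supports -CH"},
    {"id": "hydroxybutyrate_CH3","metabolite": "3-hydroxybutyrate", "group": "-CH3",        "multiplicity": "doublet",  "nominal_delta": 1.2010, "chemical_class": "carboxylic_acid"},
    {"id": "glucose_anomeric",   "metabolite": "glucose",           "group": "anomeric CH", "multiplicity": "doublet",  "nominal_delta": 5.2410, "chemical_class": "sugar"},
    {"id": "ethanol_CH3",        "metabolite": "ethanol",           "group": "-CH3",        "multiplicity": "triplet",  "nominal_delta": 1.1860, "chemical_class": "alcohol"},
    {"id": "acetone_CH3",        "metabolite": "acetone",           "group": "(-CH3)2",     "multiplicity": "singlet",  "nominal_delta": 2.2290, "chemical_class": "ketone"}
  ]
}
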