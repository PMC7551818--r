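{
  "schema_version": "1.0",
  "molecule_id": "Theopapuamide A",
  "method": "MN12SX/Def2TZVP/SMD(water)",
  "charge": 0,
  "multiplicity": 1,
  "unit": "eV",
  "eps_homo": -6.3114,
  "eps_lumo": -0.8210,
  "eps_somo_anion": -0.8169
}
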