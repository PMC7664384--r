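buffer,dH_kJ_per_mol,dH_sd_kJ_per_mol,source
HEPES,9.7,0.3,"PGI reaction enthalpy in HEPES buffer"
potassium_phosphate,9.6,0.2,"PGI reaction enthalpy in potassium phosphate buffer"
MOPS,11.1,0.5,"PGI reaction enthalpy in MOPS buffer at 310.15 K"
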