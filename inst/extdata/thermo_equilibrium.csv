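reaction,temperature_K,Q_mJ,Q_sd_mJ,Kc,Kc_units,dH_kJ_per_mol,dH_sd_kJ_per_mol,source
pgi,298.15,7.63,0.14,0.285,dimensionless,10.3,0.2,"PGI (F6P->G6P) at 298.15 K"
pgi,305.15,7.63,0.07,0.318,dimensionless,10.6,0.1,"PGI (F6P->G6P) at 305.15 K"
pgi,310.15,7.86,0.33,0.343,dimensionless,11.1,0.5,"PGI (F6P->G6P) at 310.15 K"
enolase,298.15,8.15,0.72,239.4,mol_per_kg,2.4,0.2,"enolase (PEP->2PG) at 298.15 K"
enolase,305.15,7.85,0.17,245.9,mol_per_kg,2.4,0.1,"enolase (PEP->2PG) at 305.15 K"
enolase,310.15,7.64,0.22,251.3,mol_per_kg,2.4,0.1,"enolase (PEP->2PG) at 310.15 K"
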