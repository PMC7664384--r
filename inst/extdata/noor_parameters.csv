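reaction,temperature_K,parameter,value,sd,units,source
pgi,298.15,rmax,7.03,0.58,umol_per_kg_s,"PGI substrate-saturation fit at 298.15 K"
pgi,298.15,K_F6P,4.35,0.64,mmol_per_kg,"PGI substrate-saturation fit at 298.15 K"
pgi,305.15,rmax,10.30,0.88,umol_per_kg_s,"PGI substrate-saturation fit at 305.15 K"
pgi,305.15,K_F6P,3.41,0.39,mmol_per_kg,"PGI substrate-saturation fit at 305.15 K"
pgi,310.15,rmax,13.21,1.20,umol_per_kg_s,"PGI substrate-saturation fit at 310.15 K"
pgi,310.15,K_F6P,3.26,0.09,mmol_per_kg,"PGI substrate-saturation fit at 310.15 K"
enolase,298.15,Lambda,0.34,0.01,milli_per_s,"enolase product-saturation fit at 298.15 K"
enolase,298.15,K_2PG,10.2,0.92,mmol_per_kg,"enolase product-saturation fit at 298.15 K"
enolase,305.15,Lambda,0.44,0.13,milli_per_s,"enolase product-saturation fit at 305.15 K"
enolase,305.15,K_2PG,13.8,3.35,mmol_per_kg,"enolase product-saturation fit at 305.15 K"
enolase,310.15,Lambda,0.57,0.03,milli_per_s,"enolase product-saturation fit at 310.15 K"
enolase,310.15,K_2PG,16.5,0.48,mmol_per_kg,"enolase product-saturation fit at 310.15 K"
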