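reaction,temperature_K,L_per_s,L_sd_per_s,source
pgi,298.15,217.18,14.27,"PGI flux-force fit at 298.15 K"
pgi,305.15,358.80,17.29,"PGI flux-force fit at 305.15 K"
pgi,310.15,518.44,43.84,"PGI flux-force fit at 310.15 K"
enolase,298.15,10.13,0.65,"enolase flux-force fit at 298.15 K"
enolase,305.15,14.57,3.20,"enolase flux-force fit at 305.15 K"
enolase,310.15,20.37,1.03,"enolase flux-force fit at 310.15 K"
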