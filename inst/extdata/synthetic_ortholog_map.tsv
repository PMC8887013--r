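id_a	id_b
Ps_PPP	Mb_PPP
Ps_Nudt	Mb_Nudt
Ps_myoIDH	Mb_myoIDH
Ps_DLDH	Mb_DLDH
Ps_perox001	Mb_GDH
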