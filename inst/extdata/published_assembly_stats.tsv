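species	level	length_gbp	ns_mbp	n50_mbp
Aonyx_cinereus	chr	2.44	15.5	130.94
Aonyx_cinereus	draft	2.42	1.35	0.1
Enhydra_lutris	chr	2.45	28.94	145.94
Enhydra_lutris	draft	2.46	29.68	38.75
Lutra_lutra	chr	2.44	0.1	148.99
Pteronura_brasiliensis	chr	2.46	11.89	133.38
Pteronura_brasiliensis	draft	2.45	1.4	0.17
Ailurus_fulgens	chr	2.34	34.41	143.8
Ailurus_fulgens	draft	2.34	34.04	2.98
Acinonyx_jubatus	chr	2.37	42.86	144.64
Acinonyx_jubatus	draft	2.37	42.06	3.12
Neofelis_nebulosa	chr	2.42	7.94	147.11
Neofelis_nebulosa	draft	2.41	5.89	1.38
Bison_bison	chr	2.83	199.31	101.69
Bison_bison	draft	2.83	195.77	7.19
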