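species	localized	not_amplified	declined	n_chromosomes	n_chrom_with_markers
Aonyx_cinereus	31	16	19	19	15
Enhydra_lutris	26	22	18	19	14
Lontra_canadensis	28	17	21	19	15
Lutra_lutra	26	22	18	19	13
Mustela_putorius_furo	28	17	21	20	14
Pteronura_brasiliensis	30	18	18	19	13
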