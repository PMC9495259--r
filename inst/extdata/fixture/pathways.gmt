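PWA	anchor_a	G01	G11	G12	G14	G15
PWB	anchor_b	G01	G12	G13	G16	G17
PWC	background_1	G05	G06	G07	G08
PWD	background_2	G10	G18	G19	G20
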