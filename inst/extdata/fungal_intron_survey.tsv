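species	accession	gene	label
Rozella allomycis	NC_021611	cox1	P731
Rhizopus oryzae	NC_006836	atp9	P157
Rhizopus oryzae	NC_006836	cob	P393
Rhizopus oryzae	NC_006836	cob	P490
Rhizopus oryzae	NC_006836	cox1	P386
Rhizopus oryzae	NC_006836	cox1	P615
Rhizopus oryzae	NC_006836	cox1	P720
Rhizopus oryzae	NC_006836	cox2	P685
Rhizopus oryzae	NC_006836	cox3	P219
Rhizopus oryzae	NC_006836	nad3	P124
Conidiobolus heterosporus	MK049352	atp6	U374
Conidiobolus heterosporus	MK049352	atp9	P69
Conidiobolus heterosporus	MK049352	cob	P201
Conidiobolus heterosporus	MK049352	cob	P393
Conidiobolus heterosporus	MK049352	cob	P429
Conidiobolus heterosporus	MK049352	cob	P506
Conidiobolus heterosporus	MK049352	cob	P600
Conidiobolus heterosporus	MK049352	cob	P759
Conidiobolus heterosporus	MK049352	cob	P823
Conidiobolus heterosporus	MK049352	cox1	P212
Conidiobolus heterosporus	MK049352	cox1	P281
Conidiobolus heterosporus	MK049352	cox1	P386
Conidiobolus heterosporus	MK049352	cox1	P461
Conidiobolus heterosporus	MK049352	cox1	P550
Conidiobolus heterosporus	MK049352	cox1	P615
Conidiobolus heterosporus	MK049352	cox1	P720
Conidiobolus heterosporus	MK049352	cox1	P731
Conidiobolus heterosporus	MK049352	cox1	P807
Conidiobolus heterosporus	MK049352	cox1	P867
Conidiobolus heterosporus	MK049352	cox1	P1107
Conidiobolus heterosporus	MK049352	cox1	P1125
Conidiobolus heterosporus	MK049352	cox1	P1305
Conidiobolus heterosporus	MK049352	cox2	P228
Conidiobolus heterosporus	MK049352	cox2	P328
Conidiobolus heterosporus	MK049352	cox3	P447
Conidiobolus heterosporus	MK049352	nad1	U166
Conidiobolus heterosporus	MK049352	nad1	P636
Conidiobolus heterosporus	MK049352	nad4	P915
Conidiobolus heterosporus	MK049352	nad5	P426
Conidiobolus heterosporus	MK049352	nad5	U1059
Allomyces macrogynus	NC_001715	cob	P201
Allomyces macrogynus	NC_001715	cob	P417
Allomyces macrogynus	NC_001715	cob	P429
Allomyces macrogynus	NC_001715	cob	P490
Allomyces macrogynus	NC_001715	cob	P600
Allomyces macrogynus	NC_001715	cob	P759
Allomyces macrogynus	NC_001715	cox1	P221
Allomyces macrogynus	NC_001715	cox1	P281
Allomyces macrogynus	NC_001715	cox1	S313
Allomyces macrogynus	NC_001715	cox1	P372
Allomyces macrogynus	NC_001715	cox1	P386
Allomyces macrogynus	NC_001715	cox1	P615
Allomyces macrogynus	NC_001715	cox1	P678
Allomyces macrogynus	NC_001715	cox1	P867
Allomyces macrogynus	NC_001715	cox1	P1030
Allomyces macrogynus	NC_001715	cox1	P1107
Allomyces macrogynus	NC_001715	cox1	P1230
Allomyces macrogynus	NC_001715	cox1	P1296
Allomyces macrogynus	NC_001715	cox2	P685
Allomyces macrogynus	NC_001715	nad1	P166
Allomyces macrogynus	NC_001715	nad1	P636
Allomyces macrogynus	NC_001715	nad5	P426
Allomyces macrogynus	NC_001715	nad5	P717
Allomyces macrogynus	NC_001715	nad5	P934
Hyaloraphidium curvatum	NC_003048	cob	P411
Candida albicans	NC_002653	cob	U393
Candida albicans	NC_002653	cob	U429
Candida albicans	NC_002653	cox1	P386
Candida albicans	NC_002653	cox1	P709
Candida albicans	NC_002653	cox1	P720
Candida albicans	NC_002653	cox1	P1107
Grosmannia piceiperda	FJ717837	rps3	P159
Isaria cicadae	MH922223	atp6	U572
Isaria cicadae	MH922223	atp9	P181
Isaria cicadae	MH922223	cob	P393
Isaria cicadae	MH922223	cob	P490
Isaria cicadae	MH922223	cob	P506
Isaria cicadae	MH922223	cob	P823
Isaria cicadae	MH922223	cox1	P212
Isaria cicadae	MH922223	cox1	P281
Isaria cicadae	MH922223	cox1	P709
Isaria cicadae	MH922223	cox1	P720
Isaria cicadae	MH922223	cox1	P731
Isaria cicadae	MH922223	cox1	P1057
Isaria cicadae	MH922223	cox1	P1281
Isaria cicadae	MH922223	cox2	P228
Isaria cicadae	MH922223	cox2	P357
Isaria cicadae	MH922223	cox2	P651
Isaria cicadae	MH922223	cox3	P219
Isaria cicadae	MH922223	cox3	P631
Isaria cicadae	MH922223	nad1	P636
Isaria cicadae	MH922223	nad5	P417
Isaria cicadae	MH922223	nad5	P570
Neurospora crassa	NC_026614	atp6	P344
Neurospora crassa	NC_026614	cob	P393
Neurospora crassa	NC_026614	cob	P490
Neurospora crassa	NC_026614	nad1	P636
Neurospora crassa	NC_026614	nad3	P90
Neurospora crassa	NC_026614	nad4	P505
Neurospora crassa	NC_026614	nad4L	P263
Neurospora crassa	NC_026614	nad5	P324
Neurospora crassa	NC_026614	nad5	P717
Saccharomyces cerevisiae	NC_001224	cob	S415
Saccharomyces cerevisiae	NC_001224	cob	P429
Saccharomyces cerevisiae	NC_001224	cob	P506
Saccharomyces cerevisiae	NC_001224	cob	P759
Saccharomyces cerevisiae	NC_001224	cob	P809
Saccharomyces cerevisiae	NC_001224	cox1	S169
Saccharomyces cerevisiae	NC_001224	cox1	S205
Saccharomyces cerevisiae	NC_001224	cox1	P240
Saccharomyces cerevisiae	NC_001224	cox1	P720
Saccharomyces cerevisiae	NC_001224	cox1	P971
Saccharomyces cerevisiae	NC_001224	cox1	P1107
Saccharomyces cerevisiae	NC_001224	cox1	S1132
Schizosaccharomyces pombe	NC_001326	cob	S687
Schizosaccharomyces pombe	NC_001326	cox1	P386
Schizosaccharomyces pombe	NC_001326	cox1	P731
Cryptococcus neoformans	NC_004336	cob	P490
Cryptococcus neoformans	NC_004336	nad1	P166
Puccinia striiformis	NC_039655	cob	U429
Puccinia striiformis	NC_039655	cob	P809
Puccinia striiformis	NC_039655	cox1	P386
Puccinia striiformis	NC_039655	cox1	U615
Puccinia striiformis	NC_039655	cox1	P709
Puccinia striiformis	NC_039655	cox1	P720
Puccinia striiformis	NC_039655	cox1	P807
Puccinia striiformis	NC_039655	cox1	U1107
Puccinia striiformis	NC_039655	cox2	P314
Puccinia striiformis	NC_039655	nad4	S495
Puccinia striiformis	NC_039655	nad5	P417
Puccinia striiformis	NC_039655	nad5	P717
Tilletia indica	NC_009880	cob	P490
Tilletia indica	NC_009880	cox1	P212
Tilletia indica	NC_009880	cox1	P386
Tilletia indica	NC_009880	cox1	P709
Tilletia indica	NC_009880	cox1	P1107
Tilletia indica	NC_009880	cox1	P1305
Tilletia indica	NC_009880	nad5	P417
Tilletia indica	NC_009880	nad5	P717
Tricholoma matsutake	NC_028135	cob	P823
Tricholoma matsutake	NC_028135	cox1	U281
Tricholoma matsutake	NC_028135	cox1	P372
Tricholoma matsutake	NC_028135	cox1	P386
Tricholoma matsutake	NC_028135	cox1	P720
Tricholoma matsutake	NC_028135	cox1	P900
Tricholoma matsutake	NC_028135	cox2	P318
Tricholoma matsutake	NC_028135	cox2	P357
Tricholoma matsutake	NC_028135	nad1	P276
Tricholoma matsutake	NC_028135	nad5	P417
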