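isolate	ST	bcaT	glyA	pdp	pepXP	pgk	recN	origin	markers
CC1_founder	1	1	1	1	1	1	1	dairy starter	lacE;prtP
CC2_founder	2	2	2	2	2	2	2	dairy starter	lacE;prtP
singleton_01	3	3	3	3	3	3	3	fermented product	
singleton_02	4	4	3	4	4	4	4	plant	
singleton_03	5	5	4	5	5	5	5	raw milk	
singleton_04	6	6	5	6	6	6	5	animal skin	
singleton_05	7	7	6	7	7	7	6	fermented product	
singleton_06	8	8	7	8	8	8	5	plant	
CC1_slv1	9	9	1	1	1	1	1	dairy starter	lacE;prtP
CC1_slv2	10	1	8	1	1	1	1	dairy starter	lacE;prtP
CC1_slv3	11	1	1	9	1	1	1	dairy starter	lacE;prtP
CC1_slv4	12	1	1	1	9	1	1	dairy starter	lacE;prtP
CC2_slv1	13	10	2	2	2	2	2	dairy starter	lacE;prtP
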