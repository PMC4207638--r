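individual	breed	tissue	calls	gains	losses
Akhal-teke 1	Akhal-teke	blood	37	12	25
Akhal-teke 2	Akhal-teke	blood	26	13	13
American Miniature Horse 1	American Miniature Horse	blood	59	16	43
American Miniature Horse 2	American Miniature Horse	hair	46	4	42
American Quarter Horse 1	American Quarter Horse	blood	12	0	12
American Quarter Horse 2	American Quarter Horse	blood	21	2	19
American Quarter Horse 3	American Quarter Horse	blood	14	10	4
Arabian 1	Arabian	blood	21	17	4
Arabian 2	Arabian	hair	17	0	17
Belgian 1	Belgian	blood	31	14	17
Belgian 2	Belgian	hair	14	1	13
Caspian Pony 1	Caspian Pony	blood	40	16	24
Caspian Pony 2	Caspian Pony	hair	12	1	11
Clydesdale 1	Clydesdale	blood	25	6	19
Clydesdale 2	Clydesdale	hair	16	1	15
Exmoor Pony 1	Exmoor Pony	blood	29	15	14
Exmoor Pony 2	Exmoor Pony	hair	18	8	10
Fell Pony 1	Fell Pony	blood	25	11	14
Fell Pony 2	Fell Pony	hair	47	11	36
Friesian 1	Friesian	blood	29	6	23
Friesian 2	Friesian	blood	39	10	29
Friesian 3	Friesian	blood	41	9	32
Friesian 4	Friesian	blood	22	12	10
Mongolian Native Horse 1	Mongolian Native Horse	hair	22	1	21
Mongolian Native Horse 2	Mongolian Native Horse	hair	18	2	16
Percheron 1	Percheron	blood	17	11	6
Percheron 2	Percheron	hair	12	1	11
Przewalski's Horse 1	Przewalski's Horse	fibroblast	21	5	16
Przewalski's Horse 2	Przewalski's Horse	fibroblast	21	3	18
Sorraia 1	Sorraia	blood	36	8	28
Sorraia 2	Sorraia	hair	18	1	17
Standardbred 1	Standardbred	blood	17	7	10
Standardbred 2	Standardbred	blood	44	13	31
Swiss Warmblood 1	Swiss Warmblood	blood	23	1	22
Swiss Warmblood 2	Swiss Warmblood	blood	30	6	24
Swiss Warmblood 3	Swiss Warmblood	blood	29	9	20
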