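trait	E	G	P	EG	EP	GP	EGP
MY	7	15	6	2	2	4	1
FY	4	2	0	1	0	0	0
PY	1	5	0	0	0	0	0
FPC	28	23	22	23	22	22	22
PPC	8	3	3	1	1	3	1
PL	6	10	1	3	0	1	0
SCS	6	7	0	0	0	0	0
DPR	7	8	2	3	2	2	2
SCE	8	3	2	0	2	0	0
DCE	3	3	0	1	0	0	0
SSB	8	6	6	2	6	2	2
DSB	6	11	2	0	0	0	0
NM	4	1	0	0	0	0	0
STA	11	24	1	5	1	0	0
STR	5	12	0	1	0	0	0
BD	7	14	0	2	0	0	0
RW	12	31	2	6	1	1	1
DF	8	7	1	1	1	1	1
RA	19	22	6	10	4	6	4
FUA	6	13	1	1	1	0	0
RUH	9	13	4	2	2	0	0
UD	5	14	0	3	0	0	0
UC	13	10	3	2	3	0	0
FTP	17	16	5	6	4	2	2
RTP	12	13	3	2	3	0	0
TL	16	8	5	3	5	1	1
FA	6	15	4	4	1	2	1
RLS	2	2	6	2	1	1	1
RLR	5	18	3	4	0	1	0
FL	11	14	3	6	2	2	2
FS	10	21	4	0	2	0	0
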