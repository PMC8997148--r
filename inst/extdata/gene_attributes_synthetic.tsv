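symbol	is_tumor_suppressor	lof_disease_mechanism	pli	protein_size
ATM	TRUE	TRUE	0	3056
BLM	TRUE	TRUE	0	1417
BRCA1	TRUE	TRUE	0	1863
BRCA2	TRUE	TRUE	0	3418
CHEK2	TRUE	TRUE	0	543
CLTCL1	FALSE	FALSE	0	1640
COL3A1	FALSE	TRUE	1	1466
CUX1	TRUE	TRUE	1	678
CYLD	TRUE	TRUE	1	956
DCC	TRUE	FALSE	0.99	1447
DDX3X	FALSE	FALSE	1	662
ERCC1	FALSE	TRUE	0	297
ERCC6	FALSE	TRUE	0	1493
EXT2	TRUE	TRUE	0	718
FANCE	TRUE	TRUE	0	536
FAT1	TRUE	TRUE	0	4588
FLCN	TRUE	TRUE	0.79	579
FLG	FALSE	FALSE	0	4061
G6PC3	FALSE	TRUE	0	346
HIF1A	FALSE	FALSE	0	826
MSH6	TRUE	TRUE	0	1360
MUTYH	TRUE	TRUE	0	546
NFKBIE	FALSE	TRUE	0.77	500
NSD1	TRUE	TRUE	1	2696
PALB2	TRUE	TRUE	0	1186
PBRM1	TRUE	TRUE	1	1689
PMS1	FALSE	TRUE	0	932
POLQ	FALSE	FALSE	0	2590
PRDM9	FALSE	TRUE	0	894
PTCH2	TRUE	TRUE	0	1203
RAD51C	TRUE	TRUE	0	376
RBM8A	FALSE	FALSE	0.57	174
RPS7	FALSE	TRUE	0.95	194
SPEN	FALSE	FALSE	1	3664
TP53	TRUE	TRUE	0.53	393
TSC2	TRUE	TRUE	1	1807
USP6	FALSE	TRUE	0	1406
WRN	TRUE	TRUE	0	1432
ZFHX3	TRUE	TRUE	1	3703
ZMYM3	FALSE	FALSE	1	1370
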