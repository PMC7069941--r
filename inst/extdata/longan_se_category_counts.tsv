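row	library	unique_count	total_count
Total sRNAs	NEC	1008620	10737344
Total sRNAs	EC	3116033	11439171
Total sRNAs	ICpEC	4069330	11086034
Total sRNAs	GE	4102483	11870025
Mapping to genome	NEC	703592	9169172
Mapping to genome	EC	2304585	9859682
Mapping to genome	ICpEC	2995773	9068010
Mapping to genome	GE	2902693	9588866
exon_antisense	NEC	33304	1058371
exon_antisense	EC	86317	899353
exon_antisense	ICpEC	118027	597904
exon_antisense	GE	110712	679814
exon_sense	NEC	73712	1304559
exon_sense	EC	198704	1333048
exon_sense	ICpEC	177847	791515
exon_sense	GE	171952	939647
intron_antisense	NEC	27405	629664
intron_antisense	EC	72938	690305
intron_antisense	ICpEC	102814	433831
intron_antisense	GE	117463	559132
intron_sense	NEC	35807	728128
intron_sense	EC	99419	653364
intron_sense	ICpEC	134189	518287
intron_sense	GE	147545	610314
miRNA	NEC	7099	1398392
miRNA	EC	8905	421499
miRNA	ICpEC	8830	354236
miRNA	GE	10658	403510
rRNA	NEC	34742	1794585
rRNA	EC	41221	1735104
rRNA	ICpEC	28582	642321
rRNA	GE	36052	984229
repeat	NEC	77282	393265
repeat	EC	481696	1242134
repeat	ICpEC	639164	1769925
repeat	GE	479149	1279780
snRNA	NEC	2246	62387
snRNA	EC	2873	43714
snRNA	ICpEC	2028	21565
snRNA	GE	2883	43480
snoRNA	NEC	2212	57337
snoRNA	EC	3356	84727
snoRNA	ICpEC	2504	38772
snoRNA	GE	3774	92584
tRNA	NEC	4251	119579
tRNA	EC	7064	122075
tRNA	ICpEC	4720	61901
tRNA	GE	5896	80031
unannotated	NEC	710560	3191077
unannotated	EC	2113540	4213848
unannotated	ICpEC	2850625	5855777
unannotated	GE	3016399	6197504
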