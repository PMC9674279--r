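# Gene features of the human mitochondrial genome (NC_001807.4).
# Coordinates are 0-based half-open on the heavy-strand reference.
# Curated from the standard human mtDNA gene map; validated in the package
# test suite (start codons, terminal codons, tRNA junction sequences).
name	kind	strand	start	end
TRNF	tRNA	heavy	577	648
RNR1	rRNA	heavy	648	1602
TRNV	tRNA	heavy	1602	1671
RNR2	rRNA	heavy	1671	3230
TRNL1	tRNA	heavy	3230	3305
ND1	mRNA	heavy	3307	4263
TRNI	tRNA	heavy	4263	4332
TRNQ	tRNA	light	4329	4401
TRNM	tRNA	heavy	4402	4470
ND2	mRNA	heavy	4470	5512
TRNW	tRNA	heavy	5512	5580
TRNA	tRNA	light	5587	5656
TRNN	tRNA	light	5657	5730
TRNC	tRNA	light	5761	5827
TRNY	tRNA	light	5826	5892
CO1	mRNA	heavy	5904	7446
TRNS1	tRNA	light	7446	7515
TRND	tRNA	heavy	7518	7586
CO2	mRNA	heavy	7586	8270
TRNK	tRNA	heavy	8295	8365
ATP8	mRNA	heavy	8366	8573
ATP6	mRNA	heavy	8527	9208
CO3	mRNA	heavy	9207	9991
TRNG	tRNA	heavy	9991	10059
ND3	mRNA	heavy	10059	10405
TRNR	tRNA	heavy	10405	10470
ND4L	mRNA	heavy	10470	10767
ND4	mRNA	heavy	10760	12138
TRNH	tRNA	heavy	12138	12207
TRNS2	tRNA	heavy	12207	12266
TRNL2	tRNA	heavy	12266	12337
ND5	mRNA	heavy	12337	14149
ND6	mRNA	light	14149	14674
TRNE	tRNA	light	14674	14743
CYB	mRNA	heavy	14747	15888
TRNT	tRNA	heavy	15888	15954
TRNP	tRNA	light	15956	16024
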