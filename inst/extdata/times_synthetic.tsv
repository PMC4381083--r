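codon	time_au	source
GCA	25.7	synthetic_midband
GCC	74.03	synthetic_midband
GCG	87.37	synthetic_midband
GCT	125.7	synthetic_midband
TGC	26.4	synthetic_midband
TGT	126.4	synthetic_midband
GAC	27.1	synthetic_midband
GAT	127.1	synthetic_midband
GAA	62.8	synthetic_midband
GAG	102.8	synthetic_midband
TTC	28.5	synthetic_midband
TTT	128.5	synthetic_midband
GGA	64.2	synthetic_midband
GGC	77.53	synthetic_midband
GGG	90.87	synthetic_midband
GGT	129.2	synthetic_midband
CAC	29.9	synthetic_midband
CAT	129.9	synthetic_midband
ATA	30.6	synthetic_midband
ATC	80.6	synthetic_midband
ATT	130.6	synthetic_midband
AAA	66.3	synthetic_midband
AAG	106.3	synthetic_midband
CTA	32	synthetic_midband
CTC	52	synthetic_midband
CTG	72	synthetic_midband
CTT	92	synthetic_midband
TTA	112	synthetic_midband
TTG	132	synthetic_midband
ATG	82.7	synthetic_midband
AAC	33.4	synthetic_midband
AAT	133.4	synthetic_midband
CCA	34.1	synthetic_midband
CCC	82.43	synthetic_midband
CCG	95.77	synthetic_midband
CCT	134.1	synthetic_midband
CAA	34.8	synthetic_midband
CAG	134.8	synthetic_midband
AGA	70.5	synthetic_midband
AGG	78.5	synthetic_midband
CGA	75.5	synthetic_midband
CGC	94.5	synthetic_midband
CGG	102.5	synthetic_midband
CGT	135.5	synthetic_midband
AGC	36.2	synthetic_midband
AGT	56.2	synthetic_midband
TCA	76.2	synthetic_midband
TCC	96.2	synthetic_midband
TCG	116.2	synthetic_midband
TCT	136.2	synthetic_midband
ACA	36.9	synthetic_midband
ACC	70.23	synthetic_midband
ACG	103.57	synthetic_midband
ACT	136.9	synthetic_midband
GTA	37.6	synthetic_midband
GTC	70.93	synthetic_midband
GTG	104.27	synthetic_midband
GTT	137.6	synthetic_midband
TGG	88.3	synthetic_midband
TAC	39	synthetic_midband
TAT	139	synthetic_midband
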