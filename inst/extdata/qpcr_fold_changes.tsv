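gene	log2fc_rnaseq	fold_qpcr	normalized_qpcr
sart1	3.35	1.64	0.64
tp53	4.22	3.14	2.14
mdm2	4.07	2.99	1.99
clu	3.76	3.61	2.62
cldn5a	3.42	1.20	0.20
mmp9	8.38	61.99	61.01
prpf31	3.71	2.75	1.76
lsm7	3.71	3.22	2.23
pde6h	-16.92	0.00	-1.00
opn1sw1	-7.29	0.00	-1.00
crx	-1.71	0.05	-0.95
actb1	0.71	1.00	0.00
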