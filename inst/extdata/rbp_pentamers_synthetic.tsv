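rbp	pentamer
SRSF10	AGAGA
SRSF10	AAGAA
hnRNP-L	ACACA
hnRNP-L	CACAC
hnRNP-LL	ACACA
hnRNP-LL	CACAC
RBM24	TGTGT
RBM24	GTGTG
SRSF1	GGAGG
PTBP1	TCTCT
PTBP1	CTCTC
NOVA1	TCATT
RBFOX1	GCATG
MBNL1	GCTTG
CELF1	TGTTT
TIA1	TTTTA
QKI	CTAAC
TRA2B	GAAGA
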