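name	consensus
USP_GGGGTCACS	GGGGTCACS
JHRE_GRCACGCKVS	GRCACGCKVS
MET_CACGCGMC	CACGCGMC
ADF_BMGYBGYYGYNGMVBV	BMGYBGYYGYNGMVBV
PPARG_RXRA_DR1	RGGKCAAAGGKCA
EBOX_CACGTG	CACGTG
TATA_BOX	TATAWAWR
CAAT_BOX	CCAAT
GATA	WGATAR
CREB	TGACGTCA
AP1	TGASTCA
NFKB	GGGRNNYYCC
SRF	CCWWWWWWGG
ETS	CMGGAWGY
MEF2	YTAWWWWTAR
HSE	TTCNNGAA
SP1	GGGGCGGGGC
OCT1	ATGCAAAT
NRF1	GCGCATGCGC
SYN_COFACTOR_3BP	GTCACSGCAT
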