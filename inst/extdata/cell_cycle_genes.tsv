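gene	phase
MCM5	S
PCNA	S
TYMS	S
FEN1	S
MCM2	S
MCM4	S
RRM1	S
UNG	S
GINS2	S
MCM6	S
CDCA7	S
DTL	S
HMGB2	G2M
CDK1	G2M
NUSAP1	G2M
UBE2C	G2M
BIRC5	G2M
TPX2	G2M
TOP2A	G2M
NDC80	G2M
CKS2	G2M
NUF2	G2M
CKS1B	G2M
MKI67	G2M
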