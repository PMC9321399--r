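feature_id,value
gender,
baseline_das,
KRT19,
HAO1,
CXCL1,
RARRES2,
FCRL6,
REN,
IL13,
SPON1,
MMP1,
ARNT,
TNFSF13B,
PRKCQ,
TNFRSF10B,
OSCAR,
CCL8,
DPP10,
GDNF,
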