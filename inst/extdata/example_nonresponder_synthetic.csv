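feature_id,value
gender,0
ARNT,4.691
baseline_das,2.8
CCL8,9.773
CXCL1,3.037
DPP10,3.026
FCRL6,8.82
GDNF,6.934
HAO1,3.965
IL13,7.818
KRT19,7.615
MMP1,9.906
OSCAR,2.671
PRKCQ,2.035
RARRES2,2.34
REN,10.083
SPON1,5.004
TNFRSF10B,4.311
TNFSF13B,6.635
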