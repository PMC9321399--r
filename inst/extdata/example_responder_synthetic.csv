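feature_id,value
gender,0
ARNT,-0.393
baseline_das,8
CCL8,7.877
CXCL1,5.357
DPP10,5.454
FCRL6,2.716
GDNF,3.826
HAO1,1.353
IL13,1.682
KRT19,5.375
MMP1,8.054
OSCAR,4.835
PRKCQ,6.443
RARRES2,7.724
REN,5.003
SPON1,8.476
TNFRSF10B,2.311
TNFSF13B,9.851
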