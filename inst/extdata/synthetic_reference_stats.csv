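"feature","mean","sd","n"
"KRT19",6.495,0.56,89
"HAO1",2.659,0.653,89
"CXCL1",4.197,0.58,89
"RARRES2",5.032,1.346,89
"FCRL6",5.768,1.526,89
"REN",7.543,1.27,89
"IL13",4.75,1.534,89
"SPON1",6.74,0.868,89
"MMP1",8.98,0.463,89
"ARNT",2.149,1.271,89
"TNFSF13B",8.243,0.804,89
"PRKCQ",4.239,1.102,89
"TNFRSF10B",3.311,0.5,89
"OSCAR",3.753,0.541,89
"CCL8",8.825,0.474,89
"DPP10",4.24,0.607,89
"GDNF",5.38,0.777,89
"baseline_das",5.4,1.3,89
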