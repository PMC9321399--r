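feature,uniprot,entrez,gene_name,panel,fi,beta
intercept,-,-,-,-,,3.800
baseline_das,-,-,-,-,0.21,2.133
gender,-,-,-,-,0.17,0.116
KRT19,P08727,3880,Keratin 19,IMMUNE,0.13,-2.126
HAO1,Q9UJM8,54363,Hydroxyacid oxidase 1,CVD II,0.13,-2.068
CXCL1,P09341,2919,C-X-C motif chemokine ligand 1,CVD II + INFLAM,0.10,0.421
RARRES2,Q99969,5919,Retinoic acid receptor responder 2,CVD III,0.10,2.488
FCRL6,Q6DN72,343413,Fc receptor like 6,IMMUNE,0.10,-2.595
REN,P00797,5972,Renin,CVD II,0.10,-0.960
IL13,P35225,3596,Interleukin 13,INFLAM,0.09,-0.651
SPON1,Q9HCB6,10418,Spondin 1,CVD III,0.08,2.557
MMP1,P03956,4312,Matrix metallopeptidase 1,INFLAM,0.08,-0.830
ARNT,P27540,405,Aryl hydrocarbon receptor nuclear translocator,IMMUNE,0.07,-0.758
TNFSF13B,Q9Y275,10673,Tumor necrosis factor superfamily member 13b,CVD III,0.07,1.281
PRKCQ,Q04759,5588,Protein kinase C theta,IMMUNE,0.07,0.744
TNFRSF10B,O14763,8795,TNF receptor superfamily member 10b,CVD II,0.07,-0.421
OSCAR,Q8IYS5,126014,"Osteoclast associated, immunoglobulin-like receptor",CVD II,0.05,2.661
CCL8,P80075,6355,C-C motif chemokine ligand 8,INFLAM,0.05,-0.243
DPP10,Q8N608,57628,Dipeptidyl peptidase like 10,IMMUNE,0.05,2.990
GDNF,P39905,2668,Glial cell derived neurotrophic factor,INFLAM,0.05,-2.574
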