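arm,country,region,scope,n_households,n_people,households_stopping_od,households_gaining_ownership,delta_od,delta_ownership
All CLTS,All,All,pooled,12217,58248,1605,1086,-0.13,0.09
HEW CLTS,Ethiopia,All,country,1624,9829,168,70,-0.10,0.04
Teacher CLTS,Ethiopia,All,country,3838,21216,421,229,-0.11,0.06
HEW CLTS,Ethiopia,Oromia,region,651,4013,310,282,-0.48,0.43
Teacher CLTS,Ethiopia,Oromia,region,1586,9153,895,841,-0.56,0.53
HEW CLTS,Ethiopia,SNNP,region,973,5816,-141,-211,0.15,-0.22
Teacher CLTS,Ethiopia,SNNP,region,2252,12063,-474,-612,0.21,-0.27
NGO CLTS,Ghana,All,country,3443,14263,298,305,-0.09,0.09
CLTS+NL Training,Ghana,All,country,3312,12940,718,481,-0.22,0.15
NGO CLTS,Ghana,Central,region,1463,4670,89,102,-0.06,0.07
CLTS+NL Training,Ghana,Central,region,1495,5041,237,58,-0.16,0.04
NGO CLTS,Ghana,Upper West,region,808,5208,108,64,-0.13,0.08
CLTS+NL Training,Ghana,Upper West,region,540,3474,287,179,-0.53,0.33
NGO CLTS,Ghana,Volta,region,1172,4385,100,139,-0.09,0.12
CLTS+NL Training,Ghana,Volta,region,1277,4425,195,243,-0.15,0.19
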