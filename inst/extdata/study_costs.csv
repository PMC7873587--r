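arm,country,region,scope,category,amount_usd
All CLTS,All,All,pooled,management,79660
All CLTS,All,All,pooled,training,210850
All CLTS,All,All,pooled,facilitation,169595
All CLTS,All,All,pooled,local_actor_time,12583
All CLTS,All,All,pooled,community_time,21529
All CLTS,All,All,pooled,hired_labor,21942
All CLTS,All,All,pooled,hardware,59901
HEW CLTS,Ethiopia,All,country,management,8690
HEW CLTS,Ethiopia,All,country,training,17617
HEW CLTS,Ethiopia,All,country,facilitation,4891
HEW CLTS,Ethiopia,All,country,local_actor_time,1926
HEW CLTS,Ethiopia,All,country,community_time,2546
HEW CLTS,Ethiopia,All,country,hired_labor,0
HEW CLTS,Ethiopia,All,country,hardware,1070
Teacher CLTS,Ethiopia,All,country,management,14867
Teacher CLTS,Ethiopia,All,country,training,33229
Teacher CLTS,Ethiopia,All,country,facilitation,6225
Teacher CLTS,Ethiopia,All,country,local_actor_time,3863
Teacher CLTS,Ethiopia,All,country,community_time,4151
Teacher CLTS,Ethiopia,All,country,hired_labor,0
Teacher CLTS,Ethiopia,All,country,hardware,1013
HEW CLTS,Ethiopia,Oromia,region,management,4345
HEW CLTS,Ethiopia,Oromia,region,training,9979
HEW CLTS,Ethiopia,Oromia,region,facilitation,2820
HEW CLTS,Ethiopia,Oromia,region,local_actor_time,1084
HEW CLTS,Ethiopia,Oromia,region,community_time,1435
HEW CLTS,Ethiopia,Oromia,region,hired_labor,0
HEW CLTS,Ethiopia,Oromia,region,hardware,911
Teacher CLTS,Ethiopia,Oromia,region,management,7434
Teacher CLTS,Ethiopia,Oromia,region,training,17279
Teacher CLTS,Ethiopia,Oromia,region,facilitation,1118
Teacher CLTS,Ethiopia,Oromia,region,local_actor_time,1889
Teacher CLTS,Ethiopia,Oromia,region,community_time,1886
Teacher CLTS,Ethiopia,Oromia,region,hired_labor,0
Teacher CLTS,Ethiopia,Oromia,region,hardware,633
HEW CLTS,Ethiopia,SNNP,region,management,4345
HEW CLTS,Ethiopia,SNNP,region,training,7638
HEW CLTS,Ethiopia,SNNP,region,facilitation,2071
HEW CLTS,Ethiopia,SNNP,region,local_actor_time,842
HEW CLTS,Ethiopia,SNNP,region,community_time,1110
HEW CLTS,Ethiopia,SNNP,region,hired_labor,0
HEW CLTS,Ethiopia,SNNP,region,hardware,159
Teacher CLTS,Ethiopia,SNNP,region,management,7434
Teacher CLTS,Ethiopia,SNNP,region,training,15951
Teacher CLTS,Ethiopia,SNNP,region,facilitation,5107
Teacher CLTS,Ethiopia,SNNP,region,local_actor_time,1974
Teacher CLTS,Ethiopia,SNNP,region,community_time,2265
Teacher CLTS,Ethiopia,SNNP,region,hired_labor,0
Teacher CLTS,Ethiopia,SNNP,region,hardware,380
NGO CLTS,Ghana,All,country,management,26958
NGO CLTS,Ghana,All,country,training,4076
NGO CLTS,Ghana,All,country,facilitation,73428
NGO CLTS,Ghana,All,country,local_actor_time,1242
NGO CLTS,Ghana,All,country,community_time,5847
NGO CLTS,Ghana,All,country,hired_labor,7132
NGO CLTS,Ghana,All,country,hardware,13101
CLTS+NL Training,Ghana,All,country,management,29145
CLTS+NL Training,Ghana,All,country,training,155928
CLTS+NL Training,Ghana,All,country,facilitation,85052
CLTS+NL Training,Ghana,All,country,local_actor_time,5552
CLTS+NL Training,Ghana,All,country,community_time,8985
CLTS+NL Training,Ghana,All,country,hired_labor,14810
CLTS+NL Training,Ghana,All,country,hardware,44718
NGO CLTS,Ghana,Central,region,management,8797
NGO CLTS,Ghana,Central,region,training,1199
NGO CLTS,Ghana,Central,region,facilitation,28573
NGO CLTS,Ghana,Central,region,local_actor_time,314
NGO CLTS,Ghana,Central,region,community_time,1502
NGO CLTS,Ghana,Central,region,hired_labor,1096
NGO CLTS,Ghana,Central,region,hardware,4319
CLTS+NL Training,Ghana,Central,region,management,9525
CLTS+NL Training,Ghana,Central,region,training,38427
CLTS+NL Training,Ghana,Central,region,facilitation,32281
CLTS+NL Training,Ghana,Central,region,local_actor_time,1525
CLTS+NL Training,Ghana,Central,region,community_time,3661
CLTS+NL Training,Ghana,Central,region,hired_labor,1835
CLTS+NL Training,Ghana,Central,region,hardware,23501
NGO CLTS,Ghana,Upper West,region,management,9308
NGO CLTS,Ghana,Upper West,region,training,928
NGO CLTS,Ghana,Upper West,region,facilitation,18270
NGO CLTS,Ghana,Upper West,region,local_actor_time,372
NGO CLTS,Ghana,Upper West,region,community_time,1452
NGO CLTS,Ghana,Upper West,region,hired_labor,2191
NGO CLTS,Ghana,Upper West,region,hardware,1282
CLTS+NL Training,Ghana,Upper West,region,management,10037
CLTS+NL Training,Ghana,Upper West,region,training,62874
CLTS+NL Training,Ghana,Upper West,region,facilitation,23209
CLTS+NL Training,Ghana,Upper West,region,local_actor_time,1998
CLTS+NL Training,Ghana,Upper West,region,community_time,2028
CLTS+NL Training,Ghana,Upper West,region,hired_labor,3859
CLTS+NL Training,Ghana,Upper West,region,hardware,2452
NGO CLTS,Ghana,Volta,region,management,8853
NGO CLTS,Ghana,Volta,region,training,1949
NGO CLTS,Ghana,Volta,region,facilitation,26584
NGO CLTS,Ghana,Volta,region,local_actor_time,555
NGO CLTS,Ghana,Volta,region,community_time,2893
NGO CLTS,Ghana,Volta,region,hired_labor,3845
NGO CLTS,Ghana,Volta,region,hardware,7501
CLTS+NL Training,Ghana,Volta,region,management,9582
CLTS+NL Training,Ghana,Volta,region,training,54627
CLTS+NL Training,Ghana,Volta,region,facilitation,29562
CLTS+NL Training,Ghana,Volta,region,local_actor_time,2030
CLTS+NL Training,Ghana,Volta,region,community_time,3297
CLTS+NL Training,Ghana,Volta,region,hired_labor,9115
CLTS+NL Training,Ghana,Volta,region,hardware,18765
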