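sample_id,tree_id,group,ndfa_pct,rate_mg_per_kg_day
1-1,1,dosed_wild,0.087,2.70
1-2,1,dosed_wild,0.089,3.01
1-3,1,dosed_wild,0.031,0.75
1-4,1,dosed_wild,0.102,2.21
1-5,1,undosed_wild,NA,NA
2-1,2,dosed_wild,0.292,13.2
2-2,2,dosed_wild,0.101,4.55
2-3,2,dosed_wild,0.081,3.04
2-4,2,dosed_wild,0.040,1.48
2-5,2,undosed_wild,NA,NA
4-1,4,dosed_wild,0.103,5.74
4-2,4,dosed_wild,0.077,2.91
4-3,4,dosed_wild,0.761,20.6
4-4,4,dosed_wild,0.529,14.3
4-5,4,undosed_wild,NA,NA
5-1,5,dosed_wild,0.168,5.54
5-2,5,dosed_wild,0.689,14.6
5-3,5,dosed_wild,0.241,11.4
5-4,5,dosed_wild,0.276,11.1
5-5,5,undosed_wild,NA,NA
6-1,6,dosed_wild,0.041,2.08
6-2,6,dosed_wild,0.038,1.21
6-3,6,dosed_wild,0.218,10.0
6-4,6,dosed_wild,0.474,16.9
6-5,6,undosed_wild,NA,NA
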