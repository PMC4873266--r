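sample_id,tissue,medium,cfu_per_g,tntc
1,root,MG/L,2.0e7,FALSE
1,root,NL-CCM,1.7e7,FALSE
1,root,Nfb,8.2e6,FALSE
2,root,MG/L,3.4e7,FALSE
2,root,NL-CCM,NA,TRUE
2,root,Nfb,2.0e7,FALSE
3,stem,MG/L,5.7e6,FALSE
3,stem,NL-CCM,1.3e7,FALSE
3,stem,Nfb,2.9e6,FALSE
4,stem,MG/L,4.0e5,FALSE
4,stem,NL-CCM,7.5e5,FALSE
4,stem,Nfb,4.5e5,FALSE
5,stem,MG/L,3.0e5,FALSE
5,stem,NL-CCM,7.0e5,FALSE
5,stem,Nfb,3.5e5,FALSE
6,stem,MG/L,2.9e6,FALSE
6,stem,NL-CCM,5.5e5,FALSE
6,stem,Nfb,1.1e6,FALSE
7,leaf,MG/L,6.4e6,FALSE
7,leaf,NL-CCM,4.3e6,FALSE
7,leaf,Nfb,1.1e6,FALSE
8,leaf,MG/L,1.5e7,FALSE
8,leaf,NL-CCM,1.7e7,FALSE
8,leaf,Nfb,5.7e6,FALSE
9,leaf,MG/L,1.0e6,FALSE
9,leaf,NL-CCM,7.0e5,FALSE
9,leaf,Nfb,2.0e5,FALSE
10,leaf,MG/L,NA,TRUE
10,leaf,NL-CCM,1.4e6,FALSE
10,leaf,Nfb,4.5e5,FALSE
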