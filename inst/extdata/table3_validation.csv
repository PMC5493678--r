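source,bsa,lh,boec,angii,pge2,agp,edn1,phagocytosis,superoxide,alr_ref,lr_ref
Marey[2016a],0,0,0,0,0,0,0,1,1,0.98723,0.90697
Marey[2016a],0,0,0,0,0,0,2.49,0.92,0.96,0.91686,0.90659
Marey[2016a],0,0,0,0,0,0,24.9,0.85,0.8,0.88349,0.90319
Marey[2016a],0,0,0,0,0,0,249,0.75,0.73,0.82961,0.86905
Marey[2016a],0,0,0,0,0,0,2490,0.63,0.64,0.5174,0.53188
Marey[2016a],0,0,0,0,35.2,0,0,0.68,0.53,0.79128,0.84834
Marey[2016a],0,0,0,0,0,0,249,0.82,0.53,0.93489,0.90319
Marey[2016a],0,0,0,0,35.2,0,249,0.68,0.47,0.82746,0.84452
LIU[2014],0,0,0,0,0,100,0,0.59,0.82,0.54977,0.52432
Marey[2016b],0,0,0,0,0,0,0,1.33,1.43,1.37332,1.39558
Marey[2016b],0,0,0,10,0,0,0,1.33,1.39,1.12946,0.96378
Marey[2016b],0,0,0,1,0,0,0,1.3,1.4,0.99352,0.91269
Marey[2016b],0,0,0,0.1,0,0,0,1.27,1.27,1.09679,0.90754
Marey[2016b],0,0,0,0.01,0,0,0,1.26,1.32,1.09735,0.91269
Marey[2016b],0,0,0,0.1,35.2,0,0,0.8,0.61,0.7977,0.85411
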