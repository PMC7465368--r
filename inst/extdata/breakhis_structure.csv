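label,magnification,n_images,n_patients
A,40,114,4
A,100,113,4
A,200,111,4
A,400,106,4
F,40,253,10
F,100,260,10
F,200,264,10
F,400,237,10
TA,40,109,3
TA,100,121,3
TA,200,108,3
TA,400,115,3
PT,40,149,7
PT,100,150,7
PT,200,140,7
PT,400,130,7
DC,40,864,38
DC,100,903,38
DC,200,896,38
DC,400,788,38
LC,40,156,5
LC,100,170,5
LC,200,163,5
LC,400,137,5
MC,40,205,9
MC,100,222,9
MC,200,196,9
MC,400,169,9
PC,40,145,6
PC,100,142,6
PC,200,135,6
PC,400,138,6
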