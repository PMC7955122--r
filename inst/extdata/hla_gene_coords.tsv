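gene	pos_bp
HLA-F	29690552
HLA-V	29758731
HLA-G	29794744
HLA-H	29855371
HLA-A	29910247
HLA-K	29926659
HLA-J	29974360
HLA-L	30227361
HLA-E	30457244
HLA-C	31236526
HLA-B	31321649
MICA	31367561
MICB	31462658
HLA-DRA	32407619
HLA-DRB9	32427000
HLA-DRB5	32485120
HLA-DRB6	32520000
HLA-DRB7	32525000
HLA-DRB8	32530000
HLA-DRB4	32535000
HLA-DRB3	32540000
HLA-DRB2	32543000
HLA-DRB1	32546547
HLA-DQA1	32605169
HLA-DQB1	32627241
HLA-DOB	32780540
TAP2	32789610
TAP1	32812986
HLA-DMB	32902406
HLA-DMA	32916390
HLA-DOA	32971955
HLA-DPA1	33032346
HLA-DPB1	33043703
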