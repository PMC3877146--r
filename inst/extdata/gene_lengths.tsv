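gene	length
atp6	678
atp8	159
cox1	1537
cox2	676
cox3	789
cytb	1137
nad1	939
nad2	1023
nad3	354
nad4	1339
nad4l	297
nad5	1723
nad6	525
rrnL	1316
rrnS	777
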